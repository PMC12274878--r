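test_that("planted structures are counted and recovered exactly", {
  cfg <- synthetic_genome_config(n_nested_pairs = 5, n_neighbor_pairs = 5,
                                 n_singletons = 10, n_chromosomes = 3,
                                 seed = 11)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 30L) # 2*5 + 2*5 + 10
  expect_true(all(ann$genes$biotype == "protein_coding"))
  expect_identical(find_nested_pairs(ann$genes), ann$nested_pairs)
  expect_identical(find_neighbor_candidates(ann$genes), ann$neighbor_pairs)
  expect_equal(nrow(ann$nested_pairs), 5L)
  expect_equal(nrow(ann$neighbor_pairs), 5L)

  # nested gene strictly inside its host, opposite strand, >= 1 bp margin
  g <- ann$genes
  for (i in seq_len(nrow(ann$nested_pairs))) {
    h <- g[g$gene_id == ann$nested_pairs$gene_a_id[i], ]
    n <- g[g$gene_id == ann$nested_pairs$gene_b_id[i], ]
    expect_true(h$start < n$start && n$end < h$end)
    expect_true(h$strand != n$strand)
  }

  # reproducibility and seed sensitivity
  expect_identical(generate_annotation(cfg), ann)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(generate_annotation(cfg2)$genes, ann$genes))

  # no nested pairs requested -> finder returns empty
  cfg0 <- synthetic_genome_config(n_nested_pairs = 0, n_neighbor_pairs = 2,
                                  n_singletons = 5, n_chromosomes = 2, seed = 3)
  expect_equal(nrow(find_nested_pairs(generate_annotation(cfg0)$genes)), 0L)
})

test_that("random configurations always plant exactly the reported truth", {
  withr::local_seed(301)
  for (rep in 1:25) {
    cfg <- synthetic_genome_config(
      n_nested_pairs = sample(0:15, 1), n_neighbor_pairs = sample(0:15, 1),
      n_singletons = sample(1:30, 1), n_chromosomes = sample(2:6, 1),
      host_length_range = c(4000, 12000),
      nested_length_range = c(300, 1500),
      neighbor_gap_range = sort(sample(0:999, 2)),
      inter_gene_spacing_range = c(1000, 4000),
      seed = sample.int(1e6, 1)
    )
    ann <- generate_annotation(cfg)
    expect_identical(find_nested_pairs(ann$genes), ann$nested_pairs)
    expect_identical(find_neighbor_candidates(ann$genes), ann$neighbor_pairs)
  }
})

test_that("infeasible genome configurations are rejected", {
  expect_error(synthetic_genome_config(host_length_range = c(1000, 2000),
                                       nested_length_range = c(999, 3000)),
               "infeasible")
  expect_error(synthetic_genome_config(neighbor_gap_range = c(0, 1000)),
               "below 1000")
  expect_error(synthetic_genome_config(inter_gene_spacing_range = c(500, 900)),
               "at least 1000")
  expect_error(synthetic_genome_config(n_chromosomes = 1))
})

test_that("degenerate expression-model parameters give exact coefficients", {
  cfg <- synthetic_genome_config(n_nested_pairs = 20, n_neighbor_pairs = 0,
                                 n_singletons = 5, n_chromosomes = 2, seed = 7)
  ann <- generate_annotation(cfg)
  singles <- setdiff(ann$genes$gene_id,
                     c(ann$nested_pairs$gene_a_id, ann$nested_pairs$gene_b_id))

  # p_nested = 1, q1 = 1: both genes expressed in every cell type
  p1 <- coexpression_model_params(n_cell_types = 40, p_nested = 1, q1 = 1,
                                  seed = 8)
  sets1 <- binarize(generate_expression(ann$nested_pairs, singles, p1))
  res1 <- summarize_cohort(sets1, ann$nested_pairs)$results
  expect_true(all(res1$coefficient == 1))

  # q1 = 1, q0 = 0: host set equals nested set by construction
  p2 <- coexpression_model_params(n_cell_types = 40, p_nested = 0.5,
                                  q1 = 1, q0 = 0, seed = 9)
  sets2 <- binarize(generate_expression(ann$nested_pairs, singles, p2))
  res2 <- summarize_cohort(sets2, ann$nested_pairs)$results
  expect_true(all(res2$coefficient[res2$n_either > 0] == 1))

  # a gene may not appear twice across pairs and singletons
  expect_error(generate_expression(ann$nested_pairs, ann$genes$gene_id, p2),
               "only once")
})

test_that("analytic expectations are internally consistent and match simulation", {
  # independence (q1 = q0 = q) reduces to the Jaccard of independent Bernoullis
  pq <- coexpression_model_params(p_nested = 0.4, q1 = 0.25, q0 = 0.25)
  ex <- expected_statistics(pq)
  p <- 0.4; q <- 0.25
  expect_equal(ex$coefficient, p * q / (p + q - p * q))
  expect_equal(ex$p_host_given_nested, q)

  # degenerate denominator: host never expressed and nested never expressed
  ex0 <- expected_statistics(coexpression_model_params(p_nested = 0, q1 = 0.5,
                                                       q0 = 0))
  expect_true(is.na(ex0$coefficient))
  expect_true(is.na(ex0$p_host_given_nested))
  expect_true(is.na(ex0$p_nested_given_host))

  # simulated estimates at T = 5000 match all four expectations within 3 SE
  for (par in list(c(0.3, 0.8, 0.05), c(0.1, 0.5, 0.3))) {
    params <- coexpression_model_params(n_cell_types = 5000,
                                        p_nested = par[1], q1 = par[2],
                                        q0 = par[3], seed = 17)
    ex <- expected_statistics(params)
    pairs <- data.frame(gene_a_id = sprintf("h%03d", 1:60),
                        gene_b_id = sprintf("n%03d", 1:60),
                        pair_class = "nested", stringsAsFactors = FALSE)
    sets <- binarize(generate_expression(pairs, character(), params))
    res <- summarize_cohort(sets, pairs)$results
    n <- nrow(res)
    expect_lt(abs(mean(res$coefficient) - ex$coefficient),
              3 * stats::sd(res$coefficient) / sqrt(n))
    expect_lt(abs(mean(res$p_host_given_nested) - ex$p_host_given_nested),
              3 * stats::sd(res$p_host_given_nested) / sqrt(n))
    expect_lt(abs(mean(res$p_nested_given_host) - ex$p_nested_given_host),
              3 * stats::sd(res$p_nested_given_host) / sqrt(n))
    co_rate <- mean(res$n_both) / params$n_cell_types
    expect_lt(abs(co_rate - ex$p_coexpressed), 0.01)
  }
})

test_that("the directional asymmetry follows the analytic formulas", {
  for (par in list(c(0.3, 0.8, 0.05), c(0.1, 0.5, 0.3))) {
    params <- coexpression_model_params(n_cell_types = 3000, p_nested = par[1],
                                        q1 = par[2], q0 = par[3], seed = 23)
    ex <- expected_statistics(params)
    pairs <- data.frame(gene_a_id = sprintf("h%03d", 1:80),
                        gene_b_id = sprintf("n%03d", 1:80),
                        pair_class = "nested", stringsAsFactors = FALSE)
    sets <- binarize(generate_expression(pairs, character(), params))
    s <- summarize_cohort(sets, pairs)$summary
    # the estimated means reproduce the sign of the analytic asymmetry
    expect_equal(sign(s$mean_p_host_given_nested - s$mean_p_nested_given_host),
                 sign(ex$p_host_given_nested - ex$p_nested_given_host))
  }
})

test_that("estimates converge to the analytic limits as cell types grow", {
  params_at <- function(t_cells, seed) {
    coexpression_model_params(n_cell_types = t_cells, p_nested = 0.3,
                              q1 = 0.8, q0 = 0.05, seed = seed)
  }
  ex <- expected_statistics(params_at(100, 1))
  pairs <- data.frame(gene_a_id = sprintf("h%02d", 1:40),
                      gene_b_id = sprintf("n%02d", 1:40),
                      pair_class = "nested", stringsAsFactors = FALSE)
  med_err <- vapply(c(100, 1000, 5000), function(t_cells) {
    errs <- vapply(1:20, function(s) {
      sets <- binarize(generate_expression(pairs, character(),
                                           params_at(t_cells, s)))
      sm <- summarize_cohort(sets, pairs)$summary
      abs(sm$mean_coefficient - ex$coefficient) +
        abs(sm$mean_p_host_given_nested - ex$p_host_given_nested)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("generated tables pass expression validation and cover planted genes", {
  cfg <- synthetic_genome_config(n_nested_pairs = 8, n_neighbor_pairs = 6,
                                 n_singletons = 12, n_chromosomes = 3,
                                 seed = 31)
  ann <- generate_annotation(cfg)
  singles <- setdiff(ann$genes$gene_id,
                     c(ann$nested_pairs$gene_a_id, ann$nested_pairs$gene_b_id,
                       ann$neighbor_pairs$gene_a_id, ann$neighbor_pairs$gene_b_id))
  params <- coexpression_model_params(n_cell_types = 50, seed = 32)
  tab <- generate_expression(rbind(ann$nested_pairs, ann$neighbor_pairs),
                             singles, params, dataset_label = "terminal")
  expect_setequal(rownames(tab$values), ann$genes$gene_id)
  expect_true(all(tab$values >= 0))
  expect_equal(tab$dataset_label, "terminal")
  # positive magnitudes exactly where the gate is open
  expect_true(all((tab$values > 0) == (tab$values != 0)))
})

test_that("fixture files on disk reproduce the in-memory objects", {
  dir <- withr::local_tempdir()
  gcfg <- synthetic_genome_config(n_nested_pairs = 6, n_neighbor_pairs = 4,
                                  n_singletons = 10, n_chromosomes = 3,
                                  seed = 41)
  params <- coexpression_model_params(n_cell_types = 30, seed = 42)
  fx <- write_synthetic_fixtures(gcfg, params, dir,
                                 dataset_labels = c("lineage", "terminal"))
  genes <- parse_gene_annotation(fx$paths$annotation)
  expect_equal(sort(genes$gene_id), sort(fx$truth$genes$gene_id))
  expect_identical(find_nested_pairs(genes), fx$truth$nested_pairs)
  expect_identical(find_neighbor_candidates(genes), fx$truth$neighbor_pairs)
  tab <- load_expression_table(fx$paths$expression$lineage, "long", "lineage")
  expect_setequal(rownames(tab$values), genes$gene_id)
  truth <- jsonlite::read_json(fx$paths$truth)
  expect_equal(truth$n_genes, nrow(genes))
})
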