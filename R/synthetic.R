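# integer draw, uniform on lo..hi, vector-safe and runif-backed so the RNG
# stream is consumed predictably
.rint <- function(n, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(hi >= lo)
  pmin(lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L))), hi)
}

#' Configuration for the synthetic genome generator
#'
#' Defaults mirror the scale of the worm genome analysis (six chromosomes,
#' 567 opposite nested pairs) with gene lengths and spacings typical of a
#' compact genome. Spacing between planted structures is at least 1 kb so no
#' accidental neighbor pairs (< 1 kb apart) arise, and planted structures
#' never overlap, so the planted pairs are provably the only nested and
#' neighbor pairs in the annotation.
#'
#' @param n_chromosomes Number of chromosomes (>= 2 so random
#'   cross-chromosome sampling is feasible).
#' @param n_nested_pairs,n_neighbor_pairs,n_singletons Planted structure
#'   counts.
#' @param host_length_range,nested_length_range Host and nested/ordinary gene
#'   length ranges in bp; nested genes must fit strictly inside hosts with at
#'   least 1 bp margin on each side.
#' @param neighbor_gap_range Intergenic gap range for planted neighbor pairs;
#'   both bounds must be below 1000.
#' @param inter_gene_spacing_range Gap range between consecutive planted
#'   structures; lower bound must be >= 1000.
#' @param seed Integer seed.
#' @return A `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(n_chromosomes = 6,
                                    n_nested_pairs = 567,
                                    n_neighbor_pairs = 567,
                                    n_singletons = 5000,
                                    host_length_range = c(5000, 20000),
                                    nested_length_range = c(500, 2000),
                                    neighbor_gap_range = c(0, 999),
                                    inter_gene_spacing_range = c(1000, 5000),
                                    seed = 1) {
  stopifnot(n_chromosomes >= 2,
            n_nested_pairs >= 0, n_neighbor_pairs >= 0, n_singletons >= 0,
            length(host_length_range) == 2, length(nested_length_range) == 2,
            length(neighbor_gap_range) == 2,
            length(inter_gene_spacing_range) == 2,
            host_length_range[1] <= host_length_range[2],
            nested_length_range[1] <= nested_length_range[2],
            neighbor_gap_range[1] <= neighbor_gap_range[2])
  if (n_nested_pairs + n_neighbor_pairs + n_singletons < 1) {
    stop("at least one structure must be requested")
  }
  if (nested_length_range[2] > host_length_range[1] - 2) {
    stop("infeasible config: nested genes (up to ", nested_length_range[2],
         " bp) cannot fit strictly inside the smallest host (",
         host_length_range[1], " bp) with a 1 bp margin on each side")
  }
  if (neighbor_gap_range[2] >= 1000) {
    stop("neighbor gaps must stay below 1000 bp")
  }
  if (inter_gene_spacing_range[1] < 1000) {
    stop("inter-structure spacing must be at least 1000 bp to avoid accidental neighbors")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    n_nested_pairs = as.integer(n_nested_pairs),
    n_neighbor_pairs = as.integer(n_neighbor_pairs),
    n_singletons = as.integer(n_singletons),
    host_length_range = as.integer(host_length_range),
    nested_length_range = as.integer(nested_length_range),
    neighbor_gap_range = as.integer(neighbor_gap_range),
    inter_gene_spacing_range = as.integer(inter_gene_spacing_range),
    seed = as.integer(seed)
  ), class = "synthetic_genome_config")
}

.chrom_names <- function(n) {
  worm <- paste0("chr", c("I", "II", "III", "IV", "V", "X"))
  if (n <= length(worm)) worm[seq_len(n)] else sprintf("chr%02d", seq_len(n))
}

#' Generate a synthetic gene annotation with planted pair structure
#'
#' Plants the configured numbers of opposite nested pairs, opposite-strand
#' neighbor pairs and singleton genes across chromosomes (round-robin over a
#' shuffled structure order), with inter-structure spacing >= 1 kb. By
#' construction, [find_nested_pairs()] on the result returns exactly the
#' planted nested pairs and [find_neighbor_candidates()] exactly the planted
#' neighbor pairs.
#'
#' @param config A [synthetic_genome_config()].
#' @return List with `genes` (a [gene_set()]), `nested_pairs` and
#'   `neighbor_pairs` (planted-truth pair `data.frame`s, sorted like the
#'   finder output).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  withr::with_seed(config$seed, {
    units <- c(rep("nested", config$n_nested_pairs),
               rep("neighbor", config$n_neighbor_pairs),
               rep("singleton", config$n_singletons))
    units <- units[order(stats::runif(length(units)))]
    unit_chrom <- rep_len(seq_len(config$n_chromosomes), length(units))
    chroms <- .chrom_names(config$n_chromosomes)

    hl <- config$host_length_range
    nl <- config$nested_length_range
    gp <- config$neighbor_gap_range
    sp <- config$inter_gene_spacing_range

    rows <- vector("list", length(units))
    nested_truth <- vector("list", length(units))
    neighbor_truth <- vector("list", length(units))
    cursor <- integer(config$n_chromosomes) # last occupied base per chromosome
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("SYNG%05d", gid)
    }

    for (u in seq_along(units)) {
      ch <- unit_chrom[u]
      start <- cursor[ch] + .rint(1, sp[1], sp[2]) + 1L
      if (units[u] == "nested") {
        host_len <- .rint(1, hl[1], hl[2])
        nested_len <- .rint(1, nl[1], min(nl[2], host_len - 2L))
        offset <- .rint(1, 1L, host_len - nested_len - 1L)
        host_strand <- if (stats::runif(1) < 0.5) "+" else "-"
        host_id <- next_id(); nested_id <- next_id()
        host_end <- start + host_len - 1L
        n_start <- start + offset
        rows[[u]] <- data.frame(
          gene_id = c(host_id, nested_id), chrom = chroms[ch],
          start = c(start, n_start),
          end = c(host_end, n_start + nested_len - 1L),
          strand = c(host_strand, setdiff(c("+", "-"), host_strand)),
          biotype = "protein_coding", stringsAsFactors = FALSE
        )
        nested_truth[[u]] <- data.frame(
          gene_a_id = host_id, gene_b_id = nested_id,
          chrom = chroms[ch], start_a = start, start_b = n_start,
          stringsAsFactors = FALSE
        )
        cursor[ch] <- host_end
      } else if (units[u] == "neighbor") {
        len1 <- .rint(1, nl[1], nl[2])
        len2 <- .rint(1, nl[1], nl[2])
        gap <- .rint(1, gp[1], gp[2])
        divergent <- stats::runif(1) < 0.5
        id1 <- next_id(); id2 <- next_id()
        end1 <- start + len1 - 1L
        start2 <- end1 + gap + 1L
        rows[[u]] <- data.frame(
          gene_id = c(id1, id2), chrom = chroms[ch],
          start = c(start, start2),
          end = c(end1, start2 + len2 - 1L),
          strand = if (divergent) c("-", "+") else c("+", "-"),
          biotype = "protein_coding", stringsAsFactors = FALSE
        )
        neighbor_truth[[u]] <- data.frame(
          gene_a_id = id1, gene_b_id = id2, gap_bp = gap,
          chrom = chroms[ch], start_a = start, start_b = start2,
          stringsAsFactors = FALSE
        )
        cursor[ch] <- start2 + len2 - 1L
      } else {
        len <- .rint(1, nl[1], nl[2])
        rows[[u]] <- data.frame(
          gene_id = next_id(), chrom = chroms[ch],
          start = start, end = start + len - 1L,
          strand = if (stats::runif(1) < 0.5) "+" else "-",
          biotype = "protein_coding", stringsAsFactors = FALSE
        )
        cursor[ch] <- start + len - 1L
      }
    }

    genes <- gene_set(do.call(rbind, rows), source = "synthetic")
    sort_truth <- function(lst, with_gap) {
      if (length(lst) == 0 || all(vapply(lst, is.null, logical(1)))) {
        return(.gene_pairs(pair_class = if (with_gap) "neighbor" else "nested"))
      }
      df <- do.call(rbind, lst[!vapply(lst, is.null, logical(1))])
      df <- df[order(df$chrom, df$start_a, df$start_b, method = "radix"), ]
      .gene_pairs(df$gene_a_id, df$gene_b_id,
                  pair_class = if (with_gap) "neighbor" else "nested",
                  gap_bp = if (with_gap) df$gap_bp else NA_integer_)
    }
    list(genes = genes,
         nested_pairs = sort_truth(nested_truth, with_gap = FALSE),
         neighbor_pairs = sort_truth(neighbor_truth, with_gap = TRUE))
  })
}

#' Parameters of the Bernoulli coexpression model
#'
#' The generator's expression model per cell type, for each planted pair: the
#' nested gene (gene B) is expressed with probability `p_nested`; the host
#' (gene A) is expressed with probability `q1` if the nested gene is
#' expressed in that cell type and `q0` otherwise; singleton genes are
#' expressed independently with probability `p_nested`. Expressed entries
#' receive a log-normal positive magnitude (magnitudes only exercise the I/O
#' path; every downstream statistic depends on the > 0 binarization alone).
#'
#' Defaults are chosen so the large-T conditional-probability limits mirror
#' the directional asymmetry reported for the worm embryo atlases
#' (P(host | nested) about 0.5, P(nested | host) about 0.16).
#'
#' @param n_cell_types Number of cell types T.
#' @param p_nested Per-cell-type expression probability of nested/singleton
#'   genes.
#' @param q1,q0 Host expression probability given the nested gene is / is not
#'   expressed in that cell type.
#' @param magnitude_meanlog,magnitude_sdlog Log-normal parameters of positive
#'   magnitudes.
#' @param seed Integer seed.
#' @return A `coexpression_model_params` list.
#' @export
coexpression_model_params <- function(n_cell_types = 500,
                                      p_nested = 0.1, q1 = 0.5, q0 = 0.3,
                                      magnitude_meanlog = 1,
                                      magnitude_sdlog = 1,
                                      seed = 1) {
  stopifnot(n_cell_types >= 1,
            p_nested >= 0, p_nested <= 1, q1 >= 0, q1 <= 1, q0 >= 0, q0 <= 1,
            magnitude_sdlog >= 0)
  structure(list(
    n_cell_types = as.integer(n_cell_types),
    p_nested = p_nested, q1 = q1, q0 = q0,
    magnitude_meanlog = magnitude_meanlog,
    magnitude_sdlog = magnitude_sdlog,
    seed = as.integer(seed)
  ), class = "coexpression_model_params")
}

#' Generate a synthetic expression table from the Bernoulli model
#'
#' @param pairs Pair `data.frame`; for each pair, `gene_b_id` follows the
#'   nested-gene marginal and `gene_a_id` the conditional host model.
#' @param singletons Character vector of singleton gene ids (independent
#'   expression at `p_nested`).
#' @param params A [coexpression_model_params()].
#' @param dataset_label Label stored on the table (default `"lineage"`).
#' @return An [expression_table()] covering all pair genes and singletons.
#' @export
generate_expression <- function(pairs, singletons, params,
                                dataset_label = "lineage") {
  stopifnot(inherits(params, "coexpression_model_params"))
  pair_genes <- c(rbind(pairs$gene_a_id, pairs$gene_b_id))
  all_genes <- c(pair_genes, as.character(singletons))
  if (anyDuplicated(all_genes)) {
    stop("a gene may appear only once across pairs and singletons")
  }
  t_cells <- params$n_cell_types
  n_pairs <- nrow(pairs)
  n_single <- length(singletons)
  withr::with_seed(params$seed, {
    expressed <- matrix(FALSE, nrow = length(all_genes), ncol = t_cells,
                        dimnames = list(all_genes,
                                        sprintf("ct%04d", seq_len(t_cells))))
    if (n_pairs > 0) {
      b_on <- matrix(stats::runif(n_pairs * t_cells) < params$p_nested,
                     nrow = n_pairs)
      a_on <- matrix(stats::runif(n_pairs * t_cells), nrow = n_pairs) <
        ifelse(b_on, params$q1, params$q0)
      expressed[match(pairs$gene_a_id, all_genes), ] <- a_on
      expressed[match(pairs$gene_b_id, all_genes), ] <- b_on
    }
    if (n_single > 0) {
      expressed[match(as.character(singletons), all_genes), ] <-
        matrix(stats::runif(n_single * t_cells) < params$p_nested,
               nrow = n_single)
    }
    values <- matrix(0, nrow = nrow(expressed), ncol = t_cells,
                     dimnames = dimnames(expressed))
    values[expressed] <- stats::rlnorm(sum(expressed),
                                       meanlog = params$magnitude_meanlog,
                                       sdlog = params$magnitude_sdlog)
    expression_table(values, dataset_label = dataset_label)
  })
}

#' Analytic large-T expectations of the coexpression statistics
#'
#' Under the Bernoulli model, per cell type: P(nested) = p, P(both) = p q1,
#' P(host) = p q1 + (1 - p) q0, P(either) = p + (1 - p) q0. As the number of
#' cell types grows, the count ratios converge to the corresponding
#' probability ratios.
#'
#' @param params A [coexpression_model_params()].
#' @return List with limits `coefficient`, `p_host_given_nested`,
#'   `p_nested_given_host`, `p_coexpressed` (per-cell-type co-expression
#'   probability); entries are `NA` where the limiting denominator is 0.
#' @export
expected_statistics <- function(params) {
  stopifnot(inherits(params, "coexpression_model_params"))
  p <- params$p_nested; q1 <- params$q1; q0 <- params$q0
  p_both <- p * q1
  p_host <- p * q1 + (1 - p) * q0
  p_either <- p + (1 - p) * q0
  list(
    coefficient = if (p_either > 0) p_both / p_either else NA_real_,
    p_host_given_nested = if (p > 0) q1 else NA_real_,
    p_nested_given_host = if (p_host > 0) p_both / p_host else NA_real_,
    p_coexpressed = p_both
  )
}

#' Write a complete synthetic fixture set to disk
#'
#' Writes a GFF3 annotation with planted pairs, one long-format expression
#' TSV per dataset label (each generated with a seed derived from the model
#' seed and the label index), and a planted-truth JSON (pairs, model
#' parameters, analytic expectations).
#'
#' @param genome_config A [synthetic_genome_config()].
#' @param model_params A [coexpression_model_params()].
#' @param out_dir Output directory (created if needed).
#' @param dataset_labels Labels of the expression tables to emit.
#' @return List with `paths` (annotation, expression per label, truth JSON)
#'   and `truth` (genes, planted pairs, expectations), invisibly.
#' @export
write_synthetic_fixtures <- function(genome_config, model_params, out_dir,
                                     dataset_labels = c("lineage", "terminal")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(genome_config)
  gff_path <- file.path(out_dir, "genes.gff3")
  write_gene_set_gff3(ann$genes, gff_path)

  singletons <- setdiff(ann$genes$gene_id,
                        c(ann$nested_pairs$gene_a_id, ann$nested_pairs$gene_b_id,
                          ann$neighbor_pairs$gene_a_id, ann$neighbor_pairs$gene_b_id))
  pairs_all <- rbind(ann$nested_pairs, ann$neighbor_pairs)
  expr_paths <- character(0)
  for (k in seq_along(dataset_labels)) {
    p <- model_params
    p$seed <- substream_seed(model_params$seed, k)
    tab <- generate_expression(pairs_all, singletons, p,
                               dataset_label = dataset_labels[k])
    path <- file.path(out_dir, sprintf("expression_%s.tsv", dataset_labels[k]))
    write_expression_tsv(tab, path)
    expr_paths[dataset_labels[k]] <- path
  }

  truth <- list(
    n_genes = nrow(ann$genes),
    nested_pairs = ann$nested_pairs,
    neighbor_pairs = ann$neighbor_pairs,
    model_params = unclass(model_params),
    expected = expected_statistics(model_params)
  )
  truth_path <- file.path(out_dir, "truth.json")
  .write_json(truth, truth_path)
  invisible(list(
    paths = list(annotation = gff_path, expression = as.list(expr_paths),
                 truth = truth_path),
    truth = c(list(genes = ann$genes), truth)
  ))
}

#' Export a gene set as GFF3
#'
#' One `gene` feature per record with `ID` and `biotype` attributes.
#'
#' @param genes A [gene_set()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_set_gff3 <- function(genes, path) {
  gr <- .as_granges(genes)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "nestcoex"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$biotype <- genes$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
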