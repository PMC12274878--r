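#' Build a run configuration
#'
#' @param annotation Path to the GFF3 annotation.
#' @param expression List of dataset specs, each a list with `path`, `layout`
#'   (`"long"`/`"wide"`) and `dataset_label`.
#' @param out_dir Output directory.
#' @param threshold Binarization cutoff (default 0).
#' @param null_classes Null samplers to run (subset of `"random"`,
#'   `"neighbor"`; default both).
#' @param n_null_pairs Pairs per null iteration; `NULL` (default) uses the
#'   number of nested pairs found.
#' @param n_iterations Null iterations (default 1000).
#' @param seed Top-level seed; all randomness derives from it via named
#'   substreams (null class x dataset x iteration).
#' @param biotype_filter Biotype retained from the annotation.
#' @param max_gap_bp Neighbor gap bound.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, expression, out_dir,
                       threshold = 0,
                       null_classes = c("random", "neighbor"),
                       n_null_pairs = NULL,
                       n_iterations = 1000,
                       seed = 1,
                       biotype_filter = "protein_coding",
                       max_gap_bp = 1000) {
  stopifnot(is.character(annotation), length(annotation) == 1)
  null_classes <- match.arg(null_classes, c("random", "neighbor"),
                            several.ok = TRUE)
  if (!file.exists(annotation)) stop("annotation file not found: ", annotation)
  for (spec in expression) {
    if (!all(c("path", "layout", "dataset_label") %in% names(spec))) {
      stop("each expression spec needs path, layout, dataset_label")
    }
    if (!file.exists(spec$path)) stop("expression file not found: ", spec$path)
  }
  structure(list(
    annotation = annotation, expression = expression, out_dir = out_dir,
    threshold = threshold, null_classes = null_classes,
    n_null_pairs = n_null_pairs, n_iterations = as.integer(n_iterations),
    seed = as.integer(seed), biotype_filter = biotype_filter,
    max_gap_bp = max_gap_bp
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments; `expression` is a list of
#' `{path, layout, dataset_label}` mappings. Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  y$annotation <- resolve(y$annotation)
  y$expression <- lapply(y$expression, function(s) {
    s$path <- resolve(s$path)
    s
  })
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full nested-gene coexpression analysis
#'
#' Parses the annotation, finds opposite nested pairs, and for every
#' expression dataset computes per-pair coexpression statistics, the cohort
#' summary, and the configured null distributions of the mean coefficient
#' with their comparisons to the observed nested-pair mean. All outputs are
#' written under `config$out_dir` with fixed names (`nested_pairs.tsv`,
#' `coexpression_<dataset>.tsv`, `summary_<dataset>.json`,
#' `null_<class>_<dataset>.tsv`, `null_comparison_<class>_<dataset>.json`,
#' `manifest.json`); two runs with identical config and seed produce
#' byte-identical files.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @param quiet Suppress progress messages (default `FALSE`; messages go to
#'   `stderr`).
#' @return Run report: list with `genes` (count), `nested_pairs` (count),
#'   per-dataset `summaries` and `null_comparisons`, and `outputs` (paths),
#'   invisibly.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)

  genes <- .stage("parse_annotation",
                  parse_gene_annotation(config$annotation,
                                        biotype_filter = config$biotype_filter))
  say(sprintf("annotation: %d %s genes (%d features skipped)",
              nrow(genes), config$biotype_filter,
              attr(genes, "n_skipped") %||% 0L))

  nested <- .stage("find_nested_pairs", find_nested_pairs(genes))
  say(sprintf("opposite nested pairs: %d", nrow(nested)))
  p_nested <- file.path(config$out_dir, "nested_pairs.tsv")
  write_pairs_tsv(nested, genes, p_nested)
  outputs <- c(outputs, p_nested)

  n_null_pairs <- config$n_null_pairs %||% nrow(nested)
  summaries <- list()
  null_comparisons <- list()

  for (spec in config$expression) {
    label <- spec$dataset_label
    sets <- .stage(paste0("load_expression[", label, "]"), {
      tab <- load_expression_table(spec$path, layout = spec$layout,
                                   dataset_label = label)
      binarize(tab, threshold = config$threshold)
    })
    n_unprofiled <- sum(!c(nested$gene_a_id, nested$gene_b_id) %in%
                          rownames(sets$membership))
    say(sprintf("[%s] %d cell types; %d nested-pair genes unprofiled (coefficient 0 convention)",
                label, length(sets$universe), n_unprofiled))

    cohort <- .stage(paste0("coexpression[", label, "]"),
                     summarize_cohort(sets, nested, dataset_label = label))
    p_coex <- file.path(config$out_dir, sprintf("coexpression_%s.tsv", label))
    write_cohort_tsv(cohort, p_coex)
    p_sum <- file.path(config$out_dir, sprintf("summary_%s.json", label))
    .write_json(cohort$summary, p_sum)
    outputs <- c(outputs, p_coex, p_sum)
    summaries[[label]] <- cohort$summary
    say(sprintf("[%s] fraction coexpressed %.3f, mean coefficient %.4f",
                label, cohort$summary$fraction_coexpressed,
                cohort$summary$mean_coefficient))

    for (nc in config$null_classes) {
      # named substream: one seed per (dataset, null class)
      nc_seed <- substream_seed(config$seed,
                                1000L * match(label, vapply(config$expression,
                                                            `[[`, "",
                                                            "dataset_label")) +
                                  match(nc, c("random", "neighbor")))
      nd <- .stage(paste0("null[", nc, ",", label, "]"),
                   null_mean_distribution(sets, genes, null_class = nc,
                                          n_pairs = n_null_pairs,
                                          n_iterations = config$n_iterations,
                                          seed = nc_seed,
                                          max_gap_bp = config$max_gap_bp))
      cmp <- compare_to_null(cohort$summary$mean_coefficient, nd)
      p_null <- file.path(config$out_dir, sprintf("null_%s_%s.tsv", nc, label))
      write_null_tsv(nd, p_null)
      p_cmp <- file.path(config$out_dir,
                         sprintf("null_comparison_%s_%s.json", nc, label))
      .write_json(cmp[c("observed_mean", "empirical_quantile", "n_iterations",
                        "null_class", "dataset_label")], p_cmp)
      outputs <- c(outputs, p_null, p_cmp)
      null_comparisons[[paste(nc, label, sep = "_")]] <- cmp
      say(sprintf("[%s] %s null: mean of means %.4f; observed at quantile %.3f",
                  label, nc, mean(nd$means), cmp$empirical_quantile))
    }
  }

  manifest <- list(
    package = "nestcoex",
    version = as.character(utils::packageVersion("nestcoex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    threshold = config$threshold,
    n_null_pairs = n_null_pairs,
    n_iterations = config$n_iterations,
    inputs = c(
      list(annotation = as.vector(tools::md5sum(config$annotation))),
      stats::setNames(
        lapply(config$expression, function(s) as.vector(tools::md5sum(s$path))),
        vapply(config$expression, function(s) paste0("expression_", s$dataset_label), "")
      )
    ),
    outputs = stats::setNames(as.list(as.vector(tools::md5sum(outputs))),
                              basename(outputs))
  )
  p_manifest <- file.path(config$out_dir, "manifest.json")
  .write_json(manifest, p_manifest)

  invisible(list(
    genes = nrow(genes),
    nested_pairs = nrow(nested),
    summaries = summaries,
    null_comparisons = null_comparisons,
    outputs = c(outputs, p_manifest)
  ))
}
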