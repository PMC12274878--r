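# vectorized core: counts and ratios for (gene_a, gene_b) id vectors against
# one expressed_sets object; genes absent from the table get all-FALSE rows
.pair_counts <- function(sets, gene_a, gene_b) {
  m <- sets$membership
  fetch <- function(ids) {
    out <- matrix(FALSE, nrow = length(ids), ncol = ncol(m))
    i <- match(ids, rownames(m))
    known <- !is.na(i)
    if (any(known)) out[known, ] <- m[i[known], , drop = FALSE]
    out
  }
  a <- fetch(gene_a)
  b <- fetch(gene_b)
  n_a <- as.integer(rowSums(a))
  n_b <- as.integer(rowSums(b))
  n_both <- as.integer(rowSums(a & b))
  n_either <- n_a + n_b - n_both
  data.frame(
    gene_a_id = as.character(gene_a),
    gene_b_id = as.character(gene_b),
    n_a = n_a, n_b = n_b, n_both = n_both, n_either = n_either,
    # zero-denominator rule: no cell type expresses either gene -> 0
    coefficient = ifelse(n_either > 0, n_both / n_either, 0),
    p_host_given_nested = ifelse(n_b > 0, n_both / n_b, NA_real_),
    p_nested_given_host = ifelse(n_a > 0, n_both / n_a, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Coefficient of coexpression and conditional probabilities for one pair
#'
#' The coefficient of coexpression is the number of cell types expressing
#' both genes divided by the number of cell types expressing at least one
#' (the Jaccard index of the two expressed-cell-type sets); it is defined as
#' 0 when no cell type expresses either gene. The directional conditional
#' probabilities divide the co-expressing count by the count of cell types
#' expressing the nested gene (gene B) or the host gene (gene A)
#' respectively, and are `NA` when that denominator is 0.
#'
#' @param sets An [binarize()] result.
#' @param gene_a Host gene id (gene A).
#' @param gene_b Nested gene id (gene B); must differ from `gene_a`.
#' @return One-row `data.frame` with `n_a`, `n_b`, `n_both`, `n_either`,
#'   `coefficient`, `p_host_given_nested`, `p_nested_given_host`.
#' @export
coexpression_coefficient <- function(sets, gene_a, gene_b) {
  stopifnot(inherits(sets, "expressed_sets"),
            length(gene_a) == 1, length(gene_b) == 1)
  if (identical(as.character(gene_a), as.character(gene_b))) {
    stop("a pair must reference two distinct genes")
  }
  .pair_counts(sets, gene_a, gene_b)
}

#' Per-pair coexpression results and cohort summary
#'
#' Computes the coefficient of coexpression and both conditional expression
#' probabilities for every pair, then summarizes the cohort: the fraction of
#' pairs coexpressed in at least one cell type (`coefficient > 0`), the mean
#' coefficient, and the means of the conditional probabilities taken over
#' pairs where the respective denominator is nonzero (the counts of pairs
#' entering each mean are reported so the alternative zero-imputed convention
#' can be recomputed from the per-pair table).
#'
#' @param sets An [binarize()] result.
#' @param pairs Pair `data.frame` (`gene_a_id`, `gene_b_id`, `pair_class`).
#' @param dataset_label Optional label; defaults to the label carried by
#'   `sets`.
#' @return A `cohort_summary`: list with `summary` (named list of cohort
#'   statistics), `results` (per-pair table in input order) and `ranked`
#'   (per-pair table sorted by ascending coefficient, ties broken by
#'   `gene_a_id`, for rank plots).
#' @export
summarize_cohort <- function(sets, pairs, dataset_label = sets$dataset_label) {
  stopifnot(inherits(sets, "expressed_sets"))
  if (nrow(pairs) == 0) stop("pairs must be nonempty")
  if (any(pairs$gene_a_id == pairs$gene_b_id)) {
    stop("a pair must reference two distinct genes")
  }
  res <- .pair_counts(sets, pairs$gene_a_id, pairs$gene_b_id)
  res$pair_class <- pairs$pair_class
  res <- res[, c("gene_a_id", "gene_b_id", "pair_class", "n_a", "n_b",
                 "n_both", "n_either", "coefficient",
                 "p_host_given_nested", "p_nested_given_host")]
  hgn <- res$p_host_given_nested
  ngh <- res$p_nested_given_host
  summary <- list(
    dataset_label = dataset_label,
    n_pairs = nrow(res),
    fraction_coexpressed = mean(res$coefficient > 0),
    mean_coefficient = mean(res$coefficient),
    mean_p_host_given_nested = if (any(!is.na(hgn))) mean(hgn, na.rm = TRUE) else NA_real_,
    mean_p_nested_given_host = if (any(!is.na(ngh))) mean(ngh, na.rm = TRUE) else NA_real_,
    n_pairs_defined_hgn = sum(!is.na(hgn)),
    n_pairs_defined_ngh = sum(!is.na(ngh))
  )
  ranked <- res[order(res$coefficient, res$gene_a_id, method = "radix"), ]
  rownames(ranked) <- NULL
  structure(list(summary = summary, results = res, ranked = ranked),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cohort_summary '%s': %d pairs\n", s$dataset_label, s$n_pairs))
  cat(sprintf("  coexpressed in >=1 cell type: %.1f%%\n",
              100 * s$fraction_coexpressed))
  cat(sprintf("  mean coefficient of coexpression: %.4f\n", s$mean_coefficient))
  cat(sprintf("  mean P(host | nested): %.4f  (over %d pairs)\n",
              s$mean_p_host_given_nested, s$n_pairs_defined_hgn))
  cat(sprintf("  mean P(nested | host): %.4f  (over %d pairs)\n",
              s$mean_p_nested_given_host, s$n_pairs_defined_ngh))
  invisible(x)
}

#' Write the per-pair coexpression table to TSV
#'
#' Undefined conditional probabilities are written as `NA`.
#'
#' @param cohort A [summarize_cohort()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  .write_tsv(cohort$results, path)
}
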