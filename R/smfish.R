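.locus_states <- c("none", "a_only", "b_only", "both")

.validate_loci <- function(observations) {
  need <- c("nucleus_id", "locus_index", "state")
  if (!all(need %in% names(observations))) {
    stop("locus observations require columns: ", paste(need, collapse = ", "))
  }
  if (nrow(observations) == 0) stop("locus observations must be nonempty")
  bad <- setdiff(unique(observations$state), .locus_states)
  if (length(bad) > 0) {
    stop("unknown locus state(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.locus_states, collapse = "/"), ")")
  }
  per_nucleus <- table(observations$nucleus_id)
  if (any(per_nucleus > 2)) {
    stop("nucleus '", names(per_nucleus)[which(per_nucleus > 2)[1]],
         "' has more than 2 loci")
  }
  if (anyDuplicated(observations[, c("nucleus_id", "locus_index")])) {
    stop("duplicate (nucleus_id, locus_index) observation")
  }
  invisible(observations)
}

#' Two-color transcription-site co-occurrence statistics
#'
#' Each observation is one transcription locus (allele) of one nucleus in a
#' two-color smFISH experiment with intronic probes, scored as actively
#' transcribing gene A only, gene B only, both, or neither. Marginal
#' frequencies pool all loci: `f_a` is the fraction of loci with A active
#' (states `a_only` or `both`), likewise `f_b`; `f_both` is the
#' double-positive fraction. The ratio `f_both / (f_a * f_b)` tests
#' transcriptional independence in cis: it converges to 1 when the two genes
#' fire independently at a locus, and is reported as `NA` when the product of
#' marginals is 0. The nucleus-level fraction `f_nuclei_both` counts nuclei
#' with at least one A-active locus and at least one B-active locus (not
#' necessarily the same locus).
#'
#' @param observations `data.frame` with columns `nucleus_id`, `locus_index`
#'   (1 or 2), `state` (one of `none`, `a_only`, `b_only`, `both`); at most
#'   two loci per nucleus.
#' @return A `cooccurrence_stats`: list with `n_loci`, `f_a`, `f_b`,
#'   `f_both`, `product`, `ratio`, `n_nuclei`, `f_nuclei_both`.
#' @export
tabulate_cooccurrence <- function(observations) {
  .validate_loci(observations)
  a_active <- observations$state %in% c("a_only", "both")
  b_active <- observations$state %in% c("b_only", "both")
  n_loci <- nrow(observations)
  f_a <- mean(a_active)
  f_b <- mean(b_active)
  f_both <- mean(observations$state == "both")
  product <- f_a * f_b
  nuc_a <- tapply(a_active, observations$nucleus_id, any)
  nuc_b <- tapply(b_active, observations$nucleus_id, any)
  structure(list(
    n_loci = n_loci,
    f_a = f_a, f_b = f_b, f_both = f_both,
    product = product,
    ratio = if (product > 0) f_both / product else NA_real_,
    n_nuclei = length(nuc_a),
    f_nuclei_both = mean(nuc_a & nuc_b)
  ), class = "cooccurrence_stats")
}

#' @export
print.cooccurrence_stats <- function(x, ...) {
  cat(sprintf("cooccurrence_stats: %d loci in %d nuclei\n", x$n_loci, x$n_nuclei))
  cat(sprintf("  f_A %.4f, f_B %.4f, f_both %.4f vs product %.4f (ratio %s)\n",
              x$f_a, x$f_b, x$f_both, x$product,
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  cat(sprintf("  nuclei with both genes active: %.1f%%\n", 100 * x$f_nuclei_both))
  invisible(x)
}

#' Simulate transcription loci with independent two-gene activity
#'
#' Generates two loci per nucleus; at each locus gene A is active with
#' probability `p_a` and gene B independently with probability `p_b`. This is
#' the null model for the independence check in
#' [tabulate_cooccurrence()].
#'
#' @param n_nuclei Number of nuclei (each contributes 2 loci).
#' @param p_a,p_b Per-locus activity probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tidy `data.frame` of locus observations (`nucleus_id`,
#'   `locus_index`, `state`).
#' @export
simulate_independent_loci <- function(n_nuclei, p_a, p_b, seed) {
  stopifnot(n_nuclei >= 1, p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  n_loci <- 2L * as.integer(n_nuclei)
  withr::with_seed(seed, {
    a <- stats::runif(n_loci) < p_a
    b <- stats::runif(n_loci) < p_b
    data.frame(
      nucleus_id = rep(sprintf("nuc%06d", seq_len(n_nuclei)), each = 2),
      locus_index = rep(1:2, times = n_nuclei),
      state = ifelse(a & b, "both",
                     ifelse(a, "a_only", ifelse(b, "b_only", "none"))),
      stringsAsFactors = FALSE
    )
  })
}

#' Read a tidy locus-observation TSV
#'
#' @param path TSV with columns `nucleus_id`, `locus_index`, `state`.
#' @return Validated observations `data.frame`.
#' @export
read_locus_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_loci(df)
  df
}

#' Write locus observations to TSV
#'
#' @param observations Observations `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(observations, path) {
  .write_tsv(observations[, c("nucleus_id", "locus_index", "state")], path)
}
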