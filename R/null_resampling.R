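#' Null distribution of the mean coefficient of coexpression
#'
#' Repeats `n_iterations` times: draw `n_pairs` gene pairs with the requested
#' null sampler — random cross-chromosome pairs, or neighboring
#' opposite-orientation pairs (< 1 kb apart) — and record the mean coefficient
#' of coexpression over the sample. The gene universe for sampling is the
#' annotation gene set, not the expression table's gene list; genes absent
#' from the table contribute a coefficient of 0 through the empty-set
#' convention. Iteration `i` uses an RNG stream derived deterministically
#' from `(seed, i)` via [substream_seed()], so iterations are
#' order-independent and individually reproducible, and the whole
#' distribution is bit-reproducible given `(seed, n_pairs, n_iterations)`.
#'
#' @param sets An [binarize()] result.
#' @param genes A [gene_set()] defining the sampling universe.
#' @param null_class `"random"` or `"neighbor"`.
#' @param n_pairs Pairs drawn per iteration (the study design resamples as
#'   many pairs as there are nested pairs; 567 on the worm annotation).
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param seed Integer top-level seed.
#' @param max_gap_bp Gap bound for the neighbor sampler.
#' @return A `null_distribution`: list with `null_class`,
#'   `n_pairs_per_iteration`, `n_iterations`, `seed`, `dataset_label` and the
#'   `means` vector.
#' @export
null_mean_distribution <- function(sets, genes,
                                   null_class = c("random", "neighbor"),
                                   n_pairs, n_iterations = 1000, seed,
                                   max_gap_bp = 1000) {
  null_class <- match.arg(null_class)
  stopifnot(inherits(sets, "expressed_sets"), n_pairs >= 1, n_iterations >= 1)
  if (null_class == "random") {
    if (length(unique(genes$chrom)) < 2) {
      stop("random cross-chromosome pairs are infeasible: all genes lie on one chromosome")
    }
    draw <- function() .sample_random_core(genes, n_pairs)
  } else {
    adj <- .neighbor_adjacency(genes, max_gap_bp = max_gap_bp)
    if (is.null(adj)) {
      stop("neighbor pairs are infeasible: no opposite-orientation gene pairs closer than ",
           max_gap_bp, " bp")
    }
    draw <- function() .sample_neighbor_core(adj, n_pairs)
  }
  means <- vapply(seq_len(n_iterations), function(i) {
    pairs <- withr::with_seed(substream_seed(seed, i), draw())
    mean(.pair_counts(sets, pairs$gene_a_id, pairs$gene_b_id)$coefficient)
  }, numeric(1))
  structure(list(
    null_class = null_class,
    n_pairs_per_iteration = as.integer(n_pairs),
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed),
    dataset_label = sets$dataset_label,
    means = means
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s, '%s'): %d iterations x %d pairs, seed %d\n",
              x$null_class, x$dataset_label, x$n_iterations,
              x$n_pairs_per_iteration, x$seed))
  cat(sprintf("  mean of means %.4f (sd %.4f)\n", mean(x$means), stats::sd(x$means)))
  invisible(x)
}

#' Compare an observed mean coefficient against a null distribution
#'
#' @param observed_mean Observed mean coefficient of coexpression (e.g. over
#'   the nested pairs).
#' @param null A [null_mean_distribution()] result.
#' @param n_bins Number of equal-width histogram bins spanning the pooled
#'   range of the null means and the observed value (default 30).
#' @return A `null_comparison`: list with `observed_mean`,
#'   `empirical_quantile` (fraction of null means <= observed),
#'   `n_iterations`, `null_class`, `dataset_label` and a `histogram`
#'   `data.frame` (`bin_lower`, `bin_upper`, `count`) of the null means.
#' @export
compare_to_null <- function(observed_mean, null, n_bins = 30) {
  stopifnot(inherits(null, "null_distribution"), length(observed_mean) == 1,
            n_bins >= 1)
  means <- null$means
  rng <- range(c(means, observed_mean))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(findInterval(means, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  structure(list(
    observed_mean = observed_mean,
    empirical_quantile = mean(means <= observed_mean),
    n_iterations = null$n_iterations,
    null_class = null$null_class,
    dataset_label = null$dataset_label,
    histogram = data.frame(bin_lower = breaks[-length(breaks)],
                           bin_upper = breaks[-1],
                           count = counts)
  ), class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("null_comparison (%s, '%s'): observed mean %.4f at empirical quantile %.3f (%d iterations)\n",
              x$null_class, x$dataset_label, x$observed_mean,
              x$empirical_quantile, x$n_iterations))
  invisible(x)
}

#' Write a null distribution to TSV
#'
#' Columns `iteration`, `mean_coefficient`.
#'
#' @param null A [null_mean_distribution()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_null_tsv <- function(null, path) {
  .write_tsv(data.frame(iteration = seq_along(null$means),
                        mean_coefficient = null$means), path)
}
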