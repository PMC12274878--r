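# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's interval machinery (no GRanges): plain
# predicate scans over all ordered pairs, so they can certify the finders.

# O(n^2) scan with the containment predicate: same chromosome, nested span
# inside host span (boundaries included), spans not identical, strands opposite
oracle_nested_pairs <- function(genes) {
  n <- nrow(genes)
  out <- list()
  for (i in seq_len(n)) {
    contained <- genes$chrom == genes$chrom[i] &
      genes$start[i] <= genes$start & genes$end <= genes$end[i] &
      !(genes$start == genes$start[i] & genes$end == genes$end[i]) &
      genes$strand != genes$strand[i]
    contained[i] <- FALSE
    for (j in which(contained)) {
      out[[length(out) + 1L]] <- c(genes$gene_id[i], genes$gene_id[j])
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a_id = character(), gene_b_id = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(gene_a_id = m[, 1], gene_b_id = m[, 2],
                   stringsAsFactors = FALSE)
  df[order(df$gene_a_id, df$gene_b_id, method = "radix"), , drop = FALSE]
}

# O(n^2) scan with the neighbor predicate: same chromosome, non-overlapping,
# opposite strands, 0 <= gap < max_gap (gap = downstream start - upstream end - 1)
oracle_neighbor_pairs <- function(genes, max_gap = 1000) {
  n <- nrow(genes)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (genes$chrom[i] != genes$chrom[j]) next
      if (genes$strand[i] == genes$strand[j]) next
      up <- if (genes$start[i] <= genes$start[j]) i else j
      dn <- if (genes$start[i] <= genes$start[j]) j else i
      gap <- genes$start[dn] - genes$end[up] - 1L
      if (gap >= 0 && gap < max_gap) {
        out[[length(out) + 1L]] <- c(genes$gene_id[up], genes$gene_id[dn], gap)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a_id = character(), gene_b_id = character(),
                      gap_bp = integer(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(gene_a_id = m[, 1], gene_b_id = m[, 2],
                   gap_bp = as.integer(m[, 3]), stringsAsFactors = FALSE)
  df[order(df$gene_a_id, df$gene_b_id, method = "radix"), , drop = FALSE]
}

# normalize a finder/oracle pair table for comparison
pair_key <- function(df) {
  df <- df[order(df$gene_a_id, df$gene_b_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random gene set with arbitrary overlaps/containments for property tests
random_gene_set <- function(n_genes, n_chroms = 3, span = 50000,
                            max_len = 8000) {
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = sprintf("chr%d", sample.int(n_chroms, n_genes, replace = TRUE)),
    start = sample.int(span, n_genes, replace = TRUE),
    end = 0L, strand = sample(c("+", "-"), n_genes, replace = TRUE),
    biotype = "protein_coding", stringsAsFactors = FALSE
  ) -> df
  df$end <- df$start + sample.int(max_len, n_genes, replace = TRUE) - 1L
  gene_set(df, source = "synthetic")
}

# exact set-arithmetic oracle for one pair of expressed-cell-type sets
oracle_pair_stats <- function(set_a, set_b) {
  n_a <- length(set_a)
  n_b <- length(set_b)
  n_both <- length(intersect(set_a, set_b))
  n_either <- length(union(set_a, set_b))
  list(
    n_a = n_a, n_b = n_b, n_both = n_both, n_either = n_either,
    coefficient = if (n_either > 0) n_both / n_either else 0,
    p_host_given_nested = if (n_b > 0) n_both / n_b else NA_real_,
    p_nested_given_host = if (n_a > 0) n_both / n_a else NA_real_
  )
}

# builds an expressed_sets object from a named list of cell-type sets by
# round-tripping through an expression table (1 = expressed, 0 = silent)
sets_from_list <- function(sets_list, universe, dataset_label = "lineage") {
  m <- matrix(0, nrow = length(sets_list), ncol = length(universe),
              dimnames = list(names(sets_list), universe))
  for (g in names(sets_list)) m[g, sets_list[[g]]] <- 1
  binarize(expression_table(m, dataset_label = dataset_label))
}

# Monte-Carlo oracle (different RNG generator than the package's default):
# mean Jaccard coefficient of two independent Bernoulli(p1), Bernoulli(p2)
# genes over t_cells cell types, zero-denominator rule applied
mc_jaccard_independent <- function(p1, p2, t_cells, reps, seed) {
  withr::with_seed(seed, .rng_kind = "Wichmann-Hill", {
    vals <- vapply(seq_len(reps), function(i) {
      a <- stats::runif(t_cells) < p1
      b <- stats::runif(t_cells) < p2
      either <- sum(a | b)
      if (either > 0) sum(a & b) / either else 0
    }, numeric(1))
    c(mean = mean(vals), se = stats::sd(vals) / sqrt(reps))
  })
}

# standard error of a statistic of locus observations, from k equal chunks
chunked_se <- function(values_per_chunk) {
  stats::sd(values_per_chunk) / sqrt(length(values_per_chunk))
}

# ratio f_both / (f_a * f_b) recomputed per chunk of a locus table
chunk_ratios <- function(obs, k = 50) {
  idx <- rep(seq_len(k), length.out = nrow(obs))
  vapply(seq_len(k), function(i) {
    s <- obs$state[idx == i]
    fa <- mean(s %in% c("a_only", "both"))
    fb <- mean(s %in% c("b_only", "both"))
    mean(s == "both") / (fa * fb)
  }, numeric(1))
}

# writes a toy GFF3 file and returns its path
write_toy_gff3 <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff3_gene_line <- function(chrom, start, end, strand, id,
                           biotype = "protein_coding",
                           attrs = sprintf("ID=%s;biotype=%s", id, biotype)) {
  paste(chrom, "toy", "gene", start, end, ".", strand, ".", attrs, sep = "\t")
}
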