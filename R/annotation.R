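#' Construct a validated gene set
#'
#' A gene set is a `data.frame` with one row per gene and columns `gene_id`,
#' `chrom`, `start`, `end`, `strand`, `biotype`; coordinates are 1-based and
#' inclusive, as in GFF3. Containment and distance predicates throughout the
#' package operate on these whole-gene spans.
#'
#' @param records `data.frame` with the six columns above.
#' @param source Provenance string (file path or `"synthetic"`).
#' @return The validated `data.frame` with class `gene_set` and a `source`
#'   attribute.
#' @export
gene_set <- function(records, source = "unknown") {
  required <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("gene set is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, required]
  records$gene_id <- as.character(records$gene_id)
  records$chrom <- as.character(records$chrom)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$strand <- as.character(records$strand)
  records$biotype <- as.character(records$biotype)
  if (nrow(records) > 0) {
    if (anyNA(records$start) || anyNA(records$end) || any(records$start < 1)) {
      stop("gene coordinates must be integers >= 1")
    }
    if (any(records$end < records$start)) {
      bad <- records$gene_id[records$end < records$start][1]
      stop("gene '", bad, "' has end < start")
    }
    if (!all(records$strand %in% c("+", "-"))) {
      bad <- records$gene_id[!records$strand %in% c("+", "-")][1]
      stop("gene '", bad, "' has strand outside {+, -}")
    }
    dup <- records$gene_id[duplicated(records$gene_id)]
    if (length(dup) > 0) {
      stop("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", "))
    }
  }
  rownames(records) <- NULL
  structure(records, class = c("gene_set", "data.frame"), source = source)
}

# gene_set -> GRanges (strand preserved); used by the interval machinery
.as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
}

.empty_gene_set <- function(source = "unknown") {
  gene_set(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      stringsAsFactors = FALSE),
           source = source)
}

#' Parse gene-level features from a GFF3 annotation
#'
#' Reads gene features (`type == "gene"`) from a GFF3 file and returns one
#' record per gene matching the requested biotype, using the gene feature's
#' own coordinates. Features without a usable strand (`+` or `-`) or without
#' a biotype attribute are skipped with a single warning reporting how many
#' were dropped.
#'
#' @param path Path to a GFF3 file (`.gz` accepted).
#' @param biotype_filter Biotype to retain (default `"protein_coding"`).
#' @param feature_type GFF3 feature type selecting gene rows.
#' @param biotype_attrs Attribute names checked (in order) for the biotype;
#'   the first attribute present in the file is used.
#' @param id_attrs Attribute names checked (in order) for the gene identifier.
#' @return A [gene_set()] whose `source` attribute is `path`. The number of
#'   skipped gene features is available as attribute `n_skipped`.
#' @export
parse_gene_annotation <- function(path,
                                  biotype_filter = "protein_coding",
                                  feature_type = "gene",
                                  biotype_attrs = c("biotype", "gene_biotype"),
                                  id_attrs = c("gene_id", "ID", "Name")) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      # distinguish a file with no feature lines (valid, empty annotation)
      # from genuinely malformed content
      lines <- tryCatch(readLines(path, warn = FALSE), error = function(e2) NULL)
      if (!is.null(lines)) {
        body <- lines[!grepl("^\\s*(#|$)", lines)]
        if (length(body) == 0) return(NULL)
      }
      stop("GFF3 parse error in '", path, "': ", conditionMessage(e))
    }
  )
  if (is.null(gr) || length(gr) == 0) return(.empty_gene_set(source = path))

  meta <- as.data.frame(S4Vectors::mcols(gr))
  is_gene <- !is.na(meta$type) & as.character(meta$type) == feature_type
  gr <- gr[is_gene]
  meta <- meta[is_gene, , drop = FALSE]
  if (length(gr) == 0) return(.empty_gene_set(source = path))

  id_col <- intersect(id_attrs, names(meta))
  if (length(id_col) == 0) {
    stop("no gene identifier attribute found (looked for: ",
         paste(id_attrs, collapse = ", "), ")")
  }
  gene_id <- as.character(meta[[id_col[1]]])

  bio_col <- intersect(biotype_attrs, names(meta))
  biotype <- if (length(bio_col) > 0) as.character(meta[[bio_col[1]]]) else
    rep(NA_character_, length(gr))

  strand <- as.character(GenomicRanges::strand(gr))
  usable <- strand %in% c("+", "-") & !is.na(biotype) & !is.na(gene_id)
  n_skipped <- sum(!usable)
  if (n_skipped > 0) {
    warning(n_skipped, " gene feature(s) skipped (missing strand or biotype)")
  }

  keep <- usable & biotype == biotype_filter
  gs <- gene_set(data.frame(
    gene_id = gene_id[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = strand[keep],
    biotype = biotype[keep],
    stringsAsFactors = FALSE
  ), source = path)
  attr(gs, "n_skipped") <- n_skipped
  gs
}

.gene_pairs <- function(gene_a_id = character(), gene_b_id = character(),
                        pair_class = character(), gap_bp = NA_integer_) {
  n <- length(gene_a_id)
  data.frame(
    gene_a_id = as.character(gene_a_id),
    gene_b_id = as.character(gene_b_id),
    pair_class = rep_len(as.character(pair_class), n),
    gap_bp = rep_len(as.integer(gap_bp), n),
    stringsAsFactors = FALSE
  )
}

#' Find opposite nested gene pairs
#'
#' A pair (host, nested) qualifies when both genes lie on the same chromosome,
#' the nested gene's span is entirely contained in the host's span
#' (`host$start <= nested$start` and `nested$end <= host$end`, boundaries
#' included), the two spans are not identical, and the strands are opposite.
#' Every qualifying ordered containment is reported once, so a gene can be
#' host of several nested genes, nested in several hosts, and both host and
#' nested along a containment chain.
#'
#' @param genes A [gene_set()].
#' @return `data.frame` of pairs with columns `gene_a_id` (host), `gene_b_id`
#'   (nested), `pair_class = "nested"` and `gap_bp = NA`, sorted by
#'   (chromosome, host start, nested start).
#' @export
find_nested_pairs <- function(genes) {
  if (nrow(genes) == 0) return(.gene_pairs(pair_class = "nested"))
  gr <- .as_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr, gr, type = "within",
                                      ignore.strand = TRUE)
  nested_i <- S4Vectors::queryHits(hits)
  host_i <- S4Vectors::subjectHits(hits)
  keep <- nested_i != host_i &
    genes$strand[nested_i] != genes$strand[host_i] &
    !(genes$start[nested_i] == genes$start[host_i] &
        genes$end[nested_i] == genes$end[host_i])
  nested_i <- nested_i[keep]
  host_i <- host_i[keep]
  ord <- order(genes$chrom[host_i], genes$start[host_i], genes$start[nested_i],
               genes$gene_id[host_i], genes$gene_id[nested_i], method = "radix")
  .gene_pairs(genes$gene_id[host_i][ord], genes$gene_id[nested_i][ord],
              pair_class = "nested")
}

#' Find neighboring opposite-orientation gene pair candidates
#'
#' Enumerates all pairs on the same chromosome with non-overlapping spans,
#' opposite strands, and an intergenic gap (`downstream$start - upstream$end
#' - 1` on 1-based inclusive coordinates) of at least 0 and strictly less
#' than `max_gap_bp`. Abutting genes (gap 0) qualify; any overlap, including
#' nesting, disqualifies. Both divergent (head-to-head) and convergent
#' (tail-to-tail) orientations are accepted.
#'
#' @param genes A [gene_set()].
#' @param max_gap_bp Exclusive upper bound on the intergenic gap in bases
#'   (default 1000, i.e. "less than 1 kb").
#' @return `data.frame` of pairs with `gene_a_id` the upstream gene,
#'   `gene_b_id` the downstream gene, `pair_class = "neighbor"` and the
#'   recorded `gap_bp`, sorted by (chromosome, upstream start, downstream
#'   start).
#' @export
find_neighbor_candidates <- function(genes, max_gap_bp = 1000) {
  if (length(max_gap_bp) != 1 || !is.finite(max_gap_bp) || max_gap_bp <= 0) {
    stop("max_gap_bp must be a positive integer")
  }
  if (nrow(genes) < 2) return(.gene_pairs(pair_class = "neighbor"))
  gr <- .as_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr, gr, maxgap = max_gap_bp - 1,
                                      ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  keep <- i < j # each unordered pair once
  i <- i[keep]; j <- j[keep]
  # orient: upstream gene = smaller start (non-overlap implies distinct starts)
  up <- ifelse(genes$start[i] <= genes$start[j], i, j)
  dn <- ifelse(genes$start[i] <= genes$start[j], j, i)
  gap <- genes$start[dn] - genes$end[up] - 1L
  ok <- gap >= 0L & gap < max_gap_bp & genes$strand[up] != genes$strand[dn]
  up <- up[ok]; dn <- dn[ok]; gap <- gap[ok]
  ord <- order(genes$chrom[up], genes$start[up], genes$start[dn],
               genes$gene_id[up], genes$gene_id[dn], method = "radix")
  .gene_pairs(genes$gene_id[up][ord], genes$gene_id[dn][ord],
              pair_class = "neighbor", gap_bp = gap[ord])
}

# --- samplers ---------------------------------------------------------------
# RNG-consuming cores are factored out so that iterated resampling
# (null_mean_distribution) and the one-shot public samplers draw identical
# pair sequences from identical seeds.

.sample_random_core <- function(genes, n_pairs) {
  n <- nrow(genes)
  chrom <- genes$chrom
  a <- sample.int(n, n_pairs, replace = TRUE)
  b <- integer(n_pairs)
  todo <- seq_len(n_pairs)
  while (length(todo) > 0) { # rejection sampling: uniform over other chromosomes
    cand <- sample.int(n, length(todo), replace = TRUE)
    ok <- chrom[cand] != chrom[a[todo]]
    b[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  .gene_pairs(genes$gene_id[a], genes$gene_id[b], pair_class = "random")
}

# adjacency of neighbor candidates: for every eligible gene, the vector of
# qualifying partners (both directions of each candidate pair)
.neighbor_adjacency <- function(genes, max_gap_bp = 1000) {
  cand <- find_neighbor_candidates(genes, max_gap_bp = max_gap_bp)
  if (nrow(cand) == 0) return(NULL)
  edges <- data.frame(
    gene = c(cand$gene_a_id, cand$gene_b_id),
    partner = c(cand$gene_b_id, cand$gene_a_id),
    gap_bp = c(cand$gap_bp, cand$gap_bp),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene, edges$partner, method = "radix"), ]
  list(
    eligible = sort(unique(edges$gene)),
    partners = split(edges$partner, edges$gene),
    gaps = split(edges$gap_bp, edges$gene)
  )
}

.sample_neighbor_core <- function(adj, n_pairs) {
  g <- sample(adj$eligible, n_pairs, replace = TRUE)
  counts <- vapply(adj$partners[g], length, integer(1))
  # uniform partner index via runif keeps the draw vectorized
  k <- pmin(floor(stats::runif(n_pairs) * counts) + 1L, counts)
  partner <- mapply(function(p, idx) p[idx], adj$partners[g], k,
                    USE.NAMES = FALSE)
  gap <- mapply(function(gp, idx) gp[idx], adj$gaps[g], k, USE.NAMES = FALSE)
  .gene_pairs(g, partner, pair_class = "neighbor", gap_bp = gap)
}

#' Sample random cross-chromosome gene pairs
#'
#' Each pair is drawn independently (genes may recur across pairs): gene A
#' uniformly from all genes, then gene B uniformly from the genes not on A's
#' chromosome.
#'
#' @param genes A [gene_set()] spanning at least two chromosomes.
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed; identical seeds give identical pair lists.
#' @return `data.frame` of `n_pairs` pairs with `pair_class = "random"`.
#' @export
sample_random_pairs <- function(genes, n_pairs, seed) {
  stopifnot(n_pairs >= 1)
  if (length(unique(genes$chrom)) < 2) {
    stop("random cross-chromosome pairs are infeasible: all genes lie on one chromosome")
  }
  withr::with_seed(seed, .sample_random_core(genes, n_pairs))
}

#' Sample neighboring opposite-orientation gene pairs
#'
#' Each draw picks a gene uniformly among genes having at least one qualifying
#' neighbor (opposite strand, non-overlapping, gap below `max_gap_bp`), then a
#' qualifying partner of that gene uniformly. Genes may recur across draws.
#'
#' @inheritParams sample_random_pairs
#' @param max_gap_bp Exclusive gap bound passed to [find_neighbor_candidates()].
#' @return `data.frame` of `n_pairs` pairs with `pair_class = "neighbor"` and
#'   the pair's `gap_bp`.
#' @export
sample_neighbor_pairs <- function(genes, n_pairs, seed, max_gap_bp = 1000) {
  stopifnot(n_pairs >= 1)
  adj <- .neighbor_adjacency(genes, max_gap_bp = max_gap_bp)
  if (is.null(adj)) {
    stop("neighbor pairs are infeasible: no opposite-orientation gene pairs closer than ",
         max_gap_bp, " bp")
  }
  withr::with_seed(seed, .sample_neighbor_core(adj, n_pairs))
}

#' Write gene pairs (with coordinates) to TSV
#'
#' @param pairs Pair `data.frame` from the finders or samplers.
#' @param genes The [gene_set()] supplying coordinates.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, genes, path) {
  ia <- match(pairs$gene_a_id, genes$gene_id)
  ib <- match(pairs$gene_b_id, genes$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pairs reference gene_ids absent from the gene set")
  out <- data.frame(
    gene_a_id = pairs$gene_a_id, gene_b_id = pairs$gene_b_id,
    pair_class = pairs$pair_class,
    chrom_a = genes$chrom[ia], start_a = genes$start[ia],
    end_a = genes$end[ia], strand_a = genes$strand[ia],
    chrom_b = genes$chrom[ib], start_b = genes$start[ib],
    end_b = genes$end[ib], strand_b = genes$strand[ib],
    gap_bp = pairs$gap_bp,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Read a gene-pair TSV written by [write_pairs_tsv()]
#'
#' @param path TSV path.
#' @return Pair `data.frame` with columns `gene_a_id`, `gene_b_id`,
#'   `pair_class`, `gap_bp`.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .gene_pairs(df$gene_a_id, df$gene_b_id, df$pair_class,
              gap_bp = df$gap_bp %||% NA_integer_)
}
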