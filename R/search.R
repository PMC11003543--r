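# Internal homology search: exact k-mer seeding, diagonal clustering and
# banded affine-gap extension, dc-megablast-like scoring (match +2,
# mismatch -3, gap open -5, gap extend -2). A gap of length L costs
# open + L * extend. Identity is matches / alignment columns (gap columns
# included); coverage is always coverage of the query.

#' Search engine scoring and seeding parameters
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores. `gap_open`
#'   and `gap_extend` are positive costs.
#' @param k seed k-mer size.
#' @param pad diagonal band padding around seed clusters, bp.
#' @param max_seed_gap split seed clusters whose subject positions jump more
#'   than this (bp); defaults to the query length at call time when `NA`.
#' @param min_score minimum alignment score for a reported hit.
#' @param min_seeds minimum k-mer seeds per cluster before a banded
#'   extension is attempted; 2 suppresses chance single-seed matches against
#'   unrelated sequence.
#' @return list of engine parameters.
#' @export
engine_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L, k = 11L, pad = 40L,
                          max_seed_gap = NA_integer_, min_score = 30L,
                          min_seeds = 2L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       k = as.integer(k), pad = as.integer(pad),
       max_seed_gap = as.integer(max_seed_gap),
       min_score = as.integer(min_score),
       min_seeds = as.integer(min_seeds))
}

#' Reverse complement of a nucleotide string
#' @param s nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) cpp_revcomp(s)

# raw engine call on one (query, subject) pair, plus strand only
engine_hits_raw <- function(query, subject, ep) {
  gap <- if (is.na(ep$max_seed_gap)) max(nchar(query), 200L) else ep$max_seed_gap
  cpp_find_hits(query, subject, ep$k, ep$pad, ep$match, ep$mismatch,
                ep$gap_open, ep$gap_extend, as.integer(gap), ep$min_score,
                ep$min_seeds)
}

# both-strand engine search of query against a single subject string;
# q coordinates reported in the original query orientation
engine_hits <- function(query, subject, ep = engine_params()) {
  qlen <- nchar(query)
  fw <- engine_hits_raw(query, subject, ep)
  fw$strand <- rep("+", nrow(fw))
  rv <- engine_hits_raw(cpp_revcomp(query), subject, ep)
  if (nrow(rv) > 0) {
    qs <- qlen - rv$q_end
    rv$q_end <- qlen - rv$q_start
    rv$q_start <- qs
  }
  rv$strand <- rep("-", nrow(rv))
  hits <- rbind(fw, rv)
  if (nrow(hits) > 0) {
    hits$identity <- hits$matches / hits$columns
    hits$query_coverage <- (hits$q_end - hits$q_start) / qlen
  } else {
    hits$identity <- numeric(0)
    hits$query_coverage <- numeric(0)
  }
  hits
}

# keep the best-scoring hit per subject locus: hits whose subject intervals
# overlap by more than half of the shorter hit are considered the same locus
collapse_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(-hits$score, -(hits$s_end - hits$s_start)), , drop = FALSE]
  s1 <- hits$s_start; s2 <- hits$s_end
  keep_idx <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(keep_idx) > 0) {
      ov <- pmin(s2[keep_idx], s2[i]) - pmax(s1[keep_idx], s1[i])
      shorter <- pmin(s2[keep_idx] - s1[keep_idx], s2[i] - s1[i])
      if (any(ov > 0.5 * shorter)) next
    }
    keep_idx <- c(keep_idx, i)
  }
  hits[keep_idx, , drop = FALSE]
}

#' Find genomic copies of a query sequence
#'
#' Seeded banded local alignment of `query` against every contig on both
#' strands. Hits below `min_identity` or `min_coverage` are dropped,
#' overlapping hits at the same locus are collapsed to the best-scoring one,
#' and the result is sorted by descending score. Subject coordinates always
#' satisfy `s_start < s_end`; strand is carried separately.
#'
#' @param query nucleotide string.
#' @param genome a `GenomeAssembly` (see [prepare_genome()]).
#' @param min_identity minimum identity (matches / alignment columns).
#' @param min_coverage minimum query coverage (aligned query bases / query
#'   length).
#' @param ep engine parameters, see [engine_params()].
#' @return data frame of search hits with columns `query_id`, `contig`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `strand`, `identity`,
#'   `query_coverage`, `score` plus alignment tallies (`matches`, `columns`,
#'   `pairs`, `ts`, `tv`).
#' @export
find_hits <- function(query, genome, min_identity = 0.6, min_coverage = 0.25,
                      ep = engine_params()) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  if (nchar(query) < ep$k) {
    warning("query shorter than seed size; returning no hits")
    return(empty_hits())
  }
  out <- lapply(names(genome$contigs), function(ctg) {
    hits <- engine_hits(query, genome$contigs[[ctg]], ep)
    if (nrow(hits) == 0) return(NULL)
    hits$contig <- ctg
    hits
  })
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  hits <- hits[hits$identity >= min_identity &
                 hits$query_coverage >= min_coverage, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits <- do.call(rbind, lapply(split(hits, hits$contig), collapse_hits))
  hits <- hits[order(-hits$score), , drop = FALSE]
  hits$query_id <- "query"
  rownames(hits) <- NULL
  hits[, c("query_id", "contig", "q_start", "q_end", "s_start", "s_end",
           "strand", "identity", "query_coverage", "score", "matches",
           "columns", "pairs", "ts", "tv")]
}

empty_hits <- function() {
  data.frame(query_id = character(), contig = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), identity = numeric(),
             query_coverage = numeric(), score = numeric(),
             matches = integer(), columns = integer(), pairs = integer(),
             ts = integer(), tv = integer(), stringsAsFactors = FALSE)
}

#' Optimal local pairwise alignment
#'
#' Full Smith-Waterman alignment under the engine's scoring, run on both
#' orientations of `b`; the better-scoring orientation is reported. With no
#' positive-scoring alignment, identity and coverage are 0.
#'
#' @param a,b nucleotide strings; coverage is reported for `a`.
#' @param ep engine parameters.
#' @return list with `aligned_a`, `aligned_b`, `identity`, `coverage_of_a`,
#'   `score`, `strand`, coordinates (`a_start`, `a_end`, `b_start`, `b_end`;
#'   half-open, on the input orientation of each sequence) and tallies
#'   (`matches`, `columns`, `pairs`, `ts`, `tv`).
#' @export
pairwise_align <- function(a, b, ep = engine_params()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  n <- nchar(a); m <- nchar(b)
  if ((n + 1) * (n + m + 1) > 6e8)
    stop("pairwise_align: sequences too long for full alignment; use find_hits")
  fw <- cpp_align(a, b, -n, m, TRUE, ep$match, ep$mismatch,
                  ep$gap_open, ep$gap_extend, TRUE)
  rv <- cpp_align(a, cpp_revcomp(b), -n, m, TRUE, ep$match, ep$mismatch,
                  ep$gap_open, ep$gap_extend, TRUE)
  use_rv <- rv$found && (!fw$found || rv$score > fw$score)
  r <- if (use_rv) rv else fw
  if (!r$found)
    return(list(aligned_a = "", aligned_b = "", identity = 0,
                coverage_of_a = 0, score = 0, strand = "+",
                a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                matches = 0L, columns = 0L, pairs = 0L, ts = 0L, tv = 0L))
  b_start <- r$b_start; b_end <- r$b_end
  if (use_rv) { b_start <- m - r$b_end; b_end <- m - r$b_start }
  list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
       identity = r$matches / r$columns,
       coverage_of_a = (r$a_end - r$a_start) / n,
       score = r$score, strand = if (use_rv) "-" else "+",
       a_start = r$a_start, a_end = r$a_end,
       b_start = b_start, b_end = b_end,
       matches = r$matches, columns = r$columns, pairs = r$pairs,
       ts = r$ts, tv = r$tv)
}

# free-end-gap global alignment; returns full-length padded aligned strings.
# The DP band is centred on the diagonals of the seeded local hits when any
# exist (the expected case for homologous inputs), else spans the whole
# length difference.
glocal_align <- function(a, b, band = NULL, ep = engine_params()) {
  n <- nchar(a); m <- nchar(b)
  pad <- if (is.null(band)) 150L else band
  seeds <- if (n >= ep$k && m >= ep$k) engine_hits_raw(a, b, ep) else
    data.frame()
  if (nrow(seeds) > 0) {
    d <- c(seeds$s_start - seeds$q_start, seeds$s_end - seeds$q_end)
    dlo <- min(d, 0L, m - n) - pad
    dhi <- max(d, 0L, m - n) + pad
  } else {
    dlo <- min(0L, m - n) - pad
    dhi <- max(0L, m - n) + pad
  }
  cpp_align(a, b, dlo, dhi, FALSE, ep$match, ep$mismatch,
            ep$gap_open, ep$gap_extend, TRUE)
}
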