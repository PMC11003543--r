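# Iterative consensus extension: find genomic copies of a consensus, extend
# their flanks, keep only extension sequence supported by at least one other
# copy, rebuild the consensus by majority rule, and repeat until the
# consensus stops growing or quality drops.

#' Parameters for iterative consensus extension
#'
#' @param flank bp added to each side of every selected copy per iteration.
#' @param max_iterations hard cap on curation rounds.
#' @param max_candidates copies used for consensus construction.
#' @param candidate_min_identity,candidate_min_coverage strict lower bounds
#'   for a genomic copy to be used (identity > 0.70, query coverage > 0.50).
#' @param min_matches fewer validated copies than this halts curation (the
#'   iteration's starting consensus is kept).
#' @param accept_min_coverage_of_prev a new consensus covering less than this
#'   fraction of the previous one is a quality reduction (revert).
#' @param done_fraction_of_flank growth below this fraction of `flank` means
#'   the consensus is complete.
#' @param seed integer seed for any stochastic tie sampling (none by default).
#' @return list of parameters.
#' @export
beat_params <- function(flank = 1000L, max_iterations = 10L,
                        max_candidates = 20L,
                        candidate_min_identity = 0.70,
                        candidate_min_coverage = 0.50,
                        min_matches = 3L,
                        accept_min_coverage_of_prev = 0.80,
                        done_fraction_of_flank = 0.50,
                        seed = 1L) {
  stopifnot(flank > 0, max_iterations >= 1, min_matches >= 1)
  list(flank = as.integer(flank), max_iterations = as.integer(max_iterations),
       max_candidates = as.integer(max_candidates),
       candidate_min_identity = candidate_min_identity,
       candidate_min_coverage = candidate_min_coverage,
       min_matches = as.integer(min_matches),
       accept_min_coverage_of_prev = accept_min_coverage_of_prev,
       done_fraction_of_flank = done_fraction_of_flank,
       seed = as.integer(seed))
}

#' Select candidate copies for consensus construction
#'
#' Keeps hits with identity strictly above 0.70 and query coverage strictly
#' above 0.50, then the top `max_candidates` by score. Fewer than
#' `min_matches` surviving hits signals a low-copy family.
#'
#' @param hits data frame from [find_hits()].
#' @param params [beat_params()].
#' @return list with `hits` (selected rows) and `low_copy` (logical).
#' @export
select_candidates <- function(hits, params = beat_params()) {
  keep <- hits[hits$identity > params$candidate_min_identity &
                 hits$query_coverage > params$candidate_min_coverage, ,
               drop = FALSE]
  keep <- keep[order(-keep$score), , drop = FALSE]
  keep <- head(keep, params$max_candidates)
  list(hits = keep, low_copy = nrow(keep) < params$min_matches)
}

#' Extract copies with extended flanks
#'
#' Each hit is extracted as `[s_start - flank, s_end + flank)`, clamped to
#' the contig; minus-strand hits are reverse-complemented so every extract is
#' in query orientation. The position of the original (core) hit inside each
#' extract is recorded in attributes `core_start`/`core_end`.
#'
#' @param genome a `GenomeAssembly`.
#' @param hits selected hits.
#' @param flank bp to add on each side.
#' @return list of extract strings with core-span attributes.
#' @export
extend_flanks <- function(genome, hits, flank = 1000L) {
  lapply(seq_len(nrow(hits)), function(i) {
    ctg <- genome$contigs[[hits$contig[i]]]
    clen <- nchar(ctg)
    a <- max(0L, hits$s_start[i] - flank)
    b <- min(clen, hits$s_end[i] + flank)
    s <- substr(ctg, a + 1L, b)
    left <- hits$s_start[i] - a
    right <- b - hits$s_end[i]
    core_len <- hits$s_end[i] - hits$s_start[i]
    if (hits$strand[i] == "-") {
      s <- cpp_revcomp(s)
      cs <- right
    } else cs <- left
    attr(s, "core_start") <- cs
    attr(s, "core_end") <- cs + core_len
    s
  })
}

#' Validate extended copies against the initial consensus
#'
#' Each extract must align to the round-0 consensus with identity > 0.70 and
#' coverage of the consensus > 0.50; this guards against the extension
#' locking onto a more abundant repeat neighbouring a genuine copy.
#'
#' @param extended list of extracts from [extend_flanks()].
#' @param initial_consensus the round-0 consensus sequence.
#' @param params [beat_params()].
#' @param ep engine parameters.
#' @return the retained extracts.
#' @export
validate_extended <- function(extended, initial_consensus,
                              params = beat_params(), ep = engine_params()) {
  keep <- vapply(extended, function(s) {
    h <- engine_hits(initial_consensus, as.character(s), ep)
    if (nrow(h) == 0) return(FALSE)
    # coverage of the consensus: union of aligned consensus bases
    cov <- covered_fraction(h$q_start, h$q_end, nchar(initial_consensus))
    best <- h[which.max(h$score), ]
    best$identity > params$candidate_min_identity &&
      cov > params$candidate_min_coverage
  }, logical(1))
  extended[keep]
}

covered_fraction <- function(starts, ends, len) {
  if (length(starts) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
  sum(IRanges::width(ir)) / len
}

#' Trim extended copies to mutually supported sequence
#'
#' Flank positions of each extract covered by at least one local alignment to
#' another extract are kept; unsupported flank tails are removed. The core
#' (pre-extension) span is never trimmed. Support must be contiguous with the
#' core (alignment intervals are merged across gaps of at most `merge_gap`
#' bp and the crop is the merged block containing the core), and alignments
#' below `support_min_score` are ignored: both guards keep chance
#' micro-alignments between unrelated host flanks from rescuing a flank tail.
#'
#' @param extended list of extracts with core-span attributes.
#' @param ep engine parameters.
#' @param support_min_score minimum alignment score for flank support.
#' @param merge_gap largest unsupported gap bridged when extending past the
#'   core, bp.
#' @return list of trimmed strings.
#' @export
trim_to_mutual_support <- function(extended, ep = engine_params(),
                                   support_min_score = 45L,
                                   merge_gap = 100L) {
  n <- length(extended)
  if (n < 2) {
    warning("trim_to_mutual_support: fewer than 2 sequences; unchanged")
    return(extended)
  }
  support <- replicate(n, list(lo = integer(0), hi = integer(0)),
                       simplify = FALSE)
  note <- function(i, lo, hi) {
    support[[i]]$lo <<- c(support[[i]]$lo, lo)
    support[[i]]$hi <<- c(support[[i]]$hi, hi)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- engine_hits(as.character(extended[[i]]),
                       as.character(extended[[j]]), ep)
      h <- h[h$score >= support_min_score, , drop = FALSE]
      if (nrow(h) == 0) next
      for (t in seq_len(nrow(h))) {
        note(i, h$q_start[t], h$q_end[t])
        note(j, h$s_start[t], h$s_end[t])
      }
    }
  }
  lapply(seq_len(n), function(i) {
    s <- extended[[i]]
    cs <- attr(s, "core_start"); ce <- attr(s, "core_end")
    lo <- c(support[[i]]$lo, cs)
    hi <- c(support[[i]]$hi, ce)
    ord <- order(lo, hi)
    lo <- lo[ord]; hi <- hi[ord]
    # merge intervals across small gaps, then take the block holding the core
    blo <- lo[1]; bhi <- hi[1]
    blocks_lo <- integer(0); blocks_hi <- integer(0)
    for (t in seq_along(lo)[-1]) {
      if (lo[t] - bhi <= merge_gap) bhi <- max(bhi, hi[t])
      else {
        blocks_lo <- c(blocks_lo, blo); blocks_hi <- c(blocks_hi, bhi)
        blo <- lo[t]; bhi <- hi[t]
      }
    }
    blocks_lo <- c(blocks_lo, blo); blocks_hi <- c(blocks_hi, bhi)
    b <- which(blocks_lo <= cs & blocks_hi >= ce)[1]
    out <- substr(as.character(s), blocks_lo[b] + 1L, blocks_hi[b])
    attr(out, "core_start") <- cs - blocks_lo[b]
    attr(out, "core_end") <- ce - blocks_lo[b]
    out
  })
}

# ---- multiple alignment and majority-rule consensus ------------------------

# centre-star MSA: align every sequence to the longest one with free-end-gap
# banded alignment and merge insertions; returns equal-length padded rows
center_star_msa <- function(seqs, ep = engine_params()) {
  n <- length(seqs)
  stopifnot(n >= 2)
  lens <- vapply(seqs, nchar, integer(1))
  center <- which.max(lens)
  C <- seqs[[center]]
  L <- nchar(C)
  others <- setdiff(seq_len(n), center)
  # per row: characters at centre positions 1..L, and insertion strings
  # before centre position j (1..L+1, index L+1 = after the last base)
  row_base <- vector("list", n)
  row_ins <- vector("list", n)
  ins_len <- integer(L + 1)
  for (i in others) {
    al <- glocal_align(C, seqs[[i]], ep = ep)
    ac <- strsplit(al$aligned_a, "")[[1]]
    as_ <- strsplit(al$aligned_b, "")[[1]]
    is_base <- ac != "-"
    cpos <- cumsum(is_base)          # centre position of each column
    base <- character(L)
    base[cpos[is_base]] <- as_[is_base]
    ins <- character(L + 1)
    if (any(!is_base)) {
      gaps <- which(!is_base)
      pieces <- vapply(split(as_[gaps], cpos[gaps]), paste,
                       character(1), collapse = "")
      ins[as.integer(names(pieces)) + 1L] <- pieces
    }
    row_base[[i]] <- base
    row_ins[[i]] <- ins
    ins_len <- pmax(ins_len, nchar(ins))
  }
  row_base[[center]] <- strsplit(C, "")[[1]]
  row_ins[[center]] <- character(L + 1)
  rows <- vapply(seq_len(n), function(i) {
    ins <- row_ins[[i]]
    pad <- strrep("-", ins_len - nchar(ins))
    base <- row_base[[i]]
    base[base == "" | is.na(base)] <- "-"
    paste(paste0(ins, pad, c(base, "")), collapse = "")
  }, character(1))
  rows
}

msa_matrix <- function(rows) {
  do.call(rbind, strsplit(rows, ""))
}

majority_consensus <- function(mat, min_occupancy = 2L) {
  # per-column plurality of non-gap symbols; ties broken A < C < G < T;
  # N is non-gap but never wins over a concrete base
  bases <- c("A", "C", "G", "T")
  counts <- vapply(c(bases, "N"), function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1)
  occ <- rowSums(counts)
  keep <- occ >= min_occupancy
  if (!any(keep)) return("")
  counts <- counts[keep, , drop = FALSE]
  winner <- bases[max.col(counts[, bases, drop = FALSE], ties.method = "first")]
  winner[rowSums(counts[, bases, drop = FALSE]) == 0] <- "N"
  paste(winner, collapse = "")
}

#' Build a majority-rule consensus from trimmed copies
#'
#' Builds a multiple alignment of the trimmed extracts plus the starting
#' consensus, removes columns containing exactly one non-gap symbol, removes
#' the starting-consensus row, realigns the remaining rows, and emits the
#' per-column plurality base; columns with fewer than two non-gap symbols
#' emit nothing. Ties are broken in fixed base order A < C < G < T; `N` is
#' non-gap but never a majority winner over a concrete base.
#'
#' @param sequences list/vector of trimmed copy sequences (>= 2).
#' @param starting_consensus the current iteration's starting consensus.
#' @param ep engine parameters.
#' @return the new consensus string.
#' @export
build_consensus <- function(sequences, starting_consensus,
                            ep = engine_params()) {
  sequences <- vapply(sequences, as.character, character(1))
  if (length(sequences) < 2)
    stop("build_consensus: need at least 2 sequences besides the start")
  rows <- center_star_msa(c(list(starting_consensus), as.list(sequences)),
                          ep = ep)
  mat <- msa_matrix(rows)
  occ <- colSums(mat != "-")
  mat <- mat[, occ != 1L, drop = FALSE]   # single-nucleotide columns removed
  mat <- mat[-1L, , drop = FALSE]         # drop the starting consensus row
  stripped <- apply(mat, 1L, function(r) paste(r[r != "-"], collapse = ""))
  stripped <- stripped[nchar(stripped) > 0]
  if (length(stripped) < 2)
    stop("build_consensus: degenerate family after column filtering")
  rows2 <- center_star_msa(as.list(stripped), ep = ep)
  majority_consensus(msa_matrix(rows2), min_occupancy = 2L)
}

#' Assess an iteration's new consensus
#'
#' `REVERT` if the new consensus is shorter than the previous one or covers
#' less than 80% of it; otherwise `DONE` when growth is below half the flank
#' extension, and `CONTINUE` when growth is at least that.
#'
#' @param new_consensus,prev_consensus sequences to compare.
#' @param params [beat_params()].
#' @param ep engine parameters.
#' @return list with `verdict` (`"REVERT"`, `"DONE"` or `"CONTINUE"`) and
#'   `reason`.
#' @export
assess_iteration <- function(new_consensus, prev_consensus,
                             params = beat_params(), ep = engine_params()) {
  stopifnot(nchar(new_consensus) > 0, nchar(prev_consensus) > 0)
  ln <- nchar(new_consensus); lp <- nchar(prev_consensus)
  if (ln < lp)
    return(list(verdict = "REVERT", reason = "new consensus shorter"))
  h <- engine_hits(prev_consensus, new_consensus, ep)
  cov <- if (nrow(h) == 0) 0 else
    covered_fraction(h$q_start, h$q_end, lp)
  if (cov < params$accept_min_coverage_of_prev)
    return(list(verdict = "REVERT",
                reason = sprintf("coverage of previous %.3f < %.2f", cov,
                                 params$accept_min_coverage_of_prev)))
  growth <- ln - lp
  if (growth < params$done_fraction_of_flank * params$flank)
    return(list(verdict = "DONE",
                reason = sprintf("growth %d bp < %.0f bp", growth,
                                 params$done_fraction_of_flank * params$flank)))
  list(verdict = "CONTINUE",
       reason = sprintf("growth %d bp", growth))
}

#' Curate one consensus by iterative extension
#'
#' Orchestrates tandem triage, then iterates: find genomic copies, select the
#' top candidates, extract with extended flanks, validate against the round-0
#' consensus, trim to mutual support, rebuild by majority rule, and assess.
#' Finishes with satellite/macrosatellite classification. Deterministic.
#'
#' @param record a `RAW` [consensus_record()].
#' @param genome a `GenomeAssembly`.
#' @param params [beat_params()].
#' @param ep engine parameters.
#' @return the curated record (status one of `CURATED`, `TANDEM`,
#'   `MACROSATELLITE`, `LOW_COPY`), with `iterations_run` set.
#' @export
beat_curate <- function(record, genome, params = beat_params(),
                        ep = engine_params()) {
  stopifnot(inherits(record, "ConsensusRecord"))
  if (record$status != "RAW") return(record)
  record <- triage_consensus(record)
  if (record$status != "RAW") return(record)

  initial <- record$sequence
  current <- initial
  iterations <- 0L
  final_status <- "CURATED"

  while (iterations < params$max_iterations) {
    iterations <- iterations + 1L
    hits <- find_hits(current, genome, min_identity = 0.5,
                      min_coverage = 0.2, ep = ep)
    sel <- select_candidates(hits, params)
    if (sel$low_copy) {
      if (iterations == 1L) final_status <- "LOW_COPY"
      iterations <- iterations - 1L
      break
    }
    extended <- extend_flanks(genome, sel$hits, params$flank)
    extended <- validate_extended(extended, initial, params, ep)
    if (length(extended) < params$min_matches) {
      if (iterations == 1L) final_status <- "LOW_COPY"
      iterations <- iterations - 1L
      break
    }
    trimmed <- trim_to_mutual_support(extended, ep)
    new_cons <- tryCatch(
      build_consensus(trimmed, current, ep),
      error = function(e) NULL)
    if (is.null(new_cons) || nchar(new_cons) == 0) {
      if (iterations == 1L) final_status <- "LOW_COPY"
      iterations <- iterations - 1L
      break
    }
    dec <- assess_iteration(new_cons, current, params, ep)
    if (dec$verdict == "REVERT") break
    current <- new_cons
    if (dec$verdict == "DONE") break
  }

  record$sequence <- current
  record$iterations_run <- iterations
  record <- classify_satellites(record)
  if (record$status == "RAW") record <- set_status(record, final_status)
  record
}

#' Curate a whole library
#'
#' @param library list of consensus records.
#' @param genome a `GenomeAssembly`.
#' @param params [beat_params()].
#' @param ep engine parameters.
#' @return list of curated records.
#' @export
curate_library <- function(library, genome, params = beat_params(),
                           ep = engine_params()) {
  lapply(library, beat_curate, genome = genome, params = params, ep = ep)
}
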