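# Library-vs-genome annotation on the internal search engine, genome
# masking, and optional greedy 80/80 library clustering.

#' Annotate a genome with a TE consensus library
#'
#' Runs the seeded search for every consensus on both strands, then resolves
#' competing hits greedily by descending score: a locus keeps its
#' best-scoring family and lower-scoring hits are truncated to the free
#' remainder (or dropped). Every annotation carries a raw p-distance
#' (`1 - identity` over aligned non-gap columns) and the Kimura 2-parameter
#' divergence from its alignment. Score ties are broken by longer alignment,
#' then lexicographic family id.
#'
#' @param genome a `GenomeAssembly`.
#' @param library list of consensus records.
#' @param min_score minimum alignment score for a hit to annotate.
#' @param min_identity identity floor for the search.
#' @param min_piece truncated fragments shorter than this are dropped, bp.
#' @param ep engine parameters.
#' @return annotation data frame sorted by (contig, start), with no
#'   overlapping rows; extra columns `p_distance` and `kimura`.
#' @export
annotate_genome <- function(genome, library, min_score = 40,
                            min_identity = 0.55, min_piece = 10L,
                            ep = engine_params()) {
  stopifnot(length(library) > 0)
  ep$min_score <- as.integer(min_score)
  all_hits <- list()
  for (rec in library) {
    h <- find_hits(rec$sequence, genome, min_identity = min_identity,
                   min_coverage = 0, ep = ep)
    if (nrow(h) == 0) next
    h <- h[h$score >= min_score, , drop = FALSE]
    if (nrow(h) == 0) next
    h$family <- rec$id
    h$classification <- rec$classification
    all_hits[[length(all_hits) + 1]] <- h
  }
  if (length(all_hits) == 0) return(annotate_empty())
  hits <- do.call(rbind, all_hits)
  hits$p_distance <- 1 - hits$identity
  p <- ifelse(hits$pairs > 0, hits$ts / hits$pairs, 0)
  q <- ifelse(hits$pairs > 0, hits$tv / hits$pairs, 0)
  hits$kimura <- mapply(function(pp, qq) {
    k <- kimura_distance(pp, qq)
    if (is.na(k)) 0.5 else k   # saturated alignments clamp into the last bin
  }, p, q)
  hits <- hits[order(-hits$score, -(hits$s_end - hits$s_start),
                     hits$family), , drop = FALSE]
  # greedy per-locus resolution
  rows <- vector("list", nrow(hits))
  occupied <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    ir <- IRanges::IRanges(h$s_start + 1L, h$s_end)
    occ <- occupied[[h$contig]]
    free <- if (is.null(occ)) ir else IRanges::setdiff(ir, occ)
    free <- free[IRanges::width(free) >= min_piece]
    if (length(free) == 0) next
    occupied[[h$contig]] <- if (is.null(occ)) IRanges::reduce(free) else
      IRanges::reduce(c(occ, free))
    rows[[i]] <- data.frame(
      contig = h$contig, start = IRanges::start(free) - 1L,
      end = IRanges::end(free), strand = h$strand, family = h$family,
      classification = h$classification, divergence = h$kimura,
      score = h$score, p_distance = h$p_distance, kimura = h$kimura,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(annotate_empty())
  out <- sort_annotations(do.call(rbind, rows))
  rownames(out) <- NULL
  validate_annotations(out)
  out
}

annotate_empty <- function() {
  cbind(annotations(), data.frame(p_distance = numeric(), kimura = numeric()))
}

#' Mask annotated regions of a genome
#'
#' Soft masking lower-cases annotated spans; hard masking replaces them with
#' `N`. Sequence length is preserved.
#'
#' @param genome a `GenomeAssembly`.
#' @param annots annotation data frame.
#' @param mode `"soft"` or `"hard"`.
#' @return a masked `GenomeAssembly`.
#' @export
mask_genome <- function(genome, annots, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  contigs <- genome$contigs
  for (ctg in unique(annots$contig)) {
    if (!ctg %in% names(contigs)) next
    r <- charToRaw(contigs[[ctg]])
    rows <- annots[annots$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      span <- (rows$start[i] + 1L):rows$end[i]
      if (mode == "soft") {
        r[span] <- as.raw(bitwOr(as.integer(r[span]), 0x20L))
      } else {
        r[span] <- as.raw(78L)  # 'N'
      }
    }
    contigs[[ctg]] <- rawToChar(r)
  }
  out <- genome
  out$contigs <- contigs
  out
}

#' Cluster a library at the 80/80 family threshold
#'
#' Greedy longest-first clustering: a sequence joins a cluster when it aligns
#' to the representative with identity >= 0.80 over >= 0.80 of the shorter
#' sequence, on either strand. Returns the representatives. Clustering is
#' off by default in the pipeline.
#'
#' @param library list of consensus records.
#' @param min_identity,min_coverage cluster thresholds.
#' @param ep engine parameters.
#' @return list of representative consensus records.
#' @export
cluster_library <- function(library, min_identity = 0.80,
                            min_coverage = 0.80, ep = engine_params()) {
  stopifnot(length(library) > 0)
  lens <- vapply(library, function(r) nchar(r$sequence), integer(1))
  ids <- vapply(library, function(r) r$id, character(1))
  ord <- order(-lens, ids)
  reps <- list()
  for (i in ord) {
    rec <- library[[i]]
    joined <- FALSE
    for (rep_rec in reps) {
      # coverage measured on the shorter sequence: rec (longest-first order)
      h <- engine_hits(rec$sequence, rep_rec$sequence, ep)
      if (nrow(h) == 0) next
      best <- h[which.max(h$score), ]
      cov <- covered_fraction(h$q_start, h$q_end, nchar(rec$sequence))
      if (best$identity >= min_identity && cov >= min_coverage) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps[[length(reps) + 1]] <- rec
  }
  reps
}
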