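# Nucleotide-level scoring of a test annotation against a reference:
# confusion matrix and Matthews correlation coefficient, per-copy
# classification agreement, annotation fragmentation ratio, and the
# consensus-length band summary.

annot_ranges <- function(df, contig) {
  rows <- df[df$contig == contig, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(rows$start + 1L, rows$end))
}

#' Nucleotide confusion matrix of a test annotation vs a reference
#'
#' Bases covered by both annotation sets are true positives, bases covered by
#' neither are true negatives, bases only in the test set are false
#' positives, and bases only in the reference are false negatives. TE
#' identity is ignored (presence/absence only). Counts sum to the genome
#' length.
#'
#' @param reference,test annotation data frames.
#' @param genome_length total genome length, bp (scalar, or named vector of
#'   per-contig lengths for multi-contig genomes).
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(reference, test, genome_length) {
  contigs <- union(unique(reference$contig), unique(test$contig))
  tp <- fp <- fn <- 0L
  for (ctg in contigs) {
    r <- annot_ranges(reference, ctg)
    t <- annot_ranges(test, ctg)
    inter <- IRanges::intersect(r, t)
    tp <- tp + sum(IRanges::width(inter))
    fp <- fp + sum(IRanges::width(t)) - sum(IRanges::width(inter))
    fn <- fn + sum(IRanges::width(r)) - sum(IRanges::width(inter))
  }
  total <- as.integer(sum(genome_length))
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       tn = total - as.integer(tp) - as.integer(fp) - as.integer(fn))
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; defined as 0 when
#' any denominator sum is zero.
#'
#' @param counts list with `tp`, `fp`, `fn`, `tn` (see [confusion()]).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Per-copy classification agreement
#'
#' Each reference copy is matched to the test annotations covering it. Copies
#' covered over less than `min_overlap_fraction` of their length are
#' `missing`; otherwise the copy is `correct` when the top-level class (the
#' part before `/`) of the majority-covering test classification equals the
#' reference's, else `misclassified`.
#'
#' @param reference,test annotation data frames.
#' @param min_overlap_fraction coverage threshold for a copy to count as
#'   found.
#' @return list with `correct`, `misclassified`, `missing` (reference copies).
#' @export
classification_agreement <- function(reference, test,
                                     min_overlap_fraction = 0.5) {
  correct <- mis <- missing <- 0L
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    tt <- test[test$contig == r$contig & test$start < r$end &
                 test$end > r$start, , drop = FALSE]
    if (nrow(tt) == 0) { missing <- missing + 1L; next }
    ov <- pmin(tt$end, r$end) - pmax(tt$start, r$start)
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(pmax(tt$start, r$start) + 1L, pmin(tt$end, r$end)))))
    if (covered < min_overlap_fraction * (r$end - r$start)) {
      missing <- missing + 1L
      next
    }
    by_cls <- tapply(ov, top_class(tt$classification), sum)
    winner <- names(by_cls)[which.max(by_cls)]
    if (winner == top_class(r$classification)) correct <- correct + 1L
    else mis <- mis + 1L
  }
  list(correct = correct, misclassified = mis, missing = missing)
}

#' Annotation fragmentation ratio
#'
#' For each baseline annotation overlapped by at least one annotation in
#' `other`, counts the distinct overlapping `other` annotations; reports the
#' mean per top-level classification (baseline annotations with no overlap
#' are excluded).
#'
#' @param baseline,other annotation data frames on the same genome.
#' @return data frame with `classification`, `ratio`, `n` plus an `overall`
#'   attribute (mean over all shared baseline annotations).
#' @export
fragmentation_ratio <- function(baseline, other) {
  counts <- integer(nrow(baseline))
  for (i in seq_len(nrow(baseline))) {
    b <- baseline[i, ]
    counts[i] <- sum(other$contig == b$contig & other$start < b$end &
                       other$end > b$start)
  }
  shared <- counts > 0
  cls <- top_class(baseline$classification)[shared]
  if (!any(shared)) {
    out <- data.frame(classification = character(), ratio = numeric(),
                      n = integer())
    attr(out, "overall") <- NA_real_
    return(out)
  }
  m <- tapply(counts[shared], cls, mean)
  n <- tapply(counts[shared], cls, length)
  out <- data.frame(classification = names(m), ratio = as.numeric(m),
                    n = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "overall") <- mean(counts[shared])
  out
}

#' Consensus length compared to the real TE library
#'
#' Pairs every test consensus with its best-scoring real sequence (internal
#' engine score) and reports its length as a percent of the real length,
#' plus the fraction of paired consensuses within the 95-105% band.
#'
#' @param test_library,real_library lists of consensus records.
#' @param ep engine parameters.
#' @return list with `per_consensus` (data frame `id`, `real_id`,
#'   `percent_of_real`, `in_band`; unpaired consensuses have `NA`s) and
#'   `fraction_in_band`.
#' @export
consensus_length_band <- function(test_library, real_library,
                                  ep = engine_params()) {
  stopifnot(length(test_library) > 0, length(real_library) > 0)
  rows <- lapply(test_library, function(rec) {
    best_score <- -Inf; best <- NA_integer_
    for (j in seq_along(real_library)) {
      h <- engine_hits(rec$sequence, real_library[[j]]$sequence, ep)
      if (nrow(h) == 0) next
      s <- max(h$score)
      if (s > best_score) { best_score <- s; best <- j }
    }
    if (is.na(best))
      return(data.frame(id = rec$id, real_id = NA_character_,
                        percent_of_real = NA_real_, in_band = NA))
    pct <- 100 * nchar(rec$sequence) /
      nchar(real_library[[best]]$sequence)
    data.frame(id = rec$id, real_id = real_library[[best]]$id,
               percent_of_real = pct, in_band = pct >= 95 & pct <= 105,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  paired <- !is.na(per$in_band)
  list(per_consensus = per,
       fraction_in_band = if (any(paired)) mean(per$in_band[paired]) else
         NA_real_)
}

#' Coverage-matched random annotation set
#'
#' Places intervals uniformly at random, independent of any reference, with
#' total coverage matched to `reference` (same number of intervals with the
#' same lengths, placed without overlap). Used as the null model for the
#' MCC-near-zero check.
#'
#' @param reference annotation data frame (single contig).
#' @param genome_length contig length, bp.
#' @param seed integer seed.
#' @return annotation data frame.
#' @export
random_annotations <- function(reference, genome_length, seed = NULL) {
  lens <- reference$end - reference$start
  contig <- if (nrow(reference) > 0) reference$contig[1] else "ctg_0"
  free <- genome_length - sum(lens)
  if (free < 0)
    stop("random_annotations: reference coverage exceeds genome length")
  with_preserved_rng(seed, {
    n <- length(lens)
    ord <- sample(n)
    # place in gap space: interval i starts at a sorted uniform draw from the
    # free bases plus the lengths of the intervals placed before it
    offsets <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
    starts <- offsets + cumsum(c(0L, lens[ord][-n]))
    annotations(contig = contig, start = starts, end = starts + lens[ord],
                strand = "+", family = reference$family[ord],
                classification = reference$classification[ord])
  })
}
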