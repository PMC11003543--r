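# Tandem-repeat detection inside consensus sequences and the triage rules
# applied before and after iterative curation. A single internal detector
# scores shifted self-identity for every candidate period: a region reported
# at period p matches itself shifted by p at >= 75% of positions. Harmonic
# periods (2p, 3p, ...) of an already-covered region are suppressed so each
# region carries its fundamental period.

#' Detect tandem repeats in a sequence
#'
#' Scans candidate periods 1..`max_period`, extracts maximal self-similar
#' segments (>= 75% match under a shift by the period), and suppresses
#' harmonic re-detections. Deterministic.
#'
#' @param sequence nucleotide string (length >= 2).
#' @param max_period largest period to consider, bp.
#' @param min_net minimum net segment score (match +1 / mismatch -3); filters
#'   chance self-matches in random sequence.
#' @return a `TandemProfile`: list with `regions` (data.frame `start`, `end`
#'   half-open, `period`, `identity`), `tandem_fraction` (fraction of the
#'   sequence covered by the union of regions) and `longest` (the single
#'   region of maximal length, or `NULL`).
#' @export
detect_tandem <- function(sequence, max_period = 2000L, min_net = 10L) {
  n <- nchar(sequence)
  stopifnot(n >= 2)
  segs <- cpp_tandem_segments(toupper(sequence),
                              as.integer(min(max_period, n - 1L)),
                              as.integer(min_net), 30L)
  regions <- data.frame(start = integer(), end = integer(),
                        period = integer(), identity = numeric())
  if (nrow(segs) > 0) {
    segs$identity <- segs$m / (segs$m + segs$mm)
    segs <- segs[order(segs$period, segs$start), , drop = FALSE]
    covered <- logical(n)
    keep <- logical(nrow(segs))
    for (i in seq_len(nrow(segs))) {
      span <- (segs$start[i] + 1L):segs$end[i]
      novel <- sum(!covered[span])
      if (novel >= 0.5 * length(span)) {
        keep[i] <- TRUE
        covered[span] <- TRUE
      }
    }
    segs <- segs[keep, , drop = FALSE]
    regions <- data.frame(start = segs$start, end = segs$end,
                          period = segs$period, identity = segs$identity)
    regions <- regions[order(regions$start, regions$period), , drop = FALSE]
    rownames(regions) <- NULL
    tf <- sum(covered) / n
  } else tf <- 0
  longest <- NULL
  if (nrow(regions) > 0) {
    len <- regions$end - regions$start
    longest <- regions[which.max(len), ]  # ties: leftmost (stable order)
  }
  structure(list(regions = regions, tandem_fraction = tf, longest = longest,
                 length = n),
            class = "TandemProfile")
}

# longest maximal run not covered by tandem regions; ties broken leftmost
longest_non_tandem <- function(profile) {
  n <- profile$length
  covered <- logical(n)
  for (i in seq_len(nrow(profile$regions)))
    covered[(profile$regions$start[i] + 1L):profile$regions$end[i]] <- TRUE
  if (!any(!covered)) return(c(0L, 0L))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  free <- which(!r$values)
  b <- free[which.max(r$lengths[free])]
  c(starts[b] - 1L, ends[b])  # half-open
}

#' Triage a raw consensus by tandem-repeat content
#'
#' Applies the pre-curation rules: tandem fraction > 0.90 classifies the
#' consensus as a tandem repeat (no curation); fraction in (0.50, 0.90]
#' extracts the longest non-tandem section as the final consensus (no further
#' curation); fraction <= 0.50 leaves the record `RAW` so curation proceeds.
#' Thresholds are strict as stated: a fraction of exactly 0.90 is not
#' "greater than 90%" and exactly 0.50 proceeds to curation.
#'
#' @param record a [consensus_record()] with status `RAW`.
#' @param profile optional precomputed [detect_tandem()] profile.
#' @return the record, with status and possibly sequence updated.
#' @export
triage_consensus <- function(record, profile = NULL) {
  stopifnot(inherits(record, "ConsensusRecord"))
  if (is.null(profile)) profile <- detect_tandem(record$sequence)
  f <- profile$tandem_fraction
  if (f > 0.90) return(set_status(record, "TANDEM"))
  if (f > 0.50) {
    span <- longest_non_tandem(profile)
    if (span[2] > span[1])
      record$sequence <- substr(record$sequence, span[1] + 1L, span[2])
    return(set_status(record, "CURATED"))
  }
  record
}

#' Classify satellite and macrosatellite consensuses
#'
#' Run after curation: a consensus more than 50% tandem is flagged as a
#' likely simple/satellite repeat. Within that set, a consensus whose longest
#' contiguous tandem region covers more than 90% of its length with a period
#' of 200 bp or more is classified a macrosatellite and trimmed to exactly
#' one period (the first full unit of that region).
#'
#' @param record a consensus record.
#' @param profile optional precomputed [detect_tandem()] profile.
#' @return the record with `satellite` flag, status and sequence updated.
#' @export
classify_satellites <- function(record, profile = NULL) {
  stopifnot(inherits(record, "ConsensusRecord"))
  if (is.null(profile)) profile <- detect_tandem(record$sequence)
  if (profile$tandem_fraction <= 0.50) return(record)
  record$satellite <- TRUE
  lg <- profile$longest
  if (!is.null(lg)) {
    covers <- (lg$end - lg$start) / profile$length
    if (covers > 0.90 && lg$period >= 200) {
      record$sequence <- substr(record$sequence, lg$start + 1L,
                                lg$start + lg$period)
      record$status <- "MACROSATELLITE"
    }
  }
  record
}
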