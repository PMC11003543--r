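# Post-annotation refinement: defragmentation of same-family fragment
# chains, midpoint overlap resolution, and the optional <100 bp filter.

#' Merge fragmented annotations of the same insertion
#'
#' Maximal chains of same-family, same-strand annotations on one contig with
#' inter-annotation gaps of at most `max_gap` bp (inclusive) are merged into
#' a single annotation spanning the chain. The merged divergence is the
#' length-weighted mean of member divergences and a `group_id` records the
#' chain. When full-length-LTR intervals are supplied, LTR-classified
#' annotations falling entirely inside one interval are merged into a single
#' locus regardless of gap.
#'
#' @param annots annotation data frame.
#' @param max_gap largest merged gap, bp.
#' @param ltr_intervals optional data frame with `contig`, `start`, `end`
#'   (0-based half-open) of full-length LTR elements.
#' @return defragmented annotations sorted by (contig, start).
#' @export
defragment <- function(annots, max_gap = 150L, ltr_intervals = NULL) {
  if (nrow(annots) == 0) return(annots)
  annots <- sort_annotations(annots)
  annots$.ltr_group <- NA_integer_
  if (!is.null(ltr_intervals) && nrow(ltr_intervals) > 0) {
    is_ltr <- top_class(annots$classification) == "LTR"
    for (k in seq_len(nrow(ltr_intervals))) {
      inside <- is_ltr & annots$contig == ltr_intervals$contig[k] &
        annots$start >= ltr_intervals$start[k] &
        annots$end <= ltr_intervals$end[k]
      annots$.ltr_group[inside] <- k
    }
  }
  key <- paste(annots$contig, annots$family, annots$strand)
  pieces <- lapply(split(annots, key), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    grp <- integer(nrow(g))
    cur <- 1L
    grp[1] <- cur
    for (i in seq_len(nrow(g))[-1]) {
      gap <- g$start[i] - max(g$end[seq_len(i - 1)][grp[seq_len(i - 1)] == cur])
      same_ltr <- !is.na(g$.ltr_group[i]) && !is.na(g$.ltr_group[i - 1]) &&
        g$.ltr_group[i] == g$.ltr_group[i - 1]
      if (gap > max_gap && !same_ltr) cur <- cur + 1L
      grp[i] <- cur
    }
    merged <- lapply(split(g, grp), function(m) {
      w <- m$end - m$start
      div <- if (all(is.na(m$divergence))) NA_real_ else
        sum(m$divergence * w, na.rm = TRUE) / sum(w[!is.na(m$divergence)])
      out <- m[1, , drop = FALSE]
      out$start <- min(m$start); out$end <- max(m$end)
      out$divergence <- div
      out$score <- if (all(is.na(m$score))) NA_real_ else
        max(m$score, na.rm = TRUE)
      out
    })
    do.call(rbind, merged)
  })
  out <- do.call(rbind, pieces)
  out$.ltr_group <- NULL
  out <- sort_annotations(out)
  out$group_id <- paste0("grp_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Resolve overlapping annotations
#'
#' Annotations fully contained in another are dropped in favour of the
#' container. Partial overlaps are split at the overlap midpoint: the
#' leftmost-starting annotation keeps the left half; an odd overlap gives the
#' extra base to the first. The output has zero overlapping bases and covers
#' exactly the union of the input intervals.
#'
#' @param annots annotation data frame.
#' @return non-overlapping annotations sorted by (contig, start).
#' @export
resolve_overlaps <- function(annots) {
  if (nrow(annots) <= 1) return(annots)
  pieces <- lapply(split(annots, annots$contig), function(g) {
    g <- g[order(g$start, -g$end), , drop = FALSE]
    keep <- logical(nrow(g))
    cur <- 1L
    keep[1] <- TRUE
    for (i in seq_len(nrow(g))[-1]) {
      if (g$end[i] <= g$end[cur]) next  # contained: drop
      if (g$start[i] < g$end[cur]) {
        ov <- g$end[cur] - g$start[i]
        mid <- g$start[i] + as.integer(ceiling(ov / 2))
        g$end[cur] <- mid
        g$start[i] <- mid
      }
      keep[i] <- TRUE
      cur <- i
    }
    g[keep, , drop = FALSE]
  })
  out <- sort_annotations(do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}

#' Remove short annotations
#'
#' When enabled, drops annotations shorter than `min_length` bp. Disabled by
#' default.
#'
#' @param annots annotation data frame.
#' @param min_length minimum retained length, bp.
#' @param enabled apply the filter?
#' @return filtered annotations.
#' @export
length_filter <- function(annots, min_length = 100L, enabled = FALSE) {
  if (!enabled || nrow(annots) == 0) return(annots)
  annots[annots$end - annots$start >= min_length, , drop = FALSE]
}
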