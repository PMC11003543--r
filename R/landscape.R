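# Divergence computation and genome-level summaries: Kimura 2-parameter
# distances, per-classification pie table, family table and the repeat
# landscape binned by divergence.

#' Kimura 2-parameter distance
#'
#' `K = -1/2 * ln((1 - 2p - q) * sqrt(1 - 2q))` from the transition fraction
#' `p` and transversion fraction `q`. Outside the valid domain
#' (`1 - 2p - q > 0` and `1 - 2q > 0`) the distance is undefined (saturated)
#' and `NA` is returned.
#'
#' @param p fraction of sites with transitions.
#' @param q fraction of sites with transversions.
#' @return Kimura distance in substitutions/site, or `NA` when saturated.
#' @export
kimura_distance <- function(p, q) {
  mapply(function(pp, qq) {
    a <- 1 - 2 * pp - qq
    b <- 1 - 2 * qq
    if (a <= 0 || b <= 0) return(NA_real_)
    -0.5 * log(a * sqrt(b))
  }, p, q)
}

#' Kimura divergence of annotations from their consensus
#'
#' Re-aligns each annotated genomic segment to its family consensus, counts
#' transition and transversion fractions over aligned non-gap columns, and
#' applies [kimura_distance()]. Annotations whose segment no longer aligns
#' are flagged (`divergence` set `NA`) and excluded from the landscape.
#'
#' @param annots annotation data frame.
#' @param genome a `GenomeAssembly`.
#' @param library list of consensus records (ids matched to `family`).
#' @param ep engine parameters.
#' @return the annotations with `divergence` (Kimura) and `p_distance`
#'   columns filled.
#' @export
annotation_divergences <- function(annots, genome, library,
                                   ep = engine_params()) {
  if (nrow(annots) == 0) return(annots)
  lib_ids <- vapply(library, function(r) r$id, character(1))
  annots$p_distance <- NA_real_
  for (i in seq_len(nrow(annots))) {
    j <- match(annots$family[i], lib_ids)
    if (is.na(j)) next
    seg <- substr(genome$contigs[[annots$contig[i]]],
                  annots$start[i] + 1L, annots$end[i])
    h <- engine_hits(seg, library[[j]]$sequence, ep)
    if (nrow(h) == 0) { annots$divergence[i] <- NA_real_; next }
    best <- h[which.max(h$score), ]
    p <- best$ts / best$pairs
    q <- best$tv / best$pairs
    annots$divergence[i] <- kimura_distance(p, q)
    annots$p_distance[i] <- 1 - best$matches / best$pairs
  }
  annots
}

#' Summarise annotations: pie, family table and repeat landscape
#'
#' The pie table gives the percent of the genome covered by each top-level
#' classification plus the `Non-Repeat` remainder (sums to 100). The family
#' table counts annotations and bp per family, sorted by bp descending. The
#' landscape bins annotated bp by `floor(100 * Kimura divergence)` into 1%
#' bins from 0 to 50 per top-level classification (values above 50 are
#' clamped into the last bin with a warning); by convention the axis is drawn
#' reversed so that ancient activity appears on the left.
#'
#' @param annots refined annotation data frame (non-overlapping).
#' @param genome a `GenomeAssembly`.
#' @return list with data frames `pie` (`classification`, `percent`),
#'   `families` (`family`, `classification`, `count`, `bp`, `percent`) and
#'   `landscape` (`bin`, `classification`, `percent`).
#' @export
summarize_annotations <- function(annots, genome) {
  total <- genome$total_length
  len <- annots$end - annots$start
  cls <- top_class(annots$classification)
  # pie
  by_cls <- tapply(len, cls, sum)
  pie <- data.frame(classification = names(by_cls),
                    percent = 100 * as.numeric(by_cls) / total,
                    stringsAsFactors = FALSE)
  pie <- pie[order(-pie$percent, pie$classification), , drop = FALSE]
  pie <- rbind(pie, data.frame(classification = "Non-Repeat",
                               percent = 100 - sum(pie$percent)))
  rownames(pie) <- NULL
  # family table
  if (nrow(annots) > 0) {
    fam_bp <- tapply(len, annots$family, sum)
    fam_n <- tapply(len, annots$family, length)
    fam_cls <- tapply(annots$classification, annots$family, function(x) x[1])
    families <- data.frame(family = names(fam_bp),
                           classification = as.character(fam_cls),
                           count = as.integer(fam_n),
                           bp = as.integer(fam_bp),
                           percent = 100 * as.numeric(fam_bp) / total,
                           stringsAsFactors = FALSE)
    families <- families[order(-families$bp, families$family), , drop = FALSE]
    rownames(families) <- NULL
  } else {
    families <- data.frame(family = character(), classification = character(),
                           count = integer(), bp = integer(),
                           percent = numeric())
  }
  # landscape
  has_div <- !is.na(annots$divergence)
  bins <- floor(100 * annots$divergence[has_div])
  if (any(bins > 50)) {
    warning("divergences above 0.50 clamped into the last landscape bin")
    bins[bins > 50] <- 50
  }
  bins[bins < 0] <- 0
  grid <- expand.grid(bin = 0:50, classification = unique(cls),
                      stringsAsFactors = FALSE)
  if (any(has_div)) {
    agg <- stats::aggregate(
      bp ~ bin + classification,
      data = data.frame(bin = bins, classification = cls[has_div],
                        bp = len[has_div]),
      FUN = sum)
    grid <- merge(grid, agg, by = c("bin", "classification"), all.x = TRUE)
  } else grid$bp <- NA_real_
  grid$bp[is.na(grid$bp)] <- 0
  landscape <- data.frame(bin = grid$bin,
                          classification = grid$classification,
                          percent = 100 * grid$bp / total)
  landscape <- landscape[order(landscape$classification, landscape$bin), ,
                         drop = FALSE]
  rownames(landscape) <- NULL
  list(pie = pie, families = families, landscape = landscape)
}
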