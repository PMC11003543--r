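# Fixture builders and independent oracles used across the suite. Oracles
# deliberately avoid the package's own code paths: Smith-Waterman via
# Biostrings, confusion counts via a per-base labelling loop, tandem content
# via a direct period scan.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(s, n_subs) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), n_subs)
  v[idx] <- vapply(v[idx],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   "")
  paste(v, collapse = "")
}

# full Smith-Waterman oracle under the engine's scoring (match +2,
# mismatch -3, gap of length L costs 5 + 2L), via Biostrings
oracle_sw <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  list(score = Biostrings::score(al),
       identity = matches / length(pa),
       q_start = Biostrings::start(Biostrings::pattern(al)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(al)),
       s_start = Biostrings::start(Biostrings::subject(al)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(al)))
}

# per-base confusion oracle on a single contig
oracle_confusion <- function(ref, test, genome_length) {
  in_ref <- logical(genome_length)
  in_test <- logical(genome_length)
  for (i in seq_len(nrow(ref)))
    in_ref[(ref$start[i] + 1):ref$end[i]] <- TRUE
  for (i in seq_len(nrow(test)))
    in_test[(test$start[i] + 1):test$end[i]] <- TRUE
  list(tp = sum(in_ref & in_test), fp = sum(!in_ref & in_test),
       fn = sum(in_ref & !in_test), tn = sum(!in_ref & !in_test))
}

# union length of intervals on one contig (sorted-merge, no IRanges)
oracle_union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs)
}

# brute-force tandem fraction oracle: a position is tandem-covered if some
# period p in 1..max_p matches >= 75% over a window around it
oracle_tandem_fraction <- function(s, max_p = 50, min_run = 12) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  covered <- logical(n)
  for (p in seq_len(min(max_p, n - 1))) {
    m <- v[seq_len(n - p)] == v[seq_len(n - p) + p]
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= max(min_run, p))
    for (b in runs) covered[starts[b]:(ends[b] + p)] <- TRUE
  }
  mean(covered)
}

# genome with planted TE copies at known positions; returns assembly + truth
plant_genome <- function(te, n_copies, host_len, gap = 2000, divergence = 0,
                         gc = 0.5) {
  pieces <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (i in seq_len(n_copies)) {
    host <- random_dna(gap, gc)
    copy <- if (divergence > 0)
      mutate_dna(te, round(divergence * nchar(te))) else te
    pieces <- c(pieces, host, copy)
    pos <- pos + nchar(host)
    starts <- c(starts, pos)
    pos <- pos + nchar(copy)
  }
  tail_len <- max(0L, host_len - pos)
  pieces <- c(pieces, random_dna(max(tail_len, gap), gc))
  g <- paste(pieces, collapse = "")
  list(genome = prepare_genome(stats::setNames(g, "host")),
       starts = starts, ends = starts + nchar(te))
}

# synthetic search-hit table for candidate-selection tests
make_hits <- function(identity, coverage, score) {
  n <- length(identity)
  data.frame(query_id = "q", contig = "ctg_0",
             q_start = 0L, q_end = 100L,
             s_start = seq(0L, by = 1000L, length.out = n),
             s_end = seq(500L, by = 1000L, length.out = n),
             strand = "+", identity = identity, query_coverage = coverage,
             score = score, matches = 100L, columns = 100L, pairs = 100L,
             ts = 0L, tv = 0L)
}

fake_profile <- function(len, regions = NULL) {
  if (is.null(regions))
    regions <- data.frame(start = integer(), end = integer(),
                          period = integer(), identity = numeric())
  covered <- logical(len)
  for (i in seq_len(nrow(regions)))
    covered[(regions$start[i] + 1):regions$end[i]] <- TRUE
  longest <- NULL
  if (nrow(regions) > 0)
    longest <- regions[which.max(regions$end - regions$start), ]
  structure(list(regions = regions, tandem_fraction = mean(covered),
                 longest = longest, length = len),
            class = "TandemProfile")
}
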