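# Synthetic genome generator: random base sequence at a stated GC content,
# TE copies inserted at random positions with per-copy divergence drawn
# uniformly up to a family maximum, a stated fraction of copies fragmented,
# and a second pass inserting nested copies inside first-pass insertions.
# Insertions expand the genome (no base-genome bases are overwritten), so
# every non-TE base stays uncontaminated for true-negative counting.

#' Simulation configuration
#'
#' @param genome_length base genome length before insertions, bp.
#' @param gc GC fraction of the base genome (`P(G) = P(C) = gc/2`).
#' @param families data frame with columns `name`, `classification`,
#'   `sequence`, `copy_number`, `divergence_max`, `fragmented_fraction`,
#'   `nested_fraction`.
#' @param seed integer seed; the same seed reproduces the genome and the
#'   reference byte-for-byte.
#' @param indel_rate fraction of mutation events that are small indels
#'   (default 0: substitution-only, so genome length is exactly base length
#'   plus inserted bp).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(genome_length, gc = 0.42, families = NULL, seed = 1L,
                       indel_rate = 0) {
  if (is.null(families))
    families <- data.frame(name = character(), classification = character(),
                           sequence = character(), copy_number = integer(),
                           divergence_max = numeric(),
                           fragmented_fraction = numeric(),
                           nested_fraction = numeric())
  stopifnot(gc > 0, gc < 1,
            all(c("name", "classification", "sequence", "copy_number",
                  "divergence_max", "fragmented_fraction",
                  "nested_fraction") %in% names(families)),
            all(nchar(families$sequence) > 0 | nrow(families) == 0),
            all(families$divergence_max >= 0 & families$divergence_max <= 1))
  structure(list(genome_length = as.integer(genome_length), gc = gc,
                 families = families, seed = as.integer(seed),
                 indel_rate = indel_rate),
            class = "SimConfig")
}

#' Random nucleotide sequence at a given GC content
#' @param n length, bp.
#' @param gc GC fraction.
#' @return nucleotide string.
#' @export
random_sequence <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Sample TE family copy numbers
#'
#' Draws from a normal distribution (rounded), clamped to the observed range
#' 5 to 732 copies, giving few low-copy families, most at intermediate copy
#' number and few very high.
#'
#' @param n_families number of families.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param mean,sd normal distribution parameters.
#' @return integer vector in `[5, 732]`.
#' @export
sample_copy_numbers <- function(n_families, seed = NULL, mean = 150, sd = 120) {
  stopifnot(n_families >= 1)
  with_preserved_rng(seed, {
    x <- round(rnorm(n_families, mean, sd))
    pmin(pmax(x, 5L), 732L)
  })
}

#' Mutate a TE copy
#'
#' Per-site substitution with probability `divergence`; substitutions are
#' transitions twice as often as transversions (ts:tv 2:1). Optionally a
#' fraction of mutation events are small (1-5 bp) insertions or deletions.
#'
#' @param sequence nucleotide string.
#' @param divergence per-site substitution probability (<= 0.45).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param indel_rate fraction of mutation events that are indels (default 0).
#' @return list with `sequence` and `p_distance` (realized substitution
#'   fraction, counted over substituted sites).
#' @export
mutate_copy <- function(sequence, divergence, seed = NULL, indel_rate = 0) {
  stopifnot(divergence <= 0.45)
  with_preserved_rng(seed, {
    s <- strsplit(sequence, "")[[1]]
    n <- length(s)
    hit <- which(runif(n) < divergence)
    n_indel <- if (indel_rate > 0 && length(hit) > 0)
      sum(runif(length(hit)) < indel_rate) else 0L
    indel_sites <- if (n_indel > 0) sample(hit, n_indel) else integer(0)
    subs <- setdiff(hit, indel_sites)
    if (length(subs) > 0) {
      # transition w.p. 2/3; each transversion target w.p. 1/6
      ts_map <- c(A = "G", G = "A", C = "T", T = "C")
      tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
      u <- runif(length(subs))
      for (t in seq_along(subs)) {
        b <- s[subs[t]]
        if (!b %in% names(ts_map)) next
        s[subs[t]] <- if (u[t] < 2 / 3) ts_map[[b]] else
          sample(tv_map[[b]], 1)
      }
    }
    p_dist <- length(subs) / n
    if (length(indel_sites) > 0) {
      for (site in sort(indel_sites, decreasing = TRUE)) {
        len <- sample(1:5, 1)
        if (runif(1) < 0.5) {  # insertion
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          s <- append(s, ins, after = site)
        } else {               # deletion
          drop <- site:min(site + len - 1, length(s))
          s <- s[-drop]
        }
      }
    }
    list(sequence = paste(s, collapse = ""), p_distance = p_dist)
  })
}

# truncate a fragmented copy: remove a uniform(10%, 90%) prefix or suffix
fragment_copy <- function(sequence) {
  n <- nchar(sequence)
  cut <- max(1L, min(n - 1L, round(runif(1, 0.1, 0.9) * n)))
  if (runif(1) < 0.5) substr(sequence, cut + 1L, n)
  else substr(sequence, 1L, n - cut)
}

#' Simulate a genome with known TE insertions
#'
#' Generates an i.i.d. base sequence at the configured GC content, inserts
#' every family's copies at uniform-random distinct positions (strand
#' uniform, per-copy divergence uniform on `[0, divergence_max]`, the
#' configured fraction fragmented), then runs a second pass inserting nested
#' copies (`round(nested_fraction * copy_number)` per family) inside
#' previously inserted copies. Host insertions keep a single record spanning
#' their full extent (nested child included); children carry `parent_id`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a `GenomeAssembly`, one contig `ctg_0`) and
#'   `reference` (annotation data frame with extra columns `id`,
#'   `fragmented`, `nested`, `parent_id`), sorted by start.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_preserved_rng(config$seed, {
    base <- random_sequence(config$genome_length, config$gc)
    fam <- config$families
    recs <- list()
    # first pass: draw all copies
    for (f in seq_len(nrow(fam))) {
      cn <- fam$copy_number[f]
      if (cn == 0) next
      n_frag <- round(fam$fragmented_fraction[f] * cn)
      frag <- rep(FALSE, cn)
      if (n_frag > 0) frag[sample(cn, n_frag)] <- TRUE
      for (ci in seq_len(cn)) {
        src <- fam$sequence[f]
        if (frag[ci]) src <- fragment_copy(src)
        div <- runif(1, 0, fam$divergence_max[f])
        mut <- mutate_copy(src, div, seed = NULL,
                           indel_rate = config$indel_rate)
        strand <- if (runif(1) < 0.5) "+" else "-"
        seq_out <- if (strand == "-") cpp_revcomp(mut$sequence) else
          mut$sequence
        recs[[length(recs) + 1]] <- list(
          family = fam$name[f], classification = fam$classification[f],
          sequence = seq_out, strand = strand, divergence = mut$p_distance,
          fragmented = frag[ci])
      }
    }
    n1 <- length(recs)
    if (n1 > 0) {
      total_ins <- sum(vapply(recs, function(r) nchar(r$sequence), integer(1)))
      if (config$genome_length < n1)
        stop("infeasible packing: genome too short for ", n1,
             " insertions; increase genome_length")
      pos <- sort(sample.int(config$genome_length - 1L, n1))  # distinct, 1..L-1
      ord <- sample.int(n1)  # which record gets which position
      recs <- recs[ord]
      # assemble: base split at positions, insertions interleaved
      lens <- vapply(recs, function(r) nchar(r$sequence), integer(1))
      starts <- pos + c(0L, cumsum(lens))[seq_len(n1)]
      pieces <- character(2 * n1 + 1)
      prev <- 0L
      for (i in seq_len(n1)) {
        pieces[2 * i - 1] <- substr(base, prev + 1L, pos[i])
        pieces[2 * i] <- recs[[i]]$sequence
        prev <- pos[i]
      }
      pieces[2 * n1 + 1] <- substr(base, prev + 1L, config$genome_length)
      g <- paste(pieces, collapse = "")
      ref <- data.frame(
        contig = "ctg_0", start = starts, end = starts + lens,
        strand = vapply(recs, `[[`, "", "strand"),
        family = vapply(recs, `[[`, "", "family"),
        classification = vapply(recs, `[[`, "", "classification"),
        divergence = vapply(recs, `[[`, 0, "divergence"),
        score = NA_real_,
        id = sprintf("ins_%05d", seq_len(n1)),
        fragmented = vapply(recs, `[[`, FALSE, "fragmented"),
        nested = FALSE, parent_id = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      g <- base
      ref <- cbind(annotations(),
                   data.frame(id = character(), fragmented = logical(),
                              nested = logical(), parent_id = character()))
    }
    # second pass: nested insertions inside first-pass copies
    next_id <- n1 + 1L
    for (f in seq_len(nrow(fam))) {
      n_nest <- round(fam$nested_fraction[f] * fam$copy_number[f])
      if (n_nest == 0 || n1 == 0) next
      for (ci in seq_len(n_nest)) {
        hosts <- which(!ref$nested & ref$end - ref$start >= 2L)
        if (length(hosts) == 0) break
        host <- hosts[sample.int(length(hosts), 1L)]
        at <- ref$start[host] +
          sample.int(ref$end[host] - ref$start[host] - 1L, 1L)
        div <- runif(1, 0, fam$divergence_max[f])
        mut <- mutate_copy(fam$sequence[f], div, seed = NULL,
                           indel_rate = config$indel_rate)
        strand <- if (runif(1) < 0.5) "+" else "-"
        seq_out <- if (strand == "-") cpp_revcomp(mut$sequence) else
          mut$sequence
        len <- nchar(seq_out)
        g <- paste0(substr(g, 1L, at), seq_out, substr(g, at + 1L, nchar(g)))
        # shift downstream records; stretch records spanning the breakpoint
        stretch <- ref$start < at & ref$end > at
        shift <- ref$start >= at
        ref$end[stretch] <- ref$end[stretch] + len
        ref$start[shift] <- ref$start[shift] + len
        ref$end[shift] <- ref$end[shift] + len
        ref <- rbind(ref, data.frame(
          contig = "ctg_0", start = at, end = at + len, strand = strand,
          family = fam$name[f], classification = fam$classification[f],
          divergence = mut$p_distance, score = NA_real_,
          id = sprintf("ins_%05d", next_id), fragmented = FALSE,
          nested = TRUE, parent_id = ref$id[host],
          stringsAsFactors = FALSE))
        next_id <- next_id + 1L
      }
    }
    ref <- ref[order(ref$start, ref$end), , drop = FALSE]
    rownames(ref) <- NULL
    list(genome = genome_assembly(setNames(g, "ctg_0")), reference = ref)
  })
}

#' Random simulation design in the benchmark style
#'
#' Builds a family set with random consensus sequences, copy numbers from
#' [sample_copy_numbers()], per-family maximum divergence uniform up to
#' `divergence_max`, and random fragmentation/nesting fractions.
#'
#' @param n_families number of TE families.
#' @param genome_length base genome length, bp.
#' @param gc GC fraction.
#' @param divergence_max upper bound for per-family maximum divergence.
#' @param fragmented_max,nested_max upper bounds for the per-family
#'   fragmented and nested fractions.
#' @param length_range TE consensus length range, bp.
#' @param copy_mean,copy_sd copy-number distribution parameters.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
random_sim_config <- function(n_families = 30L, genome_length = 2e6L,
                              gc = 0.42, divergence_max = 0.30,
                              fragmented_max = 0.5, nested_max = 0.2,
                              length_range = c(300L, 5000L),
                              copy_mean = 150, copy_sd = 120, seed = 1L) {
  classes <- c("LINE/L1", "LINE/RTE", "SINE/tRNA", "LTR/Gypsy", "LTR/Copia",
               "DNA/Tc1-Mariner", "DNA/hAT", "RC/Helitron", "PLE/Penelope")
  with_preserved_rng(seed, {
    lens <- round(exp(runif(n_families, log(length_range[1]),
                            log(length_range[2]))))
    fam <- data.frame(
      name = sprintf("fam_%02d", seq_len(n_families)),
      classification = sample(classes, n_families, replace = TRUE),
      sequence = vapply(lens, random_sequence, character(1), gc = gc),
      copy_number = sample_copy_numbers(n_families, seed = NULL,
                                        mean = copy_mean, sd = copy_sd),
      divergence_max = runif(n_families, 0, divergence_max),
      fragmented_fraction = runif(n_families, 0, fragmented_max),
      nested_fraction = runif(n_families, 0, nested_max),
      stringsAsFactors = FALSE)
    sim_config(genome_length, gc, fam, seed = seed)
  })
}

#' Library of consensus records from a simulation config
#' @param config a [sim_config()].
#' @return list of [consensus_record()]s (the true family sequences).
#' @export
config_library <- function(config) {
  fam <- config$families
  lapply(seq_len(nrow(fam)), function(i)
    consensus_record(fam$name[i], fam$sequence[i], fam$classification[i]))
}
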