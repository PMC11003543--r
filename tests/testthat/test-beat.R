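test_that("candidate selection enforces thresholds, cap and low-copy rule", {
  # 25 passing hits -> the 20 highest-scoring
  h <- make_hits(rep(0.9, 25), rep(0.8, 25), seq(100, 340, by = 10))
  sel <- select_candidates(h)
  expect_identical(nrow(sel$hits), 20L)
  expect_false(sel$low_copy)
  expect_setequal(sel$hits$score, seq(150, 340, by = 10))
  # identity must be strictly greater than 0.70; ties at 0.70 excluded
  h2 <- make_hits(c(0.65, 0.70, 0.701, 0.9), rep(0.8, 4), rep(100, 4))
  sel2 <- select_candidates(h2)
  expect_identical(nrow(sel2$hits), 2L)
  expect_true(all(sel2$hits$identity > 0.70))
  # coverage strictly greater than 0.50
  h3 <- make_hits(rep(0.9, 3), c(0.50, 0.51, 0.8), rep(100, 3))
  expect_identical(nrow(select_candidates(h3)$hits), 2L)
  # fewer than 3 survivors: low copy
  h4 <- make_hits(c(0.9, 0.9, 0.6), rep(0.8, 3), rep(100, 3))
  expect_true(select_candidates(h4)$low_copy)
})

test_that("flank extension clamps at contig ends and honours strand", {
  set.seed(20)
  g <- prepare_genome(c(chr = random_dna(20000)))
  hits <- data.frame(contig = "ctg_0", s_start = c(5000L, 50L),
                     s_end = c(5500L, 550L), strand = c("+", "+"))
  ex <- extend_flanks(g, hits, 1000L)
  expect_identical(nchar(ex[[1]]), 2500L)
  expect_identical(as.character(ex[[1]]),
                   substr(g$contigs[["ctg_0"]], 4001, 6500))
  expect_identical(attr(ex[[1]], "core_start"), 1000L)
  expect_identical(attr(ex[[1]], "core_end"), 1500L)
  # left clamp: [0, 1550)
  expect_identical(nchar(ex[[2]]), 1550L)
  expect_identical(attr(ex[[2]], "core_start"), 50L)
  # minus strand extract is the reverse complement of the plus extract
  hm <- data.frame(contig = "ctg_0", s_start = 5000L, s_end = 5500L,
                   strand = "-")
  exm <- extend_flanks(g, hm, 1000L)
  expect_identical(as.character(exm[[1]]), revcomp(as.character(ex[[1]])))
  expect_identical(attr(exm[[1]], "core_start"), 1000L)
})

test_that("validation keeps true copies and discards unrelated sequence", {
  set.seed(21)
  init <- random_dna(800)
  true_extract <- paste0(random_dna(300), mutate_dna(init, 40),
                         random_dna(300))
  decoy <- random_dna(1400)
  kept <- validate_extended(list(true_extract, decoy), init)
  expect_identical(length(kept), 1L)
  expect_identical(as.character(kept[[1]]), true_extract)
})

test_that("mutual-support trimming removes unique host flanks", {
  set.seed(22)
  te <- random_dna(1200)
  copies <- lapply(1:4, function(i) {
    s <- paste0(random_dna(600), mutate_dna(te, 30), random_dna(600))
    attr(s, "core_start") <- 700L   # core = central chunk of the TE copy
    attr(s, "core_end") <- 1700L
    s
  })
  tr <- trim_to_mutual_support(copies)
  for (t in tr) {
    # host flanks (600 bp each side) removed up to small alignment overhang
    expect_lte(nchar(t), 1200 + 80)
    expect_gte(nchar(t), 1000)
  }
  # identical extracts: nothing trimmed
  same <- replicate(3, {
    s <- copies[[1]]
    s
  }, simplify = FALSE)
  tr2 <- trim_to_mutual_support(same)
  expect_true(all(vapply(tr2, nchar, integer(1)) == nchar(copies[[1]])))
  # single sequence: warning, unchanged
  expect_warning(tr3 <- trim_to_mutual_support(copies[1]), "fewer than 2")
  expect_identical(as.character(tr3[[1]]), as.character(copies[[1]]))
})

test_that("majority-rule consensus handles unanimity, plurality and columns", {
  # unanimity
  expect_identical(build_consensus(c("ACGT", "ACGT", "ACGT"), "ACGT"), "ACGT")
  # column-wise plurality
  expect_identical(build_consensus(c("ACGT", "ACGA", "ACGT"), "ACGT"), "ACGT")
  # a 5-base insertion present in one row only occupies single-nucleotide
  # columns and is removed
  set.seed(23)
  core <- random_dna(60)
  with_ins <- paste0(substr(core, 1, 30), "GGGGG", substr(core, 31, 60))
  out <- build_consensus(c(core, core, with_ins), core)
  expect_identical(out, core)
  # degenerate: fewer than two rows
  expect_error(build_consensus(list("ACGT"), "ACGT"), "at least 2")
})

test_that("iteration assessment: revert, done and continue boundaries", {
  set.seed(24)
  prev <- random_dna(2000)
  params <- beat_params(flank = 1000L)
  # growth 400 < 500: done
  new_done <- paste0(prev, random_dna(400))
  expect_identical(assess_iteration(new_done, prev, params)$verdict, "DONE")
  # growth 600 >= 500: continue
  new_more <- paste0(prev, random_dna(600))
  expect_identical(assess_iteration(new_more, prev, params)$verdict,
                   "CONTINUE")
  # shorter: revert
  expect_identical(assess_iteration(substr(prev, 1, 1500), prev,
                                    params)$verdict, "REVERT")
  # same length but covering only ~75% of prev: revert
  low_cov <- paste0(substr(prev, 1, 1500), random_dna(500))
  expect_identical(assess_iteration(low_cov, prev, params)$verdict, "REVERT")
})

test_that("full curation recovers a truncated consensus to family length", {
  set.seed(25)
  te <- random_dna(2000, gc = 0.45)
  fam <- data.frame(name = "fam1", classification = "LINE/L1",
                    sequence = te, copy_number = 12L, divergence_max = 0.08,
                    fragmented_fraction = 0, nested_fraction = 0)
  sim <- simulate_genome(sim_config(300000L, 0.42, fam, seed = 26L))
  seed_rec <- consensus_record("fam1", substr(te, 601, 1400), "LINE/L1")
  cur <- beat_curate(seed_rec, sim$genome)
  expect_identical(cur$status, "CURATED")
  expect_gte(nchar(cur$sequence), 0.95 * 2000)
  expect_lte(nchar(cur$sequence), 1.05 * 2000)
  expect_gte(cur$iterations_run, 1L)
  al <- pairwise_align(cur$sequence, te)
  expect_gt(al$identity, 0.95)
})

test_that("low-copy families are returned untouched", {
  set.seed(27)
  te <- random_dna(1000)
  fam <- data.frame(name = "fam1", classification = "DNA/hAT",
                    sequence = te, copy_number = 2L, divergence_max = 0.05,
                    fragmented_fraction = 0, nested_fraction = 0)
  sim <- simulate_genome(sim_config(100000L, 0.5, fam, seed = 28L))
  rec <- beat_curate(consensus_record("fam1", te, "DNA/hAT"), sim$genome)
  expect_identical(rec$status, "LOW_COPY")
  expect_identical(rec$sequence, te)
  expect_identical(rec$iterations_run, 0L)
})

test_that("tandem consensuses skip curation entirely", {
  set.seed(29)
  g <- prepare_genome(c(chr = random_dna(50000)))
  rec <- beat_curate(consensus_record("t", strrep("ACGGT", 300)), g)
  expect_identical(rec$status, "TANDEM")
  expect_identical(rec$iterations_run, 0L)
  expect_identical(nchar(rec$sequence), 1500L)
})

test_that("curation terminates within max_iterations", {
  set.seed(30)
  te <- random_dna(1500)
  fam <- data.frame(name = "f", classification = "LTR/Gypsy", sequence = te,
                    copy_number = 8L, divergence_max = 0.05,
                    fragmented_fraction = 0, nested_fraction = 0)
  sim <- simulate_genome(sim_config(150000L, 0.5, fam, seed = 31L))
  params <- beat_params(max_iterations = 2L)
  rec <- beat_curate(consensus_record("f", substr(te, 301, 900), "LTR/Gypsy"),
                     sim$genome, params)
  expect_lte(rec$iterations_run, 2L)
})
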