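test_that("a family-free genome matches its target GC within 1%", {
  cfg <- sim_config(100000L, gc = 0.58, seed = 70L)
  sim <- simulate_genome(cfg)
  expect_identical(sim$genome$total_length, 100000L)
  expect_identical(nrow(sim$reference), 0L)
  v <- strsplit(sim$genome$contigs[["ctg_0"]], "")[[1]]
  gc <- mean(v %in% c("G", "C"))
  expect_lt(abs(gc - 0.58), 0.01)
})

test_that("first-pass insertion counts equal configured copy numbers", {
  set.seed(71)
  fam <- data.frame(name = c("a", "b"), classification = c("LINE/L1", "DNA/hAT"),
                    sequence = c(random_dna(400), random_dna(600)),
                    copy_number = c(5L, 7L), divergence_max = 0.1,
                    fragmented_fraction = 0, nested_fraction = 0)
  sim <- simulate_genome(sim_config(100000L, 0.42, fam, seed = 72L))
  expect_identical(nrow(sim$reference), 12L)
  expect_identical(sum(sim$reference$family == "a"), 5L)
  expect_identical(sum(sim$reference$family == "b"), 7L)
  # substitution-only: genome length = base + inserted bp
  expect_identical(sim$genome$total_length,
                   100000L + sum(sim$reference$end - sim$reference$start))
})

test_that("realized divergence is uniform(0, max): mean near max/2", {
  set.seed(73)
  fam <- data.frame(name = "a", classification = "LINE/L1",
                    sequence = random_dna(1000), copy_number = 200L,
                    divergence_max = 0.20, fragmented_fraction = 0,
                    nested_fraction = 0)
  sim <- simulate_genome(sim_config(1500000L, 0.42, fam, seed = 74L))
  expect_identical(nrow(sim$reference), 200L)
  expect_gte(mean(sim$reference$divergence), 0.08)
  expect_lte(mean(sim$reference$divergence), 0.12)
})

test_that("recorded spans align to their source at the recorded divergence", {
  set.seed(75)
  te <- random_dna(800)
  fam <- data.frame(name = "a", classification = "LTR/Gypsy", sequence = te,
                    copy_number = 10L, divergence_max = 0.15,
                    fragmented_fraction = 0, nested_fraction = 0)
  sim <- simulate_genome(sim_config(200000L, 0.5, fam, seed = 76L))
  for (i in seq_len(5)) {
    r <- sim$reference[i, ]
    seg <- substr(sim$genome$contigs[["ctg_0"]], r$start + 1, r$end)
    al <- pairwise_align(seg, te)
    expect_lt(abs((1 - al$identity) - r$divergence), 0.02)
  }
})

test_that("mutate_copy: divergence 0 is identity; ts:tv is about 2:1", {
  set.seed(77)
  s <- random_dna(5000)
  m0 <- mutate_copy(s, 0)
  expect_identical(m0$sequence, s)
  expect_identical(m0$p_distance, 0)
  m <- mutate_copy(s, 0.10, seed = 78L)
  expect_gte(m$p_distance, 0.08)
  expect_lte(m$p_distance, 0.12)
  v0 <- strsplit(s, "")[[1]]
  v1 <- strsplit(m$sequence, "")[[1]]
  ch <- which(v0 != v1)
  is_ts <- (v0[ch] == "A" & v1[ch] == "G") | (v0[ch] == "G" & v1[ch] == "A") |
    (v0[ch] == "C" & v1[ch] == "T") | (v0[ch] == "T" & v1[ch] == "C")
  ratio <- sum(is_ts) / sum(!is_ts)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("copy numbers are normal draws clamped to [5, 732]", {
  x <- sample_copy_numbers(10000, seed = 79L)
  expect_true(all(x >= 5 & x <= 732))
  expect_identical(x, sample_copy_numbers(10000, seed = 79L))
  # unimodal bulk: most mass strictly inside the clamps
  expect_gt(mean(x > 5 & x < 732), 0.8)
  # direct normal-sampling oracle for the interior mean
  set.seed(79)
  y <- pmin(pmax(round(rnorm(10000, 150, 120)), 5), 732)
  expect_equal(mean(x), mean(y), tolerance = 0.05)
})

test_that("fragmented copies are truncated, nested copies carry parents", {
  set.seed(80)
  te <- random_dna(1000)
  fam <- data.frame(name = "a", classification = "LINE/L1", sequence = te,
                    copy_number = 20L, divergence_max = 0.05,
                    fragmented_fraction = 0.5, nested_fraction = 0.2)
  sim <- simulate_genome(sim_config(300000L, 0.42, fam, seed = 81L))
  ref <- sim$reference
  expect_identical(sum(ref$fragmented), 10L)
  expect_identical(sum(ref$nested), 4L)
  # spans of hosts stretch to include nested children; check pure fragments
  pure <- ref$fragmented & !(ref$id %in% ref$parent_id)
  frag_len <- ref$end[pure] - ref$start[pure]
  expect_true(all(frag_len < 1000))
  expect_true(all(frag_len >= 100 - 1))  # at most 90% removed
  # every nested copy names an existing first-pass parent that contains it
  kids <- ref[ref$nested, ]
  for (i in seq_len(nrow(kids))) {
    host <- ref[ref$id == kids$parent_id[i], ]
    expect_identical(nrow(host), 1L)
    expect_false(host$nested)
    expect_lte(host$start, kids$start[i])
    expect_gte(host$end, kids$end[i])
  }
})

test_that("the same seed reproduces genome and reference exactly", {
  fam <- data.frame(name = "a", classification = "DNA/hAT",
                    sequence = "ACGTACGTACGTACGTACGTACGTACGTACGT",
                    copy_number = 6L, divergence_max = 0.2,
                    fragmented_fraction = 0.5, nested_fraction = 0.3)
  cfg <- sim_config(50000L, 0.42, fam, seed = 82L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome$contigs, s2$genome$contigs)
  expect_identical(s1$reference, s2$reference)
})
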