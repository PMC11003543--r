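test_that("a perfect short-period tandem is detected end to end", {
  p <- detect_tandem(strrep("ACGT", 50))
  expect_gte(p$tandem_fraction, 0.95)
  expect_identical(p$longest$period, 4L)
})

test_that("uniform random sequence has near-zero tandem content", {
  set.seed(3)
  s <- random_dna(1000)
  p <- detect_tandem(s)
  expect_lt(p$tandem_fraction, 0.1)
  expect_lt(oracle_tandem_fraction(s), 0.1)
})

test_that("composite sequence: fraction matches construction and oracle", {
  set.seed(5)
  s <- paste0(random_dna(400), strrep("AT", 150))
  p <- detect_tandem(s)
  expect_equal(p$tandem_fraction, 300 / 700, tolerance = 0.03)
  expect_identical(p$longest$period, 2L)
  expect_gte(p$longest$start, 390L)  # region sits in the second half
  expect_equal(oracle_tandem_fraction(s), 300 / 700, tolerance = 0.05)
})

test_that("reported regions are re-verifiable at 75% shifted self-identity", {
  set.seed(6)
  for (rep in 1:5) {
    unit <- random_dna(sample(3:40, 1))
    s <- paste0(random_dna(200),
                strrep(unit, ceiling(400 / nchar(unit))),
                random_dna(200))
    p <- detect_tandem(s)
    expect_gte(nrow(p$regions), 1L)
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(nrow(p$regions))) {
      r <- p$regions[i, ]
      idx <- (r$start + 1):(r$end - r$period)
      frac <- mean(v[idx] == v[idx + r$period])
      expect_gte(frac, 0.75)
      expect_gte(r$end - r$start, r$period)
    }
  }
})

test_that("detect_tandem is deterministic", {
  set.seed(8)
  s <- paste0(random_dna(300), strrep("ACGGT", 60), random_dna(300))
  expect_identical(detect_tandem(s), detect_tandem(s))
})

test_that("triage thresholds are strict at 0.90 and 0.50", {
  seqlen <- 1000L
  seqstr <- strrep("A", seqlen)
  rec <- consensus_record("x", seqstr)
  reg <- function(e) data.frame(start = 0L, end = e, period = 5L,
                                identity = 0.95)
  # > 0.90: tandem, sequence untouched
  r <- triage_consensus(rec, fake_profile(seqlen, reg(905L)))
  expect_identical(r$status, "TANDEM")
  expect_identical(nchar(r$sequence), seqlen)
  # exactly 0.90 is NOT ">90%": longest non-tandem section extracted
  r <- triage_consensus(rec, fake_profile(seqlen, reg(900L)))
  expect_identical(r$status, "CURATED")
  expect_identical(nchar(r$sequence), 100L)
  # 0.70: extraction of the longest non-tandem run
  r <- triage_consensus(rec, fake_profile(
    seqlen, data.frame(start = 300L, end = 1000L, period = 5L,
                       identity = 0.9)))
  expect_identical(r$status, "CURATED")
  expect_identical(nchar(r$sequence), 300L)
  # exactly 0.50 proceeds to curation (status stays RAW)
  r <- triage_consensus(rec, fake_profile(seqlen, reg(500L)))
  expect_identical(r$status, "RAW")
  expect_identical(nchar(r$sequence), seqlen)
  # 0.30: untouched
  r <- triage_consensus(rec, fake_profile(seqlen, reg(300L)))
  expect_identical(r$status, "RAW")
})

test_that("the 50-90% rule extracts the longest non-tandem section", {
  # tandem regions [0,300) and [650,1000): longest free run is [300,650)
  prof <- fake_profile(1000L, data.frame(start = c(0L, 650L),
                                         end = c(300L, 1000L),
                                         period = c(4L, 4L),
                                         identity = c(0.9, 0.9)))
  set.seed(9)
  s <- random_dna(1000)
  r <- triage_consensus(consensus_record("x", s), prof)
  expect_identical(r$status, "CURATED")
  expect_identical(r$sequence, substr(s, 301, 650))
})

test_that("macrosatellites are trimmed to one period; period < 200 is not", {
  set.seed(7)
  unit <- random_dna(250)
  mac <- classify_satellites(consensus_record("m", strrep(unit, 10)))
  expect_identical(mac$status, "MACROSATELLITE")
  expect_identical(nchar(mac$sequence), 250L)
  expect_identical(mac$sequence, unit)  # first full unit of the region
  set.seed(8)
  unit2 <- random_dna(150)
  sat <- classify_satellites(consensus_record("s", strrep(unit2, 20)))
  expect_false(sat$status == "MACROSATELLITE")
  expect_true(sat$satellite)
  expect_identical(nchar(sat$sequence), 3000L)
  # below every threshold: unflagged, unchanged
  set.seed(9)
  plain <- classify_satellites(consensus_record("p", random_dna(800)))
  expect_false(plain$satellite)
  expect_identical(nchar(plain$sequence), 800L)
})

test_that("macrosatellite boundary sits exactly at period 200", {
  set.seed(10)
  s <- strrep("A", 2500)
  reg <- function(p) fake_profile(2500L, data.frame(
    start = 0L, end = 2500L, period = p, identity = 0.98))
  r200 <- classify_satellites(consensus_record("a", s), reg(200L))
  expect_identical(r200$status, "MACROSATELLITE")
  expect_identical(nchar(r200$sequence), 200L)
  r199 <- classify_satellites(consensus_record("b", s), reg(199L))
  expect_false(r199$status == "MACROSATELLITE")
})
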