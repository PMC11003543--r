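test_that("prepare_genome sanitizes headers, case and ambiguity codes", {
  g <- prepare_genome(c(">chr1 assembly=xyz" = "acgtR", "s2" = "NNGT",
                        "s3" = "acgtacgt"))
  expect_s3_class(g, "GenomeAssembly")
  expect_identical(names(g$contigs), c("ctg_0", "ctg_1", "ctg_2"))
  expect_identical(unname(g$contigs[["ctg_0"]]), "ACGTN")
  expect_identical(unname(g$header_map[["ctg_0"]]), ">chr1 assembly=xyz")
  expect_identical(g$total_length, 17L)
  # every ambiguity code becomes N, length preserved
  amb <- prepare_genome(c(x = "ARYSWKMBDHVT"))
  expect_identical(unname(amb$contigs[["ctg_0"]]), "ANNNNNNNNNNT")
  expect_identical(nchar(amb$contigs[["ctg_0"]]), 12L)
})

test_that("prepare_genome rejects bad input", {
  expect_error(prepare_genome(character(0)), "no input")
  expect_error(prepare_genome(c(a = "ACGT", a = "GGCC")), "duplicate.*a")
  expect_error(prepare_genome(c(a = "")), "empty")
})

test_that("FASTA round-trips through 60-column output", {
  tmp <- tempfile(fileext = ".fa")
  set.seed(1)
  seqs <- c(one = random_dna(150), `two desc here` = random_dna(59),
             three = random_dna(60))
  write_fasta(seqs, tmp)
  back <- read_fasta(tmp)
  expect_identical(unname(back), unname(seqs))
  expect_identical(names(back), names(seqs))
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(tmp)) <= 60))
})

test_that("GFF3 read/write round-trips and converts coordinates", {
  tmp <- tempfile(fileext = ".gff3")
  set.seed(2)
  n <- 25
  starts <- sample.int(5000, n)
  df <- annotations(contig = sample(c("ctg_0", "ctg_1"), n, TRUE),
                    start = starts, end = starts + sample.int(500, n),
                    strand = sample(c("+", "-"), n, TRUE),
                    family = sprintf("fam%02d", sample.int(8, n, TRUE)),
                    classification = sample(c("LINE/L1", "DNA/hAT", "Unknown"),
                                            n, TRUE),
                    divergence = round(runif(n), 6),
                    score = as.numeric(sample.int(1000, n)))
  write_annotations(df, tmp, "gff3")
  back <- read_annotations(tmp, "gff3")
  back <- back[order(back$contig, back$start, back$end), ]
  dfo <- df[order(df$contig, df$start, df$end), ]
  for (col in c("contig", "start", "end", "strand", "family",
                "classification", "divergence", "score"))
    expect_equal(back[[col]], dfo[[col]], ignore_attr = TRUE)
  # 1-based inclusive on disk
  line1 <- strsplit(grep("^[^#]", readLines(tmp), value = TRUE)[1], "\t")[[1]]
  first <- df[1, ]
  expect_identical(as.integer(line1[4]), first$start + 1L)
  expect_identical(as.integer(line1[5]), first$end)
})

test_that("BED read/write round-trips BED-representable fields", {
  tmp <- tempfile(fileext = ".bed")
  df <- annotations(contig = "ctg_0", start = c(0L, 100L), end = c(100L, 300L),
                    strand = c("+", "-"), family = c("famA", "famB"),
                    classification = c("LTR/Gypsy", "Unknown"),
                    score = c(10, 20))
  write_annotations(df, tmp, "bed")
  back <- read_annotations(tmp, "bed")
  for (col in c("contig", "start", "end", "strand", "family",
                "classification", "score"))
    expect_equal(back[[col]], df[[col]], ignore_attr = TRUE)
})

test_that("empty annotation sets write valid header-only files", {
  for (fmt in c("gff3", "bed")) {
    tmp <- tempfile()
    write_annotations(annotations(), tmp, fmt)
    expect_identical(nrow(read_annotations(tmp, fmt)), 0L)
  }
})

test_that("RepeatMasker .out rows convert to half-open coordinates", {
  tmp <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat class/family begin end (left) ID",
    "",
    " 1203 12.5  0.1  0.2  ctg_0  11 20 (980) + famA LINE/L1 1 10 (0) 1",
    "  800  5.0  0.0  0.0  ctg_0  51 80 (920) C famB DNA/hAT 1 30 (0) 2"),
    tmp)
  df <- read_annotations(tmp, "rmout")
  expect_identical(df$start, c(10L, 50L))
  expect_identical(df$end, c(20L, 80L))
  expect_identical(df$end[1] - df$start[1], 10L)
  expect_identical(df$strand, c("+", "-"))
  expect_identical(df$family, c("famA", "famB"))
  expect_equal(df$divergence, c(0.125, 0.05))
})

test_that("malformed annotation lines raise errors naming the line", {
  tmp <- tempfile()
  writeLines(c("##gff-version 3", "ctg_0\tsrc\tdispersed_repeat\tx\t100"), tmp)
  expect_error(read_annotations(tmp, "gff3"), "line 2")
  writeLines("ctg_0\t100", tmp)
  expect_error(read_annotations(tmp, "bed"), "malformed")
})

test_that("library FASTA parses the name#classification convention", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">famA#LINE/L1", "ACGTACGTACGT", ">famB", "GGCCGGCC"), tmp)
  lib <- read_library(tmp)
  expect_identical(lib[[1]]$id, "famA")
  expect_identical(lib[[1]]$classification, "LINE/L1")
  expect_identical(lib[[2]]$classification, "Unknown")
  expect_identical(lib[[1]]$status, "RAW")
  out <- tempfile(fileext = ".fa")
  write_library(lib, out)
  expect_match(readLines(out)[1], "^>famA#LINE/L1 status=RAW")
})

test_that("consensus record status transitions are guarded", {
  r <- consensus_record("x", "ACGT")
  r2 <- tecurator:::set_status(r, "CURATED")
  expect_identical(r2$status, "CURATED")
  expect_error(tecurator:::set_status(r2, "TANDEM"), "transition")
})
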