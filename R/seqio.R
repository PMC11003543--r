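# Sequence and annotation input/output. Internal coordinates are 0-based
# half-open everywhere; GFF3 and RepeatMasker 1-based inclusive conventions
# are converted at the I/O boundary only.

AMBIGUOUS_IUPAC <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                     "r", "y", "s", "w", "k", "m", "b", "d", "h", "v")

#' Prepare a genome assembly for analysis
#'
#' Replaces FASTA headers with generic `ctg_<n>` identifiers (0-based, in
#' input order), upper-folds sequences, and replaces ambiguous IUPAC codes
#' (R, Y, S, W, K, M, B, D, H, V) with `N`. The original headers are retained
#' in a bijective map so they can be restored.
#'
#' @param raw_records named character vector of nucleotide sequences; names
#'   are the original FASTA headers (without the leading `>`).
#' @return a `GenomeAssembly`: list with `contigs` (named character vector,
#'   names `ctg_0`, `ctg_1`, ...), `header_map` (sanitized id -> original
#'   header), and `total_length` (bp).
#' @export
prepare_genome <- function(raw_records) {
  if (length(raw_records) == 0) stop("prepare_genome: no input records")
  headers <- names(raw_records)
  if (is.null(headers) || any(is.na(headers)) || any(headers == ""))
    stop("prepare_genome: every record needs a header")
  dup <- headers[duplicated(headers)]
  if (length(dup) > 0)
    stop("prepare_genome: duplicate header: ", dup[[1]])
  if (any(nchar(raw_records) == 0)) stop("prepare_genome: empty sequence")
  seqs <- toupper(as.character(raw_records))
  # ambiguous IUPAC -> N (keeps A, C, G, T, N)
  seqs <- chartr(paste(toupper(AMBIGUOUS_IUPAC[1:10]), collapse = ""),
                 strrep("N", 10), seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("prepare_genome: non-nucleotide symbol in record ",
         headers[which(bad)[1]])
  ids <- paste0("ctg_", seq_along(seqs) - 1L)
  genome_assembly(setNames(seqs, ids), setNames(headers, ids))
}

genome_assembly <- function(contigs, header_map = NULL) {
  if (is.null(header_map)) header_map <- setNames(names(contigs), names(contigs))
  structure(list(contigs = contigs, header_map = header_map,
                 total_length = sum(nchar(contigs))),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$contigs), "contig(s),",
      x$total_length, "bp\n")
  invisible(x)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (optionally gzipped).
#' @return named character vector; names are full header lines.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1L, n, by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, n)), con)
    }
  }
  invisible(path)
}

# ---- annotations ----------------------------------------------------------

ANNOT_COLS <- c("contig", "start", "end", "strand", "family",
                "classification", "divergence", "score")

#' Construct an annotation table
#'
#' Annotations are plain data frames with 0-based half-open coordinates and
#' columns `contig`, `start`, `end`, `strand`, `family`, `classification`,
#' `divergence`, `score` (the last two may be `NA`). Extra columns are kept.
#'
#' @param contig,start,end,strand,family,classification,divergence,score
#'   vectors recycled to a common length.
#' @param ... further columns (e.g. `group_id`).
#' @return data.frame of annotations.
#' @export
annotations <- function(contig = character(), start = integer(),
                        end = integer(), strand = "+", family = "repeat",
                        classification = "Unknown", divergence = NA_real_,
                        score = NA_real_, ...) {
  n <- max(length(contig), length(start), length(end))
  rec <- function(x, as_fun) if (n == 0) as_fun(character(0)) else
    rep_len(as_fun(x), n)
  df <- data.frame(contig = rec(contig, as.character),
                   start = rec(start, as.integer),
                   end = rec(end, as.integer),
                   strand = rec(strand, as.character),
                   family = rec(family, as.character),
                   classification = rec(classification, as.character),
                   divergence = rec(divergence, as.numeric),
                   score = rec(score, as.numeric),
                   ..., stringsAsFactors = FALSE)
  validate_annotations(df)
  df
}

validate_annotations <- function(df) {
  stopifnot(all(ANNOT_COLS %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$end <= df$start)) stop("annotation with end <= start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

sort_annotations <- function(df) {
  df[order(df$contig, df$start, df$end), , drop = FALSE]
}

split_class <- function(x) {
  # "name#Class/Family" convention: text after '#' is the classification
  has <- grepl("#", x, fixed = TRUE)
  fam <- ifelse(has, sub("#.*$", "", x), x)
  cls <- ifelse(has, sub("^[^#]*#", "", x), "Unknown")
  list(family = fam, classification = cls)
}

top_class <- function(classification) sub("/.*$", "", classification)

#' Read annotations from GFF3, BED or RepeatMasker-style tables
#'
#' GFF3 and RepeatMasker `.out` coordinates (1-based inclusive) are converted
#' to the internal 0-based half-open convention; BED passes through.
#'
#' @param path input file.
#' @param format one of `"gff3"`, `"bed"`, `"rmout"`.
#' @return annotation data frame (see [annotations()]).
#' @export
read_annotations <- function(path, format = c("gff3", "bed", "rmout")) {
  format <- match.arg(format)
  lines <- readLines(path)
  switch(format,
         gff3 = parse_gff3(lines),
         bed = parse_bed(lines),
         rmout = parse_rmout(lines))
}

parse_gff3 <- function(lines) {
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GFF3 line ", i)
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) stop("malformed GFF3 line ", i)
    if (end1 < start1) stop("GFF3 end < start at line ", i)
    attrs <- parse_gff3_attrs(f[9])
    c(list(contig = f[1], start = start1 - 1L, end = end1,
           strand = if (f[7] %in% c("+", "-")) f[7] else "+",
           score = if (f[6] == ".") NA_real_ else as.numeric(f[6])),
      attrs)
  })
  rows_to_annotations(rows)
}

parse_gff3_attrs <- function(s) {
  if (s == "." || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) != 2) next
    out[[p[1]]] <- utils::URLdecode(p[2])
  }
  out
}

parse_bed <- function(lines) {
  keep <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed BED line ", i)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) stop("malformed BED line ", i)
    if (end < start) stop("BED end < start at line ", i)
    name <- if (length(f) >= 4) f[4] else "repeat"
    sc <- split_class(name)
    list(contig = f[1], start = start, end = end,
         strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "+",
         family = sc$family, classification = sc$classification,
         score = if (length(f) >= 5 && f[5] != ".")
           suppressWarnings(as.numeric(f[5])) else NA_real_)
  })
  rows_to_annotations(rows)
}

parse_rmout <- function(lines) {
  # RepeatMasker .out: 3 header lines, whitespace-delimited records
  body <- lines[-seq_len(min(3L, length(lines)))]
  keep <- which(nzchar(trimws(body)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 13) stop("malformed RepeatMasker line ", i + 3L)
    begin <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end1)) stop("malformed RepeatMasker line ", i + 3L)
    if (end1 < begin) stop("RepeatMasker end < begin at line ", i + 3L)
    list(contig = f[5], start = begin - 1L, end = end1,
         strand = if (f[9] == "C") "-" else "+",
         family = f[10], classification = f[11],
         divergence = suppressWarnings(as.numeric(f[2])) / 100,
         score = suppressWarnings(as.numeric(f[1])))
  })
  rows_to_annotations(rows)
}

rows_to_annotations <- function(rows) {
  if (length(rows) == 0) return(annotations())
  keys <- unique(unlist(lapply(rows, names)))
  cols <- lapply(keys, function(k)
    unlist(lapply(rows, function(r) if (is.null(r[[k]])) NA else r[[k]])))
  df <- as.data.frame(setNames(cols, keys), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  for (k in c("family", "classification"))
    if (is.null(df[[k]])) df[[k]] <- if (k == "family") "repeat" else "Unknown"
  for (k in c("divergence", "score"))
    df[[k]] <- if (is.null(df[[k]])) NA_real_ else
      suppressWarnings(as.numeric(df[[k]]))
  for (k in c("fragmented", "nested"))
    if (!is.null(df[[k]])) df[[k]] <- as.logical(df[[k]])
  front <- intersect(ANNOT_COLS, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  validate_annotations(df)
  df
}

#' Write annotations to GFF3 or BED
#'
#' GFF3 output uses 1-based inclusive coordinates, source `te-curator`, type
#' `dispersed_repeat`, and carries `ID`, `family`, `classification` and (when
#' present) `divergence` plus any extra columns as attributes. BED6 output is
#' 0-based half-open with name `family#classification`.
#'
#' @param df annotation data frame.
#' @param path output file.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_annotations <- function(df, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  validate_annotations(df)
  if (format == "gff3") {
    extra <- setdiff(names(df), c(ANNOT_COLS, "id"))
    attr_str <- vapply(seq_len(nrow(df)), function(i) {
      a <- c(ID = if (!is.null(df$id)) df$id[i] else
               sprintf("te_%06d", i),
             family = df$family[i],
             classification = df$classification[i])
      if (!is.na(df$divergence[i]))
        a <- c(a, divergence = format(df$divergence[i], digits = 10))
      for (k in extra) {
        v <- df[[k]][i]
        if (!is.na(v)) a <- c(a, setNames(as.character(v), k))
      }
      paste(paste0(names(a), "=", a), collapse = ";")
    }, character(1))
    body <- if (nrow(df) == 0) character() else
      paste(df$contig, "te-curator", "dispersed_repeat",
            df$start + 1L, df$end,
            ifelse(is.na(df$score), ".", format(df$score, digits = 10)),
            df$strand, ".", attr_str, sep = "\t")
    writeLines(c("##gff-version 3", body), path)
  } else {
    body <- if (nrow(df) == 0) character() else
      paste(df$contig, df$start, df$end,
            paste0(df$family, "#", df$classification),
            ifelse(is.na(df$score), "0", format(df$score, digits = 10)),
            df$strand, sep = "\t")
    writeLines(c("#contig\tstart\tend\tname\tscore\tstrand", body), path)
  }
  invisible(path)
}

# ---- consensus records ----------------------------------------------------

CONSENSUS_STATUSES <- c("RAW", "CURATED", "TANDEM", "MACROSATELLITE", "LOW_COPY")

#' Create a TE consensus record
#'
#' @param id family identifier.
#' @param sequence consensus nucleotide sequence.
#' @param classification TE classification label (e.g. `LINE/L1`).
#' @param status curation status; new records start `RAW`.
#' @return a `ConsensusRecord` (list with class attribute).
#' @export
consensus_record <- function(id, sequence, classification = "Unknown",
                             status = "RAW") {
  stopifnot(nchar(sequence) > 0, status %in% CONSENSUS_STATUSES)
  structure(list(id = id, classification = classification,
                 sequence = toupper(sequence), status = status,
                 iterations_run = 0L, satellite = FALSE),
            class = "ConsensusRecord")
}

set_status <- function(record, status) {
  stopifnot(status %in% CONSENSUS_STATUSES)
  if (record$status != "RAW" && record$status != status)
    stop("invalid status transition ", record$status, " -> ", status)
  record$status <- status
  record
}

#' @export
print.ConsensusRecord <- function(x, ...) {
  cat(sprintf("ConsensusRecord %s#%s [%s] %d bp, %d iteration(s)\n",
              x$id, x$classification, x$status, nchar(x$sequence),
              x$iterations_run))
  invisible(x)
}

#' Read a TE library FASTA into a list of consensus records
#'
#' Headers follow the `name#Class/Family` convention; a missing `#` token
#' yields classification `Unknown`.
#'
#' @param path FASTA file.
#' @return list of [consensus_record()] objects.
#' @export
read_library <- function(path) {
  seqs <- read_fasta(path)
  ids <- sub("\\s.*$", "", names(seqs))
  sc <- split_class(ids)
  lapply(seq_along(seqs), function(i)
    consensus_record(sc$family[i], seqs[[i]], sc$classification[i]))
}

#' Write a TE library to FASTA
#'
#' Headers are `name#classification status=<status> iterations=<n>`.
#'
#' @param library list of consensus records.
#' @param path output file.
#' @export
write_library <- function(library, path) {
  seqs <- vapply(library, function(r) r$sequence, character(1))
  names(seqs) <- vapply(library, function(r)
    sprintf("%s#%s status=%s iterations=%d", r$id, r$classification,
            r$status, r$iterations_run), character(1))
  write_fasta(seqs, path)
}
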