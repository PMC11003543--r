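# End-to-end orchestration: prepare -> triage/curate -> (cluster) ->
# annotate -> defragment -> resolve overlaps -> (length filter) ->
# divergences -> summaries, written to an output directory.

#' Run the full curation and annotation pipeline
#'
#' De novo family discovery is out of scope, so a starting library is a
#' required input. Stages: genome preparation, tandem triage plus iterative
#' consensus curation of every `RAW` record, optional 80/80 clustering,
#' library-based annotation, defragmentation, overlap resolution, optional
#' <`min_length` filter, per-annotation Kimura divergences, and summary
#' tables. Results land in `out_dir/summaryFiles/`.
#'
#' @param genome a `GenomeAssembly`, named character vector of sequences, or
#'   path to a FASTA file.
#' @param library list of consensus records or path to a library FASTA with
#'   `name#Class/Family` headers.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param curate run iterative consensus curation?
#' @param cluster cluster the curated library at 80/80? (default off)
#' @param min_length_filter remove annotations under `min_length` bp?
#' @param min_length length filter threshold, bp.
#' @param softmask write a softmasked genome FASTA?
#' @param ltr_intervals optional full-length-LTR intervals for defragmentation
#'   (data frame or BED path).
#' @param params [beat_params()].
#' @param ep [engine_params()].
#' @param verbose print stage progress?
#' @return (invisibly) list with `genome`, `library`, `annotations`,
#'   `summaries` and the output paths.
#' @export
run_pipeline <- function(genome, library, out_dir = NULL,
                         curate = TRUE, cluster = FALSE,
                         min_length_filter = FALSE, min_length = 100L,
                         softmask = FALSE, ltr_intervals = NULL,
                         params = beat_params(), ep = engine_params(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  if (!inherits(genome, "GenomeAssembly")) genome <- prepare_genome(genome)
  if (is.character(library) && length(library) == 1) {
    library <- read_library(library)
  }
  if (is.character(ltr_intervals))
    ltr_intervals <- read_annotations(ltr_intervals, "bed")
  say("prepared genome: %d contig(s), %d bp", length(genome$contigs),
      genome$total_length)

  if (curate) {
    library <- curate_library(library, genome, params, ep)
    say("curated %d consensus record(s)", length(library))
  }
  if (cluster) {
    library <- cluster_library(library, ep = ep)
    say("clustered library to %d representative(s)", length(library))
  }
  usable <- Filter(function(r) r$status != "TANDEM", library)
  if (length(usable) == 0) stop("no usable consensus records after triage")

  annots <- annotate_genome(genome, usable, ep = ep)
  say("raw annotations: %d", nrow(annots))
  annots <- defragment(annots, ltr_intervals = ltr_intervals)
  annots <- resolve_overlaps(annots)
  annots <- length_filter(annots, min_length, enabled = min_length_filter)
  say("refined annotations: %d", nrow(annots))
  summaries <- summarize_annotations(annots, genome)

  paths <- NULL
  if (!is.null(out_dir)) {
    sumdir <- file.path(out_dir, "summaryFiles")
    dir.create(sumdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gff3 = file.path(sumdir, "annotations.gff3"),
      bed = file.path(sumdir, "annotations.bed"),
      library = file.path(sumdir, "library.fa"),
      pie = file.path(sumdir, "summary_pie.tsv"),
      families = file.path(sumdir, "family_summary.tsv"),
      landscape = file.path(sumdir, "landscape.tsv"))
    write_annotations(annots, paths$gff3, "gff3")
    write_annotations(annots, paths$bed, "bed")
    write_library(library, paths$library)
    write_tsv <- function(df, path)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    write_tsv(summaries$pie, paths$pie)
    write_tsv(summaries$families, paths$families)
    write_tsv(summaries$landscape, paths$landscape)
    if (softmask) {
      masked <- mask_genome(genome, annots, "soft")
      paths$softmasked <- file.path(sumdir, "genome.softmasked.fa")
      write_fasta(masked$contigs, paths$softmasked)
    }
  }
  say("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(genome = genome, library = library, annotations = annots,
                 summaries = summaries, paths = paths))
}
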