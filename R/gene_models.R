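# Core data model: genomes, coding-exon gene models, CDS assembly,
# translation, and exon-border/split-codon architecture.

#' Construct a genome object
#'
#' A genome is a named set of nucleotide sequences (chromosomes, scaffolds).
#' Sequences are upper-cased and validated against the A/C/G/T/N alphabet.
#'
#' @param records named character vector or list, sequence id -> nucleotide
#'   string.
#' @return an object of class `genome` (named character vector).
#' @examples
#' g <- genome(c(chr1 = "ATGAAATAG"))
#' @export
genome <- function(records) {
  records <- unlist(records)
  if (length(records) == 0L) stop("genome needs at least one sequence")
  ids <- names(records)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("genome sequences must carry unique non-empty ids")
  }
  if (any(nchar(records) == 0L)) stop("genome sequences must be non-empty")
  records <- norm_dna(records, "genome sequence")
  structure(records, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "sequence(s),",
      sum(nchar(x)), "nt total\n")
  invisible(x)
}

#' Construct a coding exon
#'
#' Coordinates are 0-based half-open on the forward genome strand, matching
#' the package's internal convention (GFF3 I/O converts to 1-based
#' inclusive).
#'
#' @param seq_id genome sequence id.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return a `coding_exon` list.
#' @export
coding_exon <- function(seq_id, start, end, strand) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid exon interval [", start, ",", end, ")")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "coding_exon")
}

exon_length <- function(e) e$end - e$start

#' Construct a gene model
#'
#' A gene model holds one or more transcripts, each an ordered list of
#' coding exons in transcription (5' to 3') order: ascending genomic
#' coordinates on the plus strand, descending on the minus strand. All exons
#' of one transcript must lie on one sequence and strand and must not
#' overlap.
#'
#' @param gene_id gene identifier.
#' @param species_id species identifier.
#' @param family_label free-text family/paralog label (e.g. `"GNAI1"`).
#' @param transcripts named list, transcript id -> list of [coding_exon()].
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, species_id, family_label, transcripts) {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L)
  tids <- names(transcripts)
  if (is.null(tids) || any(tids == "") || anyDuplicated(tids)) {
    stop("transcripts must carry unique names")
  }
  for (tid in tids) {
    exons <- transcripts[[tid]]
    if (length(exons) == 0L) stop("transcript ", tid, " has no exons")
    seqs <- vapply(exons, `[[`, "", "seq_id")
    strands <- vapply(exons, `[[`, "", "strand")
    if (length(unique(seqs)) != 1L || length(unique(strands)) != 1L) {
      stop("transcript ", tid, " mixes sequences or strands")
    }
    starts <- vapply(exons, `[[`, 0L, "start")
    ends <- vapply(exons, `[[`, 0L, "end")
    ord <- order(starts)
    if (any(ends[ord][-length(ord)] > starts[ord][-1L])) {
      stop("transcript ", tid, " has overlapping exons")
    }
    expect <- if (strands[1] == "+") seq_along(starts) else rev(seq_along(starts))
    if (!identical(order(starts), expect)) {
      stop("transcript ", tid,
           " exon order is not transcription order for strand ", strands[1])
    }
  }
  structure(list(gene_id = gene_id, species_id = species_id,
                 family_label = family_label, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  nex <- vapply(x$transcripts, length, 0L)
  cat("gene_model ", x$gene_id, " (", x$species_id, ", ", x$family_label,
      "): ", length(x$transcripts), " transcript(s), ",
      paste(nex, collapse = "/"), " exon(s)\n", sep = "")
  invisible(x)
}

get_transcript <- function(model, transcript_id) {
  if (is.null(transcript_id)) transcript_id <- names(model$transcripts)[1]
  exons <- model$transcripts[[transcript_id]]
  if (is.null(exons)) {
    stop("unknown transcript '", transcript_id, "' in gene ", model$gene_id)
  }
  list(id = transcript_id, exons = exons)
}

#' Assemble the coding sequence of a transcript
#'
#' Exon substrings are extracted from the genome and concatenated in
#' transcription order; minus-strand exons are reverse-complemented. The
#' result is flagged `complete` when it starts with ATG, ends with a stop
#' codon, has length divisible by 3 and contains no internal stop.
#'
#' @param model a [gene_model()].
#' @param genome a [genome()].
#' @param transcript_id transcript to assemble; defaults to the first.
#' @return a `cds_record` list with fields `gene_id`, `transcript_id`,
#'   `sequence`, `complete`, and the individual completeness checks.
#' @export
assemble_cds <- function(model, genome, transcript_id = NULL) {
  tr <- get_transcript(model, transcript_id)
  parts <- character(length(tr$exons))
  for (i in seq_along(tr$exons)) {
    e <- tr$exons[[i]]
    chrom <- genome[[e$seq_id]]
    if (is.null(chrom) || is.na(chrom)) {
      stop("exon ", i, " of ", tr$id, ": unknown sequence '", e$seq_id, "'")
    }
    if (e$end > nchar(chrom)) {
      stop("exon ", i, " of ", tr$id, " [", e$start, ",", e$end,
           ") exceeds sequence '", e$seq_id, "' length ", nchar(chrom))
    }
    s <- substr(chrom, e$start + 1L, e$end)
    parts[i] <- if (e$strand == "-") revcomp(s) else s
  }
  seqs <- paste(parts, collapse = "")
  n <- nchar(seqs)
  frame_ok <- n %% 3L == 0L && n >= 6L
  starts_atg <- frame_ok && substr(seqs, 1L, 3L) == "ATG"
  ends_stop <- frame_ok && substr(seqs, n - 2L, n) %in% STOP_CODONS
  internal_stop <- FALSE
  if (frame_ok) {
    aa <- codon_translate(seqs)
    internal_stop <- any(aa[-length(aa)] == "*")
  }
  structure(list(gene_id = model$gene_id, transcript_id = tr$id,
                 sequence = seqs,
                 frame_ok = frame_ok, starts_atg = starts_atg,
                 ends_stop = ends_stop, internal_stop = internal_stop,
                 complete = frame_ok && starts_atg && ends_stop &&
                   !internal_stop),
            class = "cds_record")
}

#' Derive the exon-border architecture of a transcript
#'
#' Internal exon borders are expressed as nucleotide offsets into the
#' spliced CDS (cumulative prefix sums of all but the last exon length). A
#' border's phase is `offset mod 3`; a border with nonzero phase is a split
#' codon: a codon encoded across the two adjacent exons.
#'
#' @inheritParams assemble_cds
#' @return an `exon_architecture` list with `exon_lengths`, `borders`
#'   (data.frame of `offset`, `phase`) and `total_length`.
#' @export
derive_architecture <- function(model, transcript_id = NULL) {
  tr <- get_transcript(model, transcript_id)
  lens <- vapply(tr$exons, exon_length, 0L)
  offs <- cumsum(lens)
  offs <- offs[-length(offs)]
  structure(list(gene_id = model$gene_id, transcript_id = tr$id,
                 exon_lengths = lens,
                 borders = data.frame(offset = as.integer(offs),
                                      phase = as.integer(offs %% 3L)),
                 total_length = sum(lens)),
            class = "exon_architecture")
}

#' @export
print.exon_architecture <- function(x, ...) {
  cat("exon_architecture ", x$gene_id, ": ", length(x$exon_lengths),
      " exon(s), ", nrow(x$borders), " internal border(s), ",
      sum(x$borders$phase != 0L), " split codon(s)\n", sep = "")
  invisible(x)
}

#' Number of split codons of an architecture
#' @param arch an `exon_architecture`.
#' @return integer count of borders with nonzero phase.
#' @export
n_split_codons <- function(arch) sum(arch$borders$phase != 0L)

#' Translate an assembled CDS
#'
#' Standard genetic code; a trailing stop codon is dropped from the protein.
#' An internal stop does not abort (fragmented assemblies are expected
#' inputs) but is flagged. Codons containing N translate to X.
#'
#' @param cds a `cds_record` or a plain nucleotide string.
#' @return list with `protein` (string) and `internal_stop` (flag).
#' @export
translate_cds <- function(cds) {
  nt <- if (inherits(cds, "cds_record")) cds$sequence else cds
  aa <- codon_translate(nt)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal <- any(aa == "*")
  list(protein = paste(aa, collapse = ""), internal_stop = internal)
}
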