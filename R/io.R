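# Standard-format I/O: FASTA, GFF3 (gene/mRNA/CDS subset), tabular
# similarity hits, expression tables, presence/absence matrices.

#' Read a genome from a FASTA file
#' @param path FASTA file.
#' @return a [genome()] object.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  genome(stats::setNames(as.character(x), ids))
}

#' Write a genome (or any named sequence set) to FASTA
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    s <- x[[id]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a protein multiple sequence alignment (aligned FASTA)
#' @param path aligned FASTA file; gap character `-`.
#' @return a `protein_msa` object: named character vector of equal-length
#'   aligned rows.
#' @export
read_protein_msa <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  protein_msa(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' Construct a protein MSA object
#' @param rows named character vector, gene id -> aligned sequence.
#' @return a `protein_msa` object.
#' @export
protein_msa <- function(rows) {
  rows <- toupper(unlist(rows))
  if (length(rows) == 0L) stop("empty alignment")
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length")
  }
  structure(rows, class = "protein_msa")
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attr))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
}

#' Write gene models to a GFF3 file
#'
#' Emits a gene/mRNA/CDS hierarchy restricted to coding exons. Internal
#' 0-based half-open coordinates are converted to the 1-based inclusive
#' GFF3 convention, and the CDS phase column ("bases to remove before the
#' next full codon") is recomputed from cumulative exon lengths.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    all_ex <- unlist(m$transcripts, recursive = FALSE)
    g_start <- min(vapply(all_ex, `[[`, 0L, "start"))
    g_end <- max(vapply(all_ex, `[[`, 0L, "end"))
    seq_id <- all_ex[[1]]$seq_id
    strand <- all_ex[[1]]$strand
    lines <- c(lines, paste(seq_id, "exonarch", "gene", g_start + 1L, g_end,
                            ".", strand, ".",
                            paste0("ID=", gff3_escape(m$gene_id),
                                   ";species=", gff3_escape(m$species_id),
                                   ";family=", gff3_escape(m$family_label)),
                            sep = "\t"))
    for (tid in names(m$transcripts)) {
      exons <- m$transcripts[[tid]]
      t_start <- min(vapply(exons, `[[`, 0L, "start"))
      t_end <- max(vapply(exons, `[[`, 0L, "end"))
      lines <- c(lines, paste(seq_id, "exonarch", "mRNA", t_start + 1L, t_end,
                              ".", strand, ".",
                              paste0("ID=", gff3_escape(tid),
                                     ";Parent=", gff3_escape(m$gene_id)),
                              sep = "\t"))
      lens <- vapply(exons, exon_length, 0L)
      offsets <- c(0L, cumsum(lens)[-length(lens)])
      phases <- (3L - offsets %% 3L) %% 3L  # bases to remove = (3 - off mod 3) mod 3
      for (i in seq_along(exons)) {
        e <- exons[[i]]
        lines <- c(lines, paste(seq_id, "exonarch", "CDS", e$start + 1L,
                                e$end, ".", strand, phases[i],
                                paste0("ID=", gff3_escape(paste0(tid, ".cds", i)),
                                       ";Parent=", gff3_escape(tid)),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Accepts the gene/mRNA/CDS subset written by [write_gene_models_gff3()]
#' (CDS features grouped by `Parent` transcript, transcripts grouped by
#' `Parent` gene). The stored phase column is validated against phases
#' recomputed from exon lengths; a mismatch raises a warning, not an error,
#' since annotations from fragmented assemblies are expected inputs.
#'
#' @param path GFF3 file.
#' @return list of [gene_model()] objects.
#' @export
read_gene_models_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(raw) == 0L) return(list())
  f <- strsplit(raw, "\t", fixed = TRUE)
  bad <- vapply(f, length, 0L) != 9L
  if (any(bad)) stop("malformed GFF3 line: ", raw[which(bad)[1]])
  tab <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attr")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  unescape <- function(x) {
    x <- gsub("%3B", ";", x, fixed = TRUE); x <- gsub("%3D", "=", x, fixed = TRUE)
    x <- gsub("%2C", ",", x, fixed = TRUE); gsub("%25", "%", x, fixed = TRUE)
  }
  genes <- tab[tab$type == "gene", , drop = FALSE]
  mrnas <- tab[tab$type == "mRNA", , drop = FALSE]
  cdss <- tab[tab$type == "CDS", , drop = FALSE]
  gene_ids <- unescape(gff3_attr(genes$attr, "ID"))
  models <- vector("list", nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    gid <- gene_ids[gi]
    sp <- unescape(gff3_attr(genes$attr[gi], "species"))
    fam <- unescape(gff3_attr(genes$attr[gi], "family"))
    sel <- unescape(gff3_attr(mrnas$attr, "Parent")) == gid
    trs <- list()
    for (mi in which(sel)) {
      tid <- unescape(gff3_attr(mrnas$attr[mi], "ID"))
      csel <- unescape(gff3_attr(cdss$attr, "Parent")) == tid
      cd <- cdss[csel, , drop = FALSE]
      ord <- order(cd$start)
      if (cd$strand[1] == "-") ord <- rev(ord)
      cd <- cd[ord, , drop = FALSE]
      exons <- lapply(seq_len(nrow(cd)), function(i) {
        coding_exon(cd$seqid[i], cd$start[i] - 1L, cd$end[i], cd$strand[i])
      })
      lens <- cd$end - cd$start + 1L
      offsets <- c(0L, cumsum(lens)[-length(lens)])
      expect <- (3L - offsets %% 3L) %% 3L
      stored <- suppressWarnings(as.integer(cd$phase))
      if (!all(is.na(stored)) && !isTRUE(all(stored == expect))) {
        warning("transcript ", tid, ": stored CDS phases disagree with ",
                "phases recomputed from exon lengths")
      }
      trs[[tid]] <- exons
    }
    models[[gi]] <- gene_model(gid, ifelse(is.na(sp), "unknown", sp),
                               ifelse(is.na(fam), "unknown", fam), trs)
  }
  stats::setNames(models, gene_ids)
}

#' Read a 12-column tabular similarity-hit file
#'
#' Standard blastn `-outfmt 6` layout: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore (1-based inclusive coordinates; sstart > send encodes a
#' minus-strand hit).
#'
#' @param path tab-separated hit file, no header.
#' @return data.frame with typed columns and a derived `strand` column.
#' @export
read_similarity_hits <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("query", "subject", "pident",
                                         "length", "mismatch", "gapopen",
                                         "qstart", "qend", "sstart", "send",
                                         "evalue", "bitscore"))
  tab$strand <- ifelse(tab$sstart <= tab$send, "+", "-")
  tab
}

#' Read an expression table (locus x experiment RPKM)
#' @param path TSV with columns `locus`, `experiment`, `tissue`, `rpkm`.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("locus", "experiment", "tissue", "rpkm")
  if (!all(need %in% names(tab))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  tab$rpkm <- as.numeric(tab$rpkm)
  tab
}

#' Read a presence/absence (copy-count) matrix
#'
#' Families as rows, species as columns; `?` or `NA` marks unknown.
#'
#' @param path TSV with a `family` column followed by one column per species.
#' @return numeric matrix (rownames = families), `NA` = unknown.
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "?"))
  rn <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- rn
  m
}
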