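# Retrogene detection and classification: locus calls from similarity
# hits, ORF discovery in hit windows, parent-protein similarity,
# cross-species ORF conservation, and functional-status assignment.

#' Default similarity-search parameters
#'
#' Nucleotide search settings used for retrogene retrieval: e-value below
#' 1e-5, match/mismatch +1/-3, gap open/extend 5/2.
#'
#' @param evalue_max,match,mismatch,gap_open,gap_extend overrides.
#' @return list of parameters.
#' @export
similarity_search_params <- function(evalue_max = 1e-5, match = 1,
                                     mismatch = -3, gap_open = 5,
                                     gap_extend = 2) {
  list(evalue_max = evalue_max, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Exact local (Smith-Waterman) nucleotide alignment
#'
#' Self-contained scorer mirroring [similarity_search_params()] defaults
#' (+1/-3, affine gaps 5/2), used to produce hit tables for tests without
#' an external search tool.
#'
#' @param query,subject nucleotide strings.
#' @param params a [similarity_search_params()] list.
#' @return list with `score`, `pident`, query/subject 1-based coordinates
#'   and alignment length.
#' @export
sw_align <- function(query, subject, params = similarity_search_params()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                mismatch = params$mismatch,
                                                baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(query, subject,
                                      substitutionMatrix = m,
                                      gapOpening = params$gap_open,
                                      gapExtension = params$gap_extend,
                                      type = "local")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  matches <- sum(pa == sa & pa != "-")
  list(score = Biostrings::score(al),
       pident = 100 * matches / length(pa),
       qstart = Biostrings::start(Biostrings::pattern(al)),
       qend = Biostrings::end(Biostrings::pattern(al)),
       sstart = Biostrings::start(Biostrings::subject(al)),
       send = Biostrings::end(Biostrings::subject(al)),
       length = length(pa))
}

merge_locus_hits <- function(hits, gap_max = 1000L) {
  # merge overlapping or near-adjacent (<= gap_max) HSPs on the same
  # subject strand into single hits
  hits <- hits[order(hits$strand, pmin(hits$sstart, hits$send)), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    s1 <- min(h$sstart, h$send); s2 <- max(h$sstart, h$send)
    placed <- FALSE
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (m$strand == h$strand && s1 <= m$s2 + gap_max && s2 >= m$s1 - gap_max) {
        merged[[j]]$s1 <- min(m$s1, s1); merged[[j]]$s2 <- max(m$s2, s2)
        merged[[j]]$q1 <- min(m$q1, h$qstart); merged[[j]]$q2 <- max(m$q2, h$qend)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      merged[[length(merged) + 1L]] <- list(strand = h$strand, s1 = s1,
                                            s2 = s2, q1 = h$qstart,
                                            q2 = h$qend)
    }
  }
  merged
}

#' Classify a candidate retrogene locus from its similarity hits
#'
#' After merging overlapping HSPs (within `gap_max` nt), more than one
#' remaining ordered hit means the locus mirrors the parent's multi-exon
#' structure and is excluded. A single hit is banded by query coverage:
#' at least 50% is a retrogene candidate, 30-50% goes to manual review,
#' below 30% is an individual exon fragment.
#'
#' @param hits data.frame of hits for one target locus (columns as
#'   produced by [read_similarity_hits()]).
#' @param query_length parent query length in nt (CDS of the longest
#'   protein-coding isoform).
#' @param gap_max HSP merge distance (default 1000 nt).
#' @return a `locus_call` list: `class` in `c("retrogene_candidate",
#'   "manual_review", "exon_fragment", "excluded_multi_hit")`, `coverage`,
#'   `n_hits`, `collinear`.
#' @export
classify_locus <- function(hits, query_length, gap_max = 1000L) {
  if (is.null(hits) || nrow(hits) == 0L) stop("empty hit set")
  merged <- merge_locus_hits(hits, gap_max)
  if (length(merged) > 1L) {
    qs <- vapply(merged, `[[`, 0, "q1")
    ss <- vapply(merged, `[[`, 0, "s1")
    collinear <- identical(order(qs), order(ss)) ||
      identical(order(qs), rev(order(ss)))
    return(structure(list(class = "excluded_multi_hit",
                          coverage = NA_real_, n_hits = length(merged),
                          collinear = collinear),
                     class = "locus_call"))
  }
  m <- merged[[1]]
  coverage <- (m$q2 - m$q1 + 1) / query_length
  cls <- if (coverage >= 0.5) "retrogene_candidate"
  else if (coverage >= 0.3) "manual_review"
  else "exon_fragment"
  structure(list(class = cls, coverage = coverage, n_hits = 1L,
                 collinear = TRUE),
            class = "locus_call")
}

#' Find open reading frames in a locus window
#'
#' The locus is extended by `flank` nt on both sides (clipped at the
#' sequence edges with a warning) and scanned on both strands in all three
#' frames. ORFs are maximal stop-free codon runs bounded by stop codons or
#' window edges, reported when at least `min_aa` codons long and, if
#' `require_met`, containing an in-frame ATG (length and coordinates are
#' then counted from the first ATG).
#'
#' @param sequence locus nucleotide string (already windowed), or a full
#'   sequence plus `hit_start`/`hit_end` (1-based) to window around.
#' @param hit_start,hit_end optional 1-based hit coordinates.
#' @param flank extension in nt (default 300).
#' @param min_aa minimum ORF length in amino acids (default 40).
#' @param require_met require an initiation methionine (default TRUE).
#' @return data.frame of ORFs: `strand`, `frame`, `start`, `end` (1-based
#'   within the window), `length_aa`, `has_met`, `protein`.
#' @export
find_orfs <- function(sequence, hit_start = NULL, hit_end = NULL,
                      flank = 300L, min_aa = 40L, require_met = TRUE) {
  sequence <- norm_dna(sequence, "locus sequence")
  if (!is.null(hit_start)) {
    w1 <- hit_start - flank; w2 <- hit_end + flank
    if (w1 < 1L || w2 > nchar(sequence)) {
      warning("ORF window clipped at sequence edge")
    }
    w1 <- max(1L, w1); w2 <- min(nchar(sequence), w2)
    sequence <- substr(sequence, w1, w2)
  }
  n <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1L, n)
      ncod <- nchar(sub) %/% 3L
      if (ncod == 0L) next
      starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      bounds <- c(0L, which(is_stop), ncod + 1L)
      for (bi in seq_len(length(bounds) - 1L)) {
        lo <- bounds[bi] + 1L; hi <- bounds[bi + 1L] - 1L
        if (hi < lo) next
        run <- codons[lo:hi]
        first_met <- which(run == "ATG")[1]
        if (require_met) {
          if (is.na(first_met)) next
          lo2 <- lo + first_met - 1L
        } else {
          lo2 <- lo
        }
        len_aa <- hi - lo2 + 1L
        if (len_aa < min_aa) next
        # coordinates on the forward window
        c1 <- frame + 1L + 3L * (lo2 - 1L)
        c2 <- frame + 3L * hi
        if (strand == "-") {
          tmp <- c(n - c2 + 1L, n - c1 + 1L)
          c1 <- tmp[1]; c2 <- tmp[2]
        }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, frame = frame, start = c1, end = c2,
          length_aa = len_aa,
          has_met = !is.na(first_met),
          protein = paste(codon_translate(paste(codons[lo2:hi],
                                                collapse = "")),
                          collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0), has_met = logical(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$length_aa, res$start), , drop = FALSE]
}

#' Check an ORF's similarity to the parent protein
#'
#' Local alignment with simple scores (match +2, mismatch -1, affine gaps
#' 5/2). The ORF is parent-similar when the aligned region spans at least
#' `min_aligned` residues with identity at least `identity_min`.
#'
#' @param orf_protein ORF protein string (or a row of [find_orfs()]).
#' @param parent_protein parent protein string.
#' @param min_aligned minimum aligned length (default 40 aa).
#' @param identity_min minimum identity over the aligned region (default
#'   0.5).
#' @return list with `similar` (flag), `identity` (percent), and
#'   `aligned_length`.
#' @export
check_parent_similarity <- function(orf_protein, parent_protein,
                                    min_aligned = 40L, identity_min = 0.5) {
  if (is.data.frame(orf_protein)) orf_protein <- orf_protein$protein[1]
  if (nchar(orf_protein) == 0L || nchar(parent_protein) == 0L) {
    stop("empty sequence")
  }
  alpha <- unique(c(strsplit(orf_protein, "")[[1]],
                    strsplit(parent_protein, "")[[1]], LETTERS, "*"))
  m <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 2
  al <- Biostrings::pairwiseAlignment(orf_protein, parent_protein,
                                      substitutionMatrix = m,
                                      gapOpening = 5, gapExtension = 2,
                                      type = "local")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  aligned <- length(pa)
  ident <- if (aligned) sum(pa == sa & pa != "-") / aligned else 0
  list(similar = aligned >= min_aligned && ident >= identity_min,
       identity = 100 * ident, aligned_length = aligned)
}

#' Check conservation of a novel ORF across clade species
#'
#' Given aligned locus sequences (one per species, same coordinates), the
#' ORF region is conserved when every species retains, within the region,
#' an open reading frame of at least `min_aa` codons containing at least
#' one methionine. A species whose region is all gaps counts as not
#' conserved.
#'
#' @param aligned named character vector of aligned nucleotide sequences
#'   (gap `-`).
#' @param region optional 1-based alignment-column range `c(from, to)`;
#'   default whole alignment.
#' @param min_aa minimum ORF length (default 40).
#' @return list with `conserved` (flag) and per-species detail data.frame.
#' @export
check_novel_orf_conservation <- function(aligned, region = NULL,
                                         min_aa = 40L) {
  if (length(aligned) < 2L) stop("need >= 2 species")
  if (length(unique(nchar(aligned))) != 1L) stop("rows differ in length")
  if (is.null(region)) region <- c(1L, nchar(aligned[[1]]))
  detail <- lapply(names(aligned), function(sp) {
    sub <- substr(aligned[[sp]], region[1], region[2])
    bare <- gsub("-", "", sub, fixed = TRUE)
    if (nchar(bare) == 0L) {
      return(data.frame(species = sp, ok = FALSE, best_aa = 0L,
                        stringsAsFactors = FALSE))
    }
    orfs <- find_orfs(bare, min_aa = min_aa, require_met = TRUE)
    data.frame(species = sp, ok = nrow(orfs) > 0L,
               best_aa = if (nrow(orfs)) max(orfs$length_aa) else 0L,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  list(conserved = all(detail$ok), detail = detail)
}

#' Assign functional status to a retrogene locus
#'
#' Decision table combining ORF conservation and expression evidence: a
#' parent-similar ORF of at least 40 aa conserved in all clade species
#' plus at least one expression experiment with RPKM above the threshold
#' gives `functional`; a conserved ORF without expression is
#' `conserved_unexpressed`; expression without a conserved ORF is
#' `expressed_only`; neither is `pseudo`. An upstream-promoter annotation
#' is recorded as supporting evidence but is not required.
#'
#' @param locus locus id (matched against the expression table).
#' @param orf_conserved flag: parent-similar >= 40 aa ORF conserved in all
#'   clade species.
#' @param expression data.frame from [read_expression_table()], or NULL.
#' @param rpkm_min expression threshold (default 0.5, exclusive).
#' @param promoter_flag input-provided promoter annotation flag.
#' @return a `functional_status` list: `status`, `n_expressed_experiments`,
#'   `orf_conserved`, `promoter`.
#' @export
assign_status <- function(locus, orf_conserved, expression = NULL,
                          rpkm_min = 0.5, promoter_flag = FALSE) {
  n_exp <- 0L
  if (!is.null(expression)) {
    rows <- expression[expression$locus == locus, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("locus ", locus, " absent from expression table; ",
              "treated as unexpressed")
    }
    n_exp <- sum(rows$rpkm > rpkm_min)
  }
  status <- if (orf_conserved && n_exp >= 1L) "functional"
  else if (orf_conserved) "conserved_unexpressed"
  else if (n_exp >= 1L) "expressed_only"
  else "pseudo"
  structure(list(locus = locus, status = status,
                 n_expressed_experiments = n_exp,
                 orf_conserved = orf_conserved, promoter = promoter_flag),
            class = "functional_status")
}
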