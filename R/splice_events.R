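# Splice-event analysis: donor/acceptor classification (canonical GT-AG,
# non-canonical GC-AG, NAGNAG-type TG acceptor 3 nt upstream), mutually
# exclusive duplicated exon detection, isoform enumeration and comparison.

intron_sequences <- function(model, genome, transcript_id = NULL) {
  tr <- get_transcript(model, transcript_id)
  exons <- tr$exons
  if (length(exons) < 2L) return(character(0))
  out <- character(length(exons) - 1L)
  for (i in seq_len(length(exons) - 1L)) {
    a <- exons[[i]]; b <- exons[[i + 1L]]
    chrom <- genome[[a$seq_id]]
    if (a$strand == "+") {
      s <- substr(chrom, a$end + 1L, b$start)
    } else {
      s <- revcomp(substr(chrom, b$end + 1L, a$start))
    }
    out[i] <- s
  }
  out
}

#' Scan splice sites of a transcript
#'
#' Per intron (strand-aware), the donor is the first two intron
#' nucleotides and the acceptor the last two. GT-AG is canonical; GC-AG is
#' the non-canonical donor class observed for conserved vertebrate introns
#' (GNAI1 intron6 type). An alternative upstream acceptor is reported when
#' intron positions -5,-4 (from the 3' end) read `TG`: splicing there
#' transfers the intron's final 3 nt (typically `CAG`) onto the downstream
#' exon (GNAS exon4-extension type).
#'
#' @param model a [gene_model()].
#' @param genome a [genome()].
#' @param transcript_id transcript; defaults to the first.
#' @return data.frame, one row per intron: `intron`, `donor`, `acceptor`,
#'   `classification`, `too_short`, `alt_acceptor` (logical),
#'   `alt_included_nt`.
#' @export
scan_splice_sites <- function(model, genome, transcript_id = NULL) {
  introns <- intron_sequences(model, genome, transcript_id)
  if (length(introns) == 0L) stop("transcript has fewer than 2 exons")
  out <- lapply(seq_along(introns), function(i) {
    s <- introns[i]
    n <- nchar(s)
    if (n < 7L) {
      return(data.frame(intron = i, donor = NA_character_,
                        acceptor = NA_character_,
                        classification = "too_short", too_short = TRUE,
                        alt_acceptor = FALSE, alt_included_nt = NA_character_,
                        stringsAsFactors = FALSE))
    }
    donor <- substr(s, 1L, 2L)
    acceptor <- substr(s, n - 1L, n)
    cls <- if (donor == "GT" && acceptor == "AG") {
      "canonical_GT_AG"
    } else if (donor == "GC" && acceptor == "AG") {
      "noncanonical_GC_AG"
    } else "other"
    alt <- substr(s, n - 4L, n - 3L) == "TG"
    data.frame(intron = i, donor = donor, acceptor = acceptor,
               classification = cls, too_short = FALSE,
               alt_acceptor = alt,
               alt_included_nt = if (alt) substr(s, n - 2L, n) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

aa_run_translate <- function(nt, entering_phase) {
  # translate a run as spliced in-frame: drop the partial codon entering
  # the run and any trailing partial codon
  drop <- (3L - entering_phase) %% 3L
  nt <- substr(nt, drop + 1L, nchar(nt))
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  if (nchar(nt) == 0L) return("")
  paste(codon_translate(nt), collapse = "")
}

aa_identity <- function(a, b) {
  # LCS-style global alignment: match 1, mismatch 0, no gap penalty;
  # identity = matches / alignment length
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  # simple match/mismatch matrix over the amino-acid alphabet
  alpha <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]],
                    LETTERS, "*"))
  m <- matrix(0, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                      gapOpening = 0, gapExtension = 0,
                                      type = "global")
  matches <- Biostrings::nmatch(al)
  matches / Biostrings::nchar(al)
}

#' Detect mutually exclusive duplicated exons
#'
#' Scans the annotated exon chain for adjacent runs of one or two
#' consecutive exons that look like in-place tandem duplicates: amino-acid
#' identity of the run translations at least `identity_min`, and run
#' lengths congruent mod 3 so that, spliced mutually exclusively, both
#' alternatives enter and exit at identical phases. Groups are extended
#' maximally (tandem arrays yield more than two alternatives). Two-exon
#' runs are tried before single exons so a duplicated exon pair (the GNAO
#' exon7-8 pattern) is reported as one group.
#'
#' @param model a [gene_model()].
#' @param genome a [genome()].
#' @param identity_min amino-acid identity threshold (default 0.30).
#' @param transcript_id transcript; defaults to the first.
#' @return list of `mxe_group` lists: `gene_id`, `alternatives` (list of
#'   exon index vectors), `identity` (minimum pairwise identity),
#'   `entering_phase`, `exiting_phase`.
#' @export
find_mutually_exclusive_exons <- function(model, genome, identity_min = 0.30,
                                          transcript_id = NULL) {
  tr <- get_transcript(model, transcript_id)
  exons <- tr$exons
  n <- length(exons)
  if (n < 2L) return(list())
  seqs <- vapply(seq_len(n), function(i) {
    e <- exons[[i]]
    s <- substr(genome[[e$seq_id]], e$start + 1L, e$end)
    if (e$strand == "-") revcomp(s) else s
  }, "")
  lens <- nchar(seqs)
  offs <- c(0L, cumsum(lens))
  groups <- list()
  used <- rep(FALSE, n)
  # exon-wise comparison of two same-length runs, as spliced at the run's
  # entering phase: a tandem-duplicated run matches its copy exon by exon
  run_identity <- function(run_a, run_b, entering) {
    ph <- entering
    idents <- numeric(length(run_a))
    for (k in seq_along(run_a)) {
      idents[k] <- aa_identity(aa_run_translate(seqs[run_a[k]], ph),
                               aa_run_translate(seqs[run_b[k]], ph))
      ph <- (ph + lens[run_a[k]]) %% 3L
    }
    min(idents)
  }
  for (L in c(2L, 1L)) {
    i <- 1L
    while (i + 2L * L - 1L <= n) {
      if (any(used[i:(i + L - 1L)])) { i <- i + 1L; next }
      entering <- offs[i] %% 3L
      alts <- list(i:(i + L - 1L))
      j <- i + L
      min_ident <- 1
      while (j + L - 1L <= n && !any(used[j:(j + L - 1L)])) {
        len_a <- sum(lens[alts[[1]]]); len_b <- sum(lens[j:(j + L - 1L)])
        if ((len_a - len_b) %% 3L != 0L) break
        ident <- run_identity(alts[[1]], j:(j + L - 1L), entering)
        if (ident < identity_min) break
        min_ident <- min(min_ident, ident)
        alts[[length(alts) + 1L]] <- j:(j + L - 1L)
        j <- j + L
      }
      if (length(alts) >= 2L) {
        idx <- unlist(alts)
        used[idx] <- TRUE
        groups[[length(groups) + 1L]] <- structure(
          list(gene_id = model$gene_id, alternatives = alts,
               identity = min_ident,
               entering_phase = entering,
               exiting_phase = (entering + sum(lens[alts[[1]]])) %% 3L),
          class = "mxe_group")
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  groups
}

#' Enumerate splice isoforms of a gene
#'
#' Takes independent alternative-splicing features -- cassette exons (in or
#' out), mutually exclusive exon groups (one alternative each), and
#' alternative upstream acceptors (canonical AG or the TG site 3 nt
#' upstream, which adds the intron's last 3 nt to the downstream exon) --
#' and produces the Cartesian product of choices, translating each
#' isoform.
#'
#' @param model a [gene_model()].
#' @param genome a [genome()].
#' @param cassette_exons integer vector of exon indices that can be
#'   skipped.
#' @param mxe_groups list of `mxe_group` (from
#'   [find_mutually_exclusive_exons()]).
#' @param alt_acceptors integer vector of intron indices with a usable TG
#'   acceptor (validated against the genome sequence).
#' @param transcript_id transcript; defaults to the first.
#' @return data.frame, one row per isoform: `label`, `exons` (comma string
#'   of included exon indices), `acceptor_shift` (comma string of intron
#'   indices spliced at the upstream site), `cds`, `protein`, `frame_ok`,
#'   `premature_stop`.
#' @export
enumerate_isoforms <- function(model, genome, cassette_exons = integer(0),
                               mxe_groups = list(),
                               alt_acceptors = integer(0),
                               transcript_id = NULL) {
  tr <- get_transcript(model, transcript_id)
  n <- length(tr$exons)
  mxe_idx <- unlist(lapply(mxe_groups, function(g) unlist(g$alternatives)))
  if (any(cassette_exons %in% mxe_idx)) {
    stop("conflicting features: exon(s) ",
         paste(intersect(cassette_exons, mxe_idx), collapse = ","),
         " are both cassette and mutually exclusive")
  }
  if (any(cassette_exons < 1L | cassette_exons > n)) stop("cassette exon out of range")
  introns <- intron_sequences(model, genome, transcript_id)
  if (any(alt_acceptors < 1L | alt_acceptors > length(introns))) {
    stop("alt acceptor intron out of range")
  }
  for (ai in alt_acceptors) {
    s <- introns[ai]
    if (substr(s, nchar(s) - 4L, nchar(s) - 3L) != "TG") {
      stop("intron ", ai, " has no TG acceptor 3 nt upstream of its 3' end")
    }
  }
  seqs <- vapply(seq_len(n), function(i) {
    e <- tr$exons[[i]]
    s <- substr(genome[[e$seq_id]], e$start + 1L, e$end)
    if (e$strand == "-") revcomp(s) else s
  }, "")

  choice_sets <- list()
  for (ce in cassette_exons) {
    choice_sets[[paste0("cassette", ce)]] <-
      list(list(kind = "cassette", exon = ce, include = TRUE),
           list(kind = "cassette", exon = ce, include = FALSE))
  }
  for (gi in seq_along(mxe_groups)) {
    g <- mxe_groups[[gi]]
    choice_sets[[paste0("mxe", gi)]] <- lapply(seq_along(g$alternatives),
      function(ai) list(kind = "mxe", group = gi, alt = ai))
  }
  for (ai in alt_acceptors) {
    choice_sets[[paste0("acc", ai)]] <-
      list(list(kind = "acceptor", intron = ai, shifted = FALSE),
           list(kind = "acceptor", intron = ai, shifted = TRUE))
  }
  combos <- if (length(choice_sets)) {
    expand.grid(lapply(choice_sets, seq_along), KEEP.OUT.ATTRS = FALSE)
  } else data.frame(row.names = 1)

  rows <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    include <- rep(TRUE, n)
    shifts <- integer(0)
    lab <- character(0)
    for (fi in seq_along(choice_sets)) {
      ch <- choice_sets[[fi]][[combos[ci, fi]]]
      if (ch$kind == "cassette") {
        include[ch$exon] <- ch$include
        lab <- c(lab, paste0("e", ch$exon, if (ch$include) "+" else "-"))
      } else if (ch$kind == "mxe") {
        g <- mxe_groups[[ch$group]]
        for (ai in seq_along(g$alternatives)) {
          if (ai != ch$alt) include[g$alternatives[[ai]]] <- FALSE
        }
        lab <- c(lab, paste0("mxe", ch$group, ".", ch$alt))
      } else {
        if (ch$shifted) shifts <- c(shifts, ch$intron)
        lab <- c(lab, paste0("i", ch$intron, if (ch$shifted) "TG" else "AG"))
      }
    }
    kept <- which(include)
    parts <- character(0)
    for (k in seq_along(kept)) {
      i <- kept[k]
      ext <- ""
      if (k > 1L) {
        # acceptor shift applies to the intron immediately upstream of this
        # exon in the spliced product
        up_intron <- i - 1L
        if (up_intron %in% shifts) {
          s <- introns[up_intron]
          ext <- substr(s, nchar(s) - 2L, nchar(s))
        }
      }
      parts <- c(parts, paste0(ext, seqs[i]))
    }
    cds <- paste(parts, collapse = "")
    frame_ok <- nchar(cds) %% 3L == 0L && nchar(cds) >= 3L
    prot <- NA_character_; pstop <- NA
    if (frame_ok) {
      tl <- translate_cds(cds)
      prot <- tl$protein; pstop <- tl$internal_stop
    }
    rows[[ci]] <- data.frame(
      label = if (length(lab)) paste(lab, collapse = "_") else "canonical",
      exons = paste(kept, collapse = ","),
      acceptor_shift = paste(shifts, collapse = ","),
      cds = cds, protein = prot, frame_ok = frame_ok,
      premature_stop = pstop, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare two isoform proteins
#'
#' @param a,b protein strings (or rows of [enumerate_isoforms()] output).
#' @return list with `length_difference` (absolute residue-count
#'   difference) and `substitutions` (mismatched aligned positions of a
#'   global alignment, gaps excluded).
#' @export
isoform_delta <- function(a, b) {
  pa <- if (is.list(a) || is.data.frame(a)) a$protein else a
  pb <- if (is.list(b) || is.data.frame(b)) b$protein else b
  if (is.na(pa) || is.na(pb)) stop("isoform does not translate")
  alpha <- unique(c(strsplit(pa, "")[[1]], strsplit(pb, "")[[1]],
                    LETTERS, "*"))
  m <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 1
  al <- Biostrings::pairwiseAlignment(pa, pb, substitutionMatrix = m,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  subs <- sum(sa != sb & sa != "-" & sb != "-")
  list(length_difference = abs(nchar(pa) - nchar(pb)),
       substitutions = as.integer(subs))
}
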