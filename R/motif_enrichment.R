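# Positional (local) motif enrichment: PWM scanning for the best site per
# sequence, a binomial test of site counts in a window against a uniform
# position null, a Fisher exact differential test against a control set,
# and multiple-testing adjustment.

#' Construct a position weight matrix
#'
#' @param id motif identifier.
#' @param probs 4 x w numeric matrix (rows A, C, G, T) of column
#'   probabilities; columns must each sum to 1 within 1e-9.
#' @param background length-4 background frequencies (default uniform).
#' @param pseudocount added to every cell before log-odds scoring
#'   (default 0.01).
#' @return a `pwm` object.
#' @export
pwm <- function(id, probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A,C,G,T)")
  if (ncol(probs) < 1L) stop("motif width must be >= 1")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must sum to 1")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  adj <- sweep(probs + pseudocount, 2, colSums(probs + pseudocount), "/")
  structure(list(id = id, width = ncol(probs), probs = probs,
                 background = background,
                 logodds = log2(adj / background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", x$width, "\n")
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' the file-level `Background letter frequencies` line, when present, sets
#' the scoring background.
#'
#' @param path MEME minimal motif file.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return named list of [pwm()] objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    lett <- toks[is.na(vals)]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 4L && all(c("A", "C", "G", "T") %in% lett)) {
      bg <- vals[match(c("A", "C", "G", "T"), lett)]
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  out <- list()
  for (mi in seq_along(motif_at)) {
    header <- strsplit(trimws(lines[motif_at[mi]]), "\\s+")[[1]]
    id <- header[2]
    lp <- grep("^letter-probability matrix", lines)
    lp <- lp[lp > motif_at[mi]][1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1L):(lp + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4), USE.NAMES = FALSE))
    out[[id]] <- pwm(id, t(mat), background = bg, pseudocount = pseudocount)
  }
  out
}

scan_scores <- function(seqs_split, lo) {
  # lo: 4 x w log-odds matrix; seqs_split: list of integer-coded sequences
  w <- ncol(lo)
  lapply(seqs_split, function(code) {
    n <- length(code)
    if (n < w) return(numeric(0))
    vapply(seq_len(n - w + 1L), function(s) {
      idx <- code[s:(s + w - 1L)]
      if (anyNA(idx)) return(-Inf)
      sum(lo[cbind(idx, seq_len(w))])
    }, 0)
  })
}

#' Best motif site per sequence
#'
#' Scores every window with the PWM log-odds against the background and
#' records the best-scoring window's 0-based center position
#' (`start + floor((w-1)/2)`). DNA mode scans both strands (a minus-strand
#' window's center is expressed in forward coordinates); ties go to the
#' leftmost position and then the forward strand.
#'
#' @param sequences named character vector of equal-role sequences;
#'   sequences shorter than the motif are skipped with a warning.
#' @param pwm a [pwm()].
#' @param both_strands scan the reverse complement too (default TRUE; use
#'   FALSE for RNA motifs).
#' @return data.frame: `sequence`, `center` (0-based), `score`, `strand`.
#' @export
best_site_per_sequence <- function(sequences, pwm, both_strands = TRUE) {
  if (length(sequences) == 0L) stop("empty input")
  short <- nchar(sequences) < pwm$width
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than the motif skipped")
    sequences <- sequences[!short]
  }
  if (length(sequences) == 0L) stop("all sequences shorter than the motif")
  code <- function(x) {
    match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
  }
  fwd <- scan_scores(lapply(sequences, code), pwm$logodds)
  w <- pwm$width
  out <- lapply(seq_along(sequences), function(i) {
    sc_f <- fwd[[i]]
    n <- nchar(sequences[[i]])
    best_center <- NA_integer_; best_score <- -Inf; best_strand <- "+"
    centers_f <- seq_along(sc_f) - 1L + (w - 1L) %/% 2L
    if (both_strands) {
      sc_r <- scan_scores(list(code(revcomp(sequences[[i]]))), pwm$logodds)[[1]]
      # window starting at s (0-based) on the reverse strand covers
      # forward positions n-s-w .. n-s-1
      centers_r <- n - seq_along(sc_r) + 1L - w + (w - 1L) %/% 2L
    } else {
      sc_r <- numeric(0); centers_r <- integer(0)
    }
    all_sc <- c(sc_f, sc_r)
    all_ct <- c(centers_f, centers_r)
    all_st <- c(rep("+", length(sc_f)), rep("-", length(sc_r)))
    # ties: leftmost center, then forward strand (locale-independent)
    ord <- order(-all_sc, all_ct, all_st != "+")
    b <- ord[1]
    data.frame(sequence = names(sequences)[i] %||% as.character(i),
               center = as.integer(all_ct[b]), score = all_sc[b],
               strand = all_st[b], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Binomial test of local (positional) enrichment
#'
#' Tests whether best-site counts concentrate in a window more than a
#' uniform distribution over possible site positions would produce. The
#' null success probability is window width / (L - w + 1) and the p-value
#' is the upper binomial tail P(X >= k).
#'
#' @param best_sites data.frame from [best_site_per_sequence()].
#' @param region_length L, length of the scanned sequences.
#' @param motif_width w of the scanned motif.
#' @param window `c(start, width)` in 0-based center coordinates; when
#'   NULL, every window of `window_width` centers is scanned and the
#'   minimum-p window is reported with a Bonferroni adjustment over the
#'   number of windows tried.
#' @param window_width width used during window scanning (default 10).
#' @return an `enrichment_result` data.frame row: window, counts, `p`
#'   (raw) and `p_adjusted` (only differs when scanning).
#' @export
local_enrichment <- function(best_sites, region_length, motif_width,
                             window = NULL, window_width = 10L) {
  npos <- region_length - motif_width + 1L
  if (npos < 1L) stop("region shorter than motif")
  first_center <- (motif_width - 1L) %/% 2L
  centers <- first_center + seq_len(npos) - 1L
  n <- nrow(best_sites)
  one <- function(win_start, win_width, n_tests = 1L) {
    win <- centers[centers >= win_start & win_start + win_width > centers]
    if (length(win) == 0L) stop("window outside scannable positions")
    k <- sum(best_sites$center >= win_start &
               best_sites$center < win_start + win_width)
    pi0 <- length(win) / npos
    p <- stats::pbinom(k - 1L, n, pi0, lower.tail = FALSE)
    data.frame(window_start = win_start, window_width = win_width,
               in_window = k, total = n, pi0 = pi0, p = p,
               p_adjusted = min(1, p * n_tests), stringsAsFactors = FALSE)
  }
  if (!is.null(window)) {
    return(one(window[1], window[2]))
  }
  starts <- centers[centers + window_width - 1L <= max(centers)]
  res <- lapply(starts, one, win_width = window_width,
                n_tests = length(starts))
  res <- do.call(rbind, res)
  res[which.min(res$p), , drop = FALSE]
}

#' Fisher exact test of differential positional enrichment
#'
#' One-sided Fisher exact test on the 2x2 table of in-window versus
#' out-of-window best sites in a primary versus a control sequence set;
#' the tested direction is enrichment in the primary set.
#'
#' @param primary_sites,control_sites data.frames from
#'   [best_site_per_sequence()] over the same motif and coordinates.
#' @param window `c(start, width)` in 0-based center coordinates.
#' @return data.frame row with the table counts and `p`.
#' @export
differential_enrichment <- function(primary_sites, control_sites, window) {
  if (nrow(primary_sites) == 0L || nrow(control_sites) == 0L) {
    stop("empty site set")
  }
  inwin <- function(x) {
    sum(x$center >= window[1] & x$center < window[1] + window[2])
  }
  a <- inwin(primary_sites); b <- nrow(primary_sites) - a
  c_ <- inwin(control_sites); d <- nrow(control_sites) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(window_start = window[1], window_width = window[2],
             primary_in = a, primary_out = b,
             control_in = c_, control_out = d, p = p,
             stringsAsFactors = FALSE)
}

#' Adjust enrichment p-values for multiple testing
#'
#' @param results data.frame with a `p` column (one row per motif/window
#'   test).
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @param n_tests total number of tests (default `nrow(results)`).
#' @return `results` with a `p_adjusted` column, clipped at 1.
#' @export
adjust_pvalues <- function(results, method = c("bonferroni", "BH"),
                           n_tests = nrow(results)) {
  method <- match.arg(method)
  if (nrow(results) == 0L) stop("no results to adjust")
  results$p_adjusted <- stats::p.adjust(results$p, method = method,
                                        n = max(n_tests, nrow(results)))
  results
}

#' Per-position best-site probability table
#'
#' Plot-ready table of the fraction of sequences whose best site centers
#' at each position, for a primary and optionally a control set.
#'
#' @param best_sites data.frame from [best_site_per_sequence()].
#' @param region_length L.
#' @param motif_width w.
#' @return data.frame `center`, `probability`.
#' @export
position_probability_table <- function(best_sites, region_length,
                                       motif_width) {
  first_center <- (motif_width - 1L) %/% 2L
  centers <- first_center:(region_length - motif_width + first_center)
  counts <- vapply(centers, function(ct) sum(best_sites$center == ct), 0L)
  data.frame(center = centers,
             probability = counts / max(1L, nrow(best_sites)))
}
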