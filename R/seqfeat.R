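#' TOP-IDP disorder propensity scale
#'
#' Per-residue disorder propensities (positive = disorder-promoting,
#' negative = order-promoting) from the TOP-IDP scale of Campen et al.
#' (2008). `X` is assigned 0 (neutral).
#'
#' @format Named numeric vector over the 20 amino acids plus X.
#' @export
top_idp_scale <- c(A = 0.06, R = 0.180, N = 0.007, D = 0.192, C = 0.02,
                   Q = 0.318, E = 0.736, G = 0.166, H = 0.303, I = -0.486,
                   L = -0.326, K = 0.586, M = -0.397, F = -0.697, P = 0.987,
                   S = 0.341, T = 0.059, W = -0.884, Y = -0.510, V = -0.121,
                   X = 0)

.check_protein_chars <- function(chars) {
  bad <- which(!chars %in% .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("non-amino-acid character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
}

# Shannon entropy (bits) of residue counts in a window, X excluded from
# both the counts and the denominator.
.window_entropy <- function(chars) {
  chars <- chars[chars != "X"]
  if (!length(chars)) return(0)
  f <- tabulate(factor(chars, levels = .AA_ALPHABET[1:20])) / length(chars)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' SEG-style low-complexity segmentation
#'
#' Wootton-Federhen style sliding-window segmentation: the Shannon
#' entropy (bits, X residues excluded) of every length-`window`
#' subsequence is computed; windows with entropy at or below `trigger`
#' seed segments, which are extended across adjacent windows with
#' entropy at or below `extension`; the residues spanned by each maximal
#' run form one masked interval. Intervals are 0-based half-open and the
#' masked fraction is reported. Sequences shorter than `window` are
#' scored as a single window.
#'
#' @param seq protein sequence (string over the 20 amino acids plus X).
#' @param window window length (default 12).
#' @param trigger seeding entropy threshold in bits (default 2.2).
#' @param extension extension entropy threshold in bits (default 2.5).
#' @return A list of class `complexity_mask`: `intervals` (data frame
#'   `start`, `end`; 0-based half-open), `fraction`, `length`.
#' @export
seg_mask <- function(seq, window = 12L, trigger = 2.2, extension = 2.5) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  .check_protein_chars(chars)
  L <- length(chars)
  w <- min(window, L)
  n_win <- L - w + 1L
  ent <- vapply(seq_len(n_win), function(i) .window_entropy(chars[i:(i + w - 1L)]), 0)
  extendable <- ent <= extension
  triggers <- ent <= trigger
  intervals <- list()
  i <- 1L
  while (i <= n_win) {
    if (extendable[i]) {
      j <- i
      while (j < n_win && extendable[j + 1L]) j <- j + 1L
      if (any(triggers[i:j]))
        intervals[[length(intervals) + 1L]] <- c(i - 1L, j + w - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  iv <- if (length(intervals)) {
    m <- do.call(rbind, intervals)
    data.frame(start = m[, 1L], end = m[, 2L])
  } else data.frame(start = integer(), end = integer())
  masked <- if (nrow(iv)) sum(iv$end - iv$start) else 0L
  structure(list(intervals = iv, fraction = masked / L, length = L),
            class = "complexity_mask")
}

#' Disorder profile from a propensity scale
#'
#' Per-residue disorder score as the centered moving average of a
#' residue propensity scale (default [top_idp_scale]); at the sequence
#' ends the window shrinks to the available residues. A residue is
#' called disordered exactly when its score exceeds `threshold`. This is
#' a transparent propensity-scale profile, not a trained predictor: the
#' pipeline consumes only the disordered fraction, for comparing
#' distributions between strata.
#'
#' @param seq protein sequence.
#' @param scale named propensity vector covering the alphabet.
#' @param threshold call threshold (default 0).
#' @param smooth_window centered smoothing window, odd (default 21).
#' @return A list of class `disorder_profile`: `score` (per residue),
#'   `call` (logical), `fraction`, `window_shrunk` flag.
#' @export
disorder_fraction <- function(seq, scale = top_idp_scale, threshold = 0,
                              smooth_window = 21L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  .check_protein_chars(chars)
  if (anyNA(scale[chars])) stop("propensity scale does not cover the sequence alphabet")
  v <- unname(scale[chars])
  L <- length(v)
  h <- (smooth_window - 1L) %/% 2L
  shrunk <- L < smooth_window
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  score <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  call <- score > threshold
  structure(list(score = score, call = call, fraction = mean(call),
                 window_shrunk = shrunk),
            class = "disorder_profile")
}

#' Compositionally biased regions
#'
#' Scans every length-`window` subsequence for residues occurring more
#' often than expected under the background composition, using the
#' upper-tail binomial P(X >= k; w, f). Overlapping significant windows
#' for the same residue are merged into maximal runs and the lowest p in
#' each run reported. X residues are excluded from the counts and the
#' effective window size. A residue observed despite background
#' frequency 0 yields a p = 0 sentinel, flagged.
#'
#' @param seq protein sequence.
#' @param background_freqs named frequency vector over the 20 amino
#'   acids, summing to 1 (default uniform).
#' @param window window length (default 15).
#' @param p_max significance threshold per window (default 1e-3).
#' @return Data frame: `start`, `end` (0-based half-open), `residue`,
#'   `p`, `zero_background` flag. Empty when nothing is significant.
#' @export
bias_regions <- function(seq, background_freqs = NULL, window = 15L, p_max = 1e-3) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  .check_protein_chars(chars)
  aa <- .AA_ALPHABET[1:20]
  if (is.null(background_freqs))
    background_freqs <- stats::setNames(rep(1 / 20, 20), aa)
  if (abs(sum(background_freqs) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  L <- length(chars)
  w <- min(window, L)
  n_win <- L - w + 1L
  hits <- list()
  for (i in seq_len(n_win)) {
    win <- chars[i:(i + w - 1L)]
    win <- win[win != "X"]
    if (!length(win)) next
    cnt <- table(win)
    for (r in names(cnt)) {
      k <- cnt[[r]]
      f <- background_freqs[[r]]
      if (is.null(f)) f <- 0
      if (f == 0) {
        hits[[length(hits) + 1L]] <- list(start = i - 1L, end = i - 1L + w,
                                          residue = r, p = 0, zero = TRUE)
        next
      }
      p <- stats::pbinom(k - 1, length(win), f, lower.tail = FALSE)
      if (p < p_max)
        hits[[length(hits) + 1L]] <- list(start = i - 1L, end = i - 1L + w,
                                          residue = r, p = p, zero = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), residue = character(),
                      p = numeric(), zero_background = logical(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(hits, as.data.frame, stringsAsFactors = FALSE))
  out <- list()
  for (r in unique(df$residue)) {
    sub <- df[df$residue == r, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start[i] <= cur$end) {      # overlap or adjacency -> extend run
        cur$end <- max(cur$end, sub$end[i])
        cur$p <- min(cur$p, sub$p[i])
        cur$zero <- cur$zero || sub$zero[i]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$residue), , drop = FALSE]
  data.frame(start = res$start, end = res$end, residue = res$residue,
             p = res$p, zero_background = res$zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

.window_matrix <- function(windows) {
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("all windows must share one width")
  do.call(rbind, strsplit(windows, "", fixed = TRUE))
}

#' Greedy motif over-representation (motif-x style)
#'
#' Iteratively builds fixed-width motifs from aligned foreground windows
#' by repeatedly fixing the (position, residue) pair with the smallest
#' upper-tail binomial p-value against the background composition at
#' that position, accepting a step when p is below `p_per_step` and the
#' matching foreground windows number at least `min_occ`. Matching
#' windows are removed from both sets after each completed motif and the
#' recursion restarts until no pair qualifies.
#'
#' @param foreground character vector of equal-width windows (same
#'   central-residue convention as the background).
#' @param background character vector of equal-width windows.
#' @param min_occ minimum foreground occurrences per motif (default 20).
#' @param p_per_step per-step binomial significance (default 1e-6).
#' @return Data frame: `pattern` (`.` = unconstrained), `fg_matches`,
#'   `bg_matches`, `score` (sum of -log10 step p-values). Empty when no
#'   motif qualifies; a warning is raised when the foreground is smaller
#'   than `min_occ`.
#' @export
motif_enrich <- function(foreground, background, min_occ = 20L, p_per_step = 1e-6) {
  empty <- data.frame(pattern = character(), fg_matches = integer(),
                      bg_matches = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(foreground) < min_occ) {
    warning("foreground smaller than min_occ (", length(foreground),
            " < ", min_occ, "): no motifs")
    return(empty)
  }
  fg_all <- .window_matrix(foreground)
  bg_all <- .window_matrix(background)
  if (ncol(fg_all) != ncol(bg_all)) stop("foreground/background widths differ")
  width <- ncol(fg_all)
  motifs <- list()
  repeat {
    fg <- fg_all; bg <- bg_all
    fixed <- rep(NA_character_, width)
    score <- 0
    repeat {
      if (nrow(fg) < min_occ) break
      best <- NULL
      for (pos in which(is.na(fixed))) {
        tab <- table(fg[, pos])
        for (r in names(tab)) {
          k <- tab[[r]]
          if (k < min_occ) next
          n_bg <- max(nrow(bg), 1L)
          f <- max(sum(bg[, pos] == r) / n_bg, 1 / (2 * n_bg))
          p <- stats::pbinom(k - 1, nrow(fg), f, lower.tail = FALSE)
          if (is.null(best) || p < best$p) best <- list(pos = pos, r = r, p = p)
        }
      }
      if (is.null(best) || best$p >= p_per_step) break
      fixed[best$pos] <- best$r
      score <- score - log10(max(best$p, .Machine$double.xmin))
      fg <- fg[fg[, best$pos] == best$r, , drop = FALSE]
      bg <- bg[bg[, best$pos] == best$r, , drop = FALSE]
    }
    if (all(is.na(fixed))) break
    keep_fg <- rep(TRUE, nrow(fg_all)); keep_bg <- rep(TRUE, nrow(bg_all))
    for (pos in which(!is.na(fixed))) {
      keep_fg <- keep_fg & fg_all[, pos] == fixed[pos]
      keep_bg <- keep_bg & bg_all[, pos] == fixed[pos]
    }
    pat <- fixed; pat[is.na(pat)] <- "."
    motifs[[length(motifs) + 1L]] <-
      data.frame(pattern = paste(pat, collapse = ""),
                 fg_matches = sum(keep_fg), bg_matches = sum(keep_bg),
                 score = score, stringsAsFactors = FALSE)
    fg_all <- fg_all[!keep_fg, , drop = FALSE]
    bg_all <- bg_all[!keep_bg, , drop = FALSE]
    if (nrow(fg_all) < min_occ) break
  }
  if (!length(motifs)) return(empty)
  do.call(rbind, motifs)
}

#' Find Ser-(Pro)3-4 tandem repeats
#'
#' Locates maximal runs of consecutive `S(P){3,4}` units, the defining
#' repeat of extensin-like cell-wall proteins, requiring at least
#' `min_units` consecutive units.
#'
#' @param seq protein sequence.
#' @param min_units minimum consecutive units (default 2).
#' @return Data frame `start`, `end` (0-based half-open), `n_units`.
#' @export
find_sp_repeats <- function(seq, min_units = 2L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  pat <- sprintf("(?:SP{3,4}){%d,}", min_units)
  m <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(), n_units = integer()))
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  n_units <- vapply(seq_along(starts), function(i) {
    sub <- substr(s, starts[i] + 1L, ends[i])
    length(gregexpr("SP{3,4}", sub, perl = TRUE)[[1L]])
  }, 1L)
  data.frame(start = starts, end = ends, n_units = n_units)
}

#' Secretory/membrane targeting gate
#'
#' Classifies a protein's targeting evidence with the precedence signal
#' peptide > signal anchor > transmembrane domain: `SECRETORY_SP`,
#' `SECRETORY_SA`, `MEMBRANE_TM`, else `NONE`. The coccolith-candidate
#' (COPRO) qualifying classes are the first three. A missing annotation
#' row is treated conservatively as `NONE` with a warning.
#'
#' @param annotation one-row data frame (or list) with logical fields
#'   `sp`, `sa`, `tm`; or `NULL`/all-NA for missing.
#' @return One of `"SECRETORY_SP"`, `"SECRETORY_SA"`, `"MEMBRANE_TM"`,
#'   `"NONE"`.
#' @export
targeting_gate <- function(annotation) {
  if (is.null(annotation) || !length(annotation)) {
    warning("missing targeting annotation: classified NONE")
    return("NONE")
  }
  g <- function(f) isTRUE(as.logical(annotation[[f]]))
  if (g("sp")) "SECRETORY_SP"
  else if (g("sa")) "SECRETORY_SA"
  else if (g("tm")) "MEMBRANE_TM"
  else "NONE"
}

#' Built-in heuristic targeting predictor
#'
#' A deliberately simple stand-in used only so synthetic tests can run
#' without an external predictor table: a run of >= `min_h` hydrophobic
#' residues starting within the first `n_start` residues marks a
#' candidate signal sequence, called a signal peptide when a small
#' residue (A/G/S/C) sits at the -1 cleavage-like boundary position
#' after the run, otherwise a signal anchor; any later hydrophobic run
#' of >= `min_tm` residues sets the transmembrane flag. Real analyses
#' should supply predictor output tables instead.
#'
#' @param seq protein sequence.
#' @param min_h minimum N-terminal hydrophobic run (default 8).
#' @param n_start latest admissible start of the run (default 12).
#' @param min_tm minimum internal hydrophobic run (default 17).
#' @return Data frame with logical `sp`, `sa`, `tm`.
#' @export
predict_targeting <- function(seq, min_h = 8L, n_start = 12L, min_tm = 17L) {
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hydro <- chars %in% c("A", "I", "L", "M", "F", "V", "W", "C")
  runs <- rle(hydro)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sp <- sa <- tm <- FALSE
  for (i in seq_along(runs$lengths)) {
    if (!runs$values[i]) next
    if (starts[i] <= n_start && runs$lengths[i] >= min_h) {
      boundary <- min(ends[i] + 5L, length(chars))
      if (boundary > ends[i] && any(chars[(ends[i] + 1L):boundary] %in% c("A", "G", "S", "C")))
        sp <- TRUE else sa <- TRUE
    } else if (starts[i] > n_start && runs$lengths[i] >= min_tm) {
      tm <- TRUE
    }
  }
  if (sp) sa <- FALSE
  data.frame(sp = sp, sa = sa, tm = tm)
}
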