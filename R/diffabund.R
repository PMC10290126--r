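#' Reference-channel normalization of log2 reporter intensities
#'
#' Each value is replaced by its log2 ratio to a reference channel — an
#' explicit channel, or an "artificial reference" formed as the rowwise
#' mean of all channels — and each channel is then median-centered
#' (the median of its ratios subtracted). Applying the transform to an
#' already-normalized matrix leaves it unchanged.
#'
#' @param matrix numeric matrix of log2 intensities, proteins in rows,
#'   channels in columns (dimnames required).
#' @param reference_channel column name of the reference channel, or
#'   `NULL` (default) for the artificial rowwise-mean reference.
#' @return Matrix of median-centered log2 ratios; rows whose reference
#'   value is missing are flagged in the `missing_reference` attribute.
#' @export
normalize_md <- function(matrix, reference_channel = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  ref <- if (is.null(reference_channel)) {
    rowMeans(matrix, na.rm = TRUE)
  } else {
    if (!reference_channel %in% colnames(matrix))
      stop("reference channel not in matrix: ", reference_channel)
    matrix[, reference_channel]
  }
  miss <- !is.finite(ref)
  ratios <- sweep(matrix, 1L, ref, "-")
  med <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  out <- sweep(ratios, 2L, med, "-")
  attr(out, "missing_reference") <- rownames(matrix)[miss]
  out
}

# Newton inversion of trigamma, as needed for moment matching of the
# prior degrees of freedom (solve trigamma(y) = x for y > 0).
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, 0)
}

# Moment-matching fit of the scaled-F model for sample variances:
# s^2 ~ s0^2 * F(d, d0). Closed-form on log variances via digamma /
# trigamma moments; d0 = Inf when the observed spread is no wider than
# the chi-square sampling spread.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & df > 0 & s2 > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) stop("need at least 2 variances to fit the prior")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1L) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(ebar)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' Per-protein two-sample comparison with variance shrinkage: sample
#' variances are modeled as scaled-F draws around a prior variance
#' `s0^2` with prior degrees of freedom `d0`, both estimated by
#' closed-form moment matching on log variances. The posterior variance
#' `(d0*s0^2 + d*s^2) / (d0 + d)` replaces `s^2` in the t statistic,
#' which is referred to `d0 + d` degrees of freedom. With `d0 = 0` the
#' ordinary two-sample pooled t-test is recovered; with `d0 = Inf` all
#' proteins share one variance. Missing values are handled
#' pairwise-complete per protein; proteins with fewer than two complete
#' values in either group are marked untestable and excluded from the
#' BH adjustment denominator.
#'
#' @param matrix numeric matrix (proteins x samples) of normalized log2
#'   values.
#' @param design factor or character vector of length `ncol(matrix)`
#'   with exactly two levels; the log2 fold change is level2 - level1.
#' @param d0 optional fixed prior degrees of freedom overriding the
#'   moment estimate (use `0` for the ordinary t-test).
#' @return A list of class `moderated_test`: `table` (protein, logFC,
#'   t, df_total, p, adj_p, testable), `d0`, `s0_2`.
#' @export
moderated_t <- function(matrix, design, d0 = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(design))
  design <- as.factor(design)
  if (nlevels(design) != 2L) stop("design must have exactly two groups")
  g1 <- design == levels(design)[1L]
  g2 <- design == levels(design)[2L]
  n_prot <- nrow(matrix)
  m1 <- m2 <- s2 <- df <- rep(NA_real_, n_prot)
  n1 <- n2 <- integer(n_prot)
  for (i in seq_len(n_prot)) {
    x1 <- matrix[i, g1]; x1 <- x1[is.finite(x1)]
    x2 <- matrix[i, g2]; x2 <- x2[is.finite(x2)]
    n1[i] <- length(x1); n2[i] <- length(x2)
    if (n1[i] >= 2L && n2[i] >= 2L) {
      m1[i] <- mean(x1); m2[i] <- mean(x2)
      s2[i] <- (sum((x1 - m1[i])^2) + sum((x2 - m2[i])^2)) / (n1[i] + n2[i] - 2L)
      df[i] <- n1[i] + n2[i] - 2L
    }
  }
  testable <- is.finite(df)
  if (sum(testable) < 2L) stop("fewer than 2 testable proteins")
  if (is.null(d0)) {
    prior <- .fit_variance_prior(s2[testable], df[testable])
    d0 <- prior$d0; s0_2 <- prior$s0_2
  } else {
    s0_2 <- if (d0 > 0) mean(s2[testable]) else 0
  }
  post_s2 <- if (is.infinite(d0)) rep(s0_2, n_prot) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  se <- sqrt(post_s2 * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- lfc / se
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(tstat), df_total)
  p[!testable] <- NA_real_
  adj <- bh_adjust(p)
  prot <- rownames(matrix)
  if (is.null(prot)) prot <- sprintf("protein_%d", seq_len(n_prot))
  structure(list(table = data.frame(protein = prot, logFC = lfc, t = tstat,
                                    df_total = df_total, p = p, adj_p = adj,
                                    testable = testable,
                                    stringsAsFactors = FALSE),
                 d0 = d0, s0_2 = s0_2),
            class = "moderated_test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps the standard step-up procedure; `NA` inputs are excluded from
#' the test count `m` and propagated as `NA`. Output is invariant to
#' input order and monotone in p-value rank.
#'
#' @param p_values numeric vector of p-values in `[0,1]` (NA allowed).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must lie in [0,1]")
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Count significantly regulated proteins
#'
#' Strict-inequality count of proteins with BH-adjusted p below `alpha`,
#' with the qualifying list sorted by adjusted p then id.
#'
#' @param results a `moderated_test` from [moderated_t()] (or its `table`).
#' @param alpha significance level (default 0.05).
#' @return List: `n`, `proteins` (data frame sorted by adj_p, protein).
#' @export
count_regulated <- function(results, alpha = 0.05) {
  tab <- if (inherits(results, "moderated_test")) results$table else results
  stopifnot(all(c("protein", "adj_p") %in% names(tab)))
  hit <- !is.na(tab$adj_p) & tab$adj_p < alpha
  sel <- tab[hit, , drop = FALSE]
  sel <- sel[order(sel$adj_p, sel$protein), , drop = FALSE]
  rownames(sel) <- NULL
  list(n = nrow(sel), proteins = sel)
}
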