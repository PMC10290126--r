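#' Construct a peak list (one MS/MS spectrum)
#'
#' @param id spectrum id (unique within a collection).
#' @param precursor_mz precursor m/z.
#' @param mz fragment m/z values (sorted ascending on construction).
#' @param intensity matching non-negative intensities.
#' @param charge optional precursor charge (NA when unknown).
#' @param denovo_score optional de novo sequencing quality score.
#' @param sample optional sample id.
#' @return A list of class `peaklist`.
#' @export
peaklist <- function(id, precursor_mz, mz, intensity, charge = NA_integer_,
                     denovo_score = NA_real_, sample = NA_character_) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L,
            all(intensity >= 0), is.numeric(precursor_mz))
  ord <- order(mz)
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 charge = as.integer(charge), mz = mz[ord],
                 intensity = intensity[ord],
                 denovo_score = as.numeric(denovo_score),
                 sample = as.character(sample)),
            class = "peaklist")
}

#' Read / write spectra in MGF format
#'
#' Minimal Mascot Generic Format support: `BEGIN IONS`/`END IONS` blocks
#' with `TITLE=`, `PEPMASS=`, optional `CHARGE=` and the optional
#' per-spectrum user parameter `DENOVO_SCORE=`; peak lines are
#' whitespace-separated m/z and intensity. No installed R package reads
#' MGF, so this small reader/writer is provided here. A sidecar TSV
#' (columns `spectrum_id`, `denovo_score`) may supply scores instead of
#' in-file parameters.
#'
#' @param path MGF file.
#' @param scores optional sidecar data frame (`spectrum_id`,
#'   `denovo_score`) overriding in-file scores.
#' @return A list of [peaklist] objects, in file order.
#' @export
read_mgf <- function(path, scores = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      score <- NA_real_; sample <- NA_character_
      mz <- numeric(); int <- numeric()
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
        else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1L]][1L])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (startsWith(ln, "DENOVO_SCORE=")) {
          score <- as.numeric(sub("^DENOVO_SCORE=", "", ln))
        } else if (startsWith(ln, "SAMPLE=")) {
          sample <- sub("^SAMPLE=", "", ln)
        } else if (nzchar(ln) && !grepl("^[A-Z_]+=", ln)) {
          parts <- as.numeric(strsplit(ln, "\\s+")[[1L]])
          mz <- c(mz, parts[1L]); int <- c(int, parts[2L])
        }
        i <- i + 1L
      }
      if (is.na(title)) stop("spectrum without TITLE in ", path)
      out[[length(out) + 1L]] <-
        peaklist(title, pepmass, mz, int, charge, score, sample)
    }
    i <- i + 1L
  }
  if (!is.null(scores)) {
    stopifnot(all(c("spectrum_id", "denovo_score") %in% names(scores)))
    idx <- match(vapply(out, `[[`, "", "id"), scores$spectrum_id)
    for (j in seq_along(out))
      if (!is.na(idx[j])) out[[j]]$denovo_score <- scores$denovo_score[idx[j]]
  }
  out
}

#' @rdname read_mgf
#' @param spectra list of [peaklist] objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)), con)
    if (!is.na(sp$charge)) writeLines(paste0("CHARGE=", sp$charge, "+"), con)
    if (!is.na(sp$denovo_score))
      writeLines(paste0("DENOVO_SCORE=", format(sp$denovo_score, digits = 10)), con)
    if (!is.na(sp$sample)) writeLines(paste0("SAMPLE=", sp$sample), con)
    writeLines(paste(format(sp$mz, digits = 10, trim = TRUE),
                     format(sp$intensity, digits = 10, trim = TRUE)), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Gate spectra by de novo quality score
#'
#' Retains exactly the spectra whose de novo score is at or above the
#' cutoff (spectra scoring less are discarded), preserving input order.
#' Spectra without a score are dropped with a warning and counted in the
#' `n_unscored` attribute.
#'
#' @param spectra list of [peaklist] objects.
#' @param cutoff score cutoff (default 60).
#' @return Filtered list with attributes `n_input`, `n_unscored`.
#' @export
gate_by_denovo <- function(spectra, cutoff = 60) {
  scores <- vapply(spectra, `[[`, 0, "denovo_score")
  unscored <- is.na(scores)
  if (any(unscored))
    warning(sum(unscored), " spectra lack a de novo score and were dropped")
  keep <- !unscored & scores >= cutoff
  out <- spectra[keep]
  attr(out, "n_input") <- length(spectra)
  attr(out, "n_unscored") <- sum(unscored)
  out
}

.binned_vector <- function(sp, bin_width) {
  bins <- floor(sp$mz / bin_width)
  v <- tapply(sqrt(sp$intensity), bins, sum)
  stats::setNames(as.numeric(v), names(v))
}

.cosine_named <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  num <- sum(a[shared] * b[shared])
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) 0 else num / den
}

#' Similarity between two spectra
#'
#' Normalized dot product (cosine) of square-root-transformed
#' intensities summed into fixed-width m/z bins. Symmetric, 1 for
#' identical spectra, 0 for spectra sharing no bin.
#'
#' @param a,b [peaklist] objects.
#' @param bin_width m/z bin width (default 0.5).
#' @return Similarity in `[0,1]`.
#' @export
spectrum_similarity <- function(a, b, bin_width = 0.5) {
  .cosine_named(.binned_vector(a, bin_width), .binned_vector(b, bin_width))
}

#' Greedy spectral clustering
#'
#' Deterministic single-pass clustering: spectra are pre-sorted by
#' (precursor m/z, id); each spectrum joins the cluster of highest
#' consensus similarity among clusters whose mean precursor m/z is
#' within `precursor_tol` (and whose charge matches when both are
#' annotated), provided that similarity reaches `threshold`; otherwise
#' it seeds a new cluster. The consensus is the sum of members' binned
#' square-root-intensity vectors. The output clusters partition the
#' input.
#'
#' @param spectra list of [peaklist] objects (typically gated).
#' @param threshold similarity threshold in `[0,1]` (default 0.7).
#' @param precursor_tol precursor m/z tolerance (default 2).
#' @param bin_width m/z bin width for the similarity kernel (default 0.5).
#' @return List of clusters, each a list with `id`, `members` (spectrum
#'   ids), `precursor_mz`, `charge`, `consensus` (named binned vector).
#' @export
cluster_spectra <- function(spectra, threshold = 0.7, precursor_tol = 2,
                            bin_width = 0.5) {
  if (!length(spectra)) return(list())
  ids <- vapply(spectra, `[[`, "", "id")
  pmz <- vapply(spectra, `[[`, 0, "precursor_mz")
  ord <- order(pmz, ids)
  spectra <- spectra[ord]
  pmz <- pmz[ord]
  clusters <- list()
  cl_pmz <- numeric()
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    v <- .binned_vector(sp, bin_width)
    best <- 0; best_j <- NA_integer_
    if (length(clusters)) {
      cand <- which(abs(cl_pmz - sp$precursor_mz) <= precursor_tol)
      for (j in cand) {
        cl <- clusters[[j]]
        if (!is.na(cl$charge) && !is.na(sp$charge) && cl$charge != sp$charge) next
        s <- .cosine_named(v, cl$consensus)
        if (s > best) { best <- s; best_j <- j }
      }
    }
    if (!is.na(best_j) && best >= threshold) {
      cl <- clusters[[best_j]]
      cl$members <- c(cl$members, sp$id)
      shared <- union(names(cl$consensus), names(v))
      cons <- stats::setNames(numeric(length(shared)), shared)
      cons[names(cl$consensus)] <- cl$consensus
      cons[names(v)] <- cons[names(v)] + v
      cl$consensus <- cons
      cl$precursor_mz <- (cl$precursor_mz * (length(cl$members) - 1L) +
                            sp$precursor_mz) / length(cl$members)
      clusters[[best_j]] <- cl
      cl_pmz[best_j] <- cl$precursor_mz
    } else {
      clusters[[length(clusters) + 1L]] <-
        list(id = sprintf("cluster_%d", length(clusters) + 1L),
             members = sp$id, precursor_mz = sp$precursor_mz,
             charge = sp$charge, consensus = v)
      cl_pmz <- c(cl_pmz, sp$precursor_mz)
    }
  }
  clusters
}

#' Cluster identification rate under one search database
#'
#' A cluster counts as identified when at least one member spectrum has
#' a peptide-spectrum match at or above the peptide probability cutoff
#' in the supplied PSM table; the rate is identified clusters over all
#' clusters. PSMs for spectra absent from the clustering are ignored but
#' counted.
#'
#' @param clusters output of [cluster_spectra()].
#' @param psm_table data frame with columns `spectrum_id`, `probability`
#'   (best peptide probability per spectrum under one database).
#' @param peptide_prob_cutoff probability cutoff (default 0.95).
#' @param sample_id,database_id optional labels carried into the result.
#' @return One-row data frame: `sample_id`, `database_id`, `n_clusters`,
#'   `n_identified`, `rate`, `n_unmatched_psms`.
#' @export
cluster_id_rate <- function(clusters, psm_table, peptide_prob_cutoff = 0.95,
                            sample_id = NA_character_, database_id = NA_character_) {
  stopifnot(all(c("spectrum_id", "probability") %in% names(psm_table)))
  member_ids <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  unmatched <- sum(!psm_table$spectrum_id %in% member_ids)
  hits <- unique(psm_table$spectrum_id[psm_table$probability >= peptide_prob_cutoff])
  identified <- vapply(clusters, function(cl) any(cl$members %in% hits), TRUE)
  n <- length(clusters)
  data.frame(sample_id = sample_id, database_id = database_id,
             n_clusters = n, n_identified = sum(identified),
             rate = if (n) sum(identified) / n else 0,
             n_unmatched_psms = unmatched, stringsAsFactors = FALSE)
}

#' Resample a control score distribution to match a reference
#'
#' Stratified resampling of control spectra so the per-bin proportions
#' of their de novo scores match the reference histogram (bins over the
#' pooled score range). The resample is the largest achievable without
#' replacement; reference bins with mass but too few control candidates
#' are under-filled and reported. Kolmogorov-Smirnov statistics between
#' control and reference scores are returned before and after matching.
#'
#' @param control_spectra list of [peaklist] objects with scores.
#' @param reference_scores numeric vector of reference scores.
#' @param n_bins number of histogram bins (default 20).
#' @param seed integer seed for within-bin sampling.
#' @return List: `spectra` (resampled subset), `ks_before`, `ks_after`,
#'   `underfilled` (data frame of short bins), `n_selected`.
#' @export
match_score_distribution <- function(control_spectra, reference_scores,
                                     n_bins = 20L, seed = 1L) {
  scores <- vapply(control_spectra, `[[`, 0, "denovo_score")
  if (!length(scores) || !length(reference_scores))
    stop("both score collections must be non-empty")
  ks_before <- suppressWarnings(
    unname(stats::ks.test(scores, reference_scores)$statistic))
  rng <- range(c(scores, reference_scores))
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  ref_bin <- bin_of(reference_scores)
  ctl_bin <- bin_of(scores)
  prop <- tabulate(ref_bin, n_bins) / length(reference_scores)
  avail <- tabulate(ctl_bin, n_bins)
  active <- prop > 0
  if (!any(avail[active] > 0)) {
    warning("control and reference score distributions do not overlap: empty resample")
    return(list(spectra = list(), ks_before = ks_before, ks_after = NA_real_,
                underfilled = data.frame(), n_selected = 0L))
  }
  m <- floor(min(ifelse(active & avail > 0, avail / prop, Inf)[active]))
  want <- ifelse(active, round(m * prop), 0L)
  take <- pmin(want, avail)
  underfilled <- data.frame(bin = which(take < want),
                            wanted = want[take < want],
                            available = avail[take < want])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sel <- integer()
  for (b in which(take > 0)) {
    idx <- which(ctl_bin == b)
    sel <- c(sel, if (length(idx) == take[b]) idx else sample(idx, take[b]))
  }
  sel <- sort(sel)
  ks_after <- if (length(sel) >= 2L)
    suppressWarnings(unname(stats::ks.test(scores[sel], reference_scores)$statistic))
  else NA_real_
  list(spectra = control_spectra[sel], ks_before = ks_before,
       ks_after = ks_after, underfilled = underfilled, n_selected = length(sel))
}
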