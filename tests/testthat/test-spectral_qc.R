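mk_spec <- function(id, mz, int, pmz = 500, score = NA, charge = 2L)
  peaklist(id, pmz, mz, int, charge = charge, denovo_score = score)

test_that("MGF round-trips spectra including scores", {
  sp <- list(mk_spec("s1", c(100.02, 250.5), c(10, 20), pmz = 450.25, score = 72.5),
             mk_spec("s2", c(300.1), c(5), pmz = 600))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  back <- read_mgf(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "s1")
  expect_equal(back[[1]]$mz, c(100.02, 250.5))
  expect_equal(back[[1]]$denovo_score, 72.5)
  expect_equal(back[[2]]$precursor_mz, 600)
  # sidecar score table overrides
  scores <- data.frame(spectrum_id = "s2", denovo_score = 80)
  back2 <- read_mgf(f, scores = scores)
  expect_equal(back2[[2]]$denovo_score, 80)
})

test_that("de novo gating keeps scores at or above the cutoff", {
  sp <- list(mk_spec("a", 100, 1, score = 59.9),
             mk_spec("b", 100, 1, score = 60),
             mk_spec("c", 100, 1, score = 60.1),
             mk_spec("d", 100, 1))
  expect_warning(g <- gate_by_denovo(sp, 60), "lack a de novo score")
  expect_equal(vapply(g, `[[`, "", "id"), c("b", "c"))
  expect_equal(attr(g, "n_unscored"), 1)
  all_low <- list(mk_spec("a", 100, 1, score = 10))
  expect_length(gate_by_denovo(all_low, 60), 0)
})

test_that("gated fraction follows the planted score mixture", {
  sp <- gen_spectra(n_peptides = 200, clones_per_peptide = 2,
                    db_coverage = c(A = 1), noise = 0.1, seed = 8,
                    junk_frac = 0.5)
  g <- gate_by_denovo(sp$spectra, 60)
  n_real <- sum(sp$truth$real)
  n_junk <- sum(!sp$truth$real)
  expected <- n_real * pnorm(60, 75, 8, lower.tail = FALSE) +
    n_junk * pnorm(60, 40, 10, lower.tail = FALSE)
  expect_lt(abs(length(g) - expected), 3 * sqrt(expected))
})

test_that("spectrum similarity is the binned square-root cosine", {
  a <- mk_spec("a", c(100.1, 200.2), c(4, 9))
  expect_equal(spectrum_similarity(a, a), 1.0)
  b <- mk_spec("b", c(300.3, 400.4), c(4, 9))
  expect_equal(spectrum_similarity(a, b), 0.0)
  # one shared equal-intensity bin of two
  c1 <- mk_spec("c1", c(100.1, 200.2), c(1, 1))
  c2 <- mk_spec("c2", c(200.2, 300.3), c(1, 1))
  expect_equal(spectrum_similarity(c1, c2), 0.5)
  expect_equal(spectrum_similarity(c1, c2), spectrum_similarity(c2, c1))
})

test_that("clustering groups identical spectra and separates disjoint ones", {
  trip <- lapply(1:3, function(i) mk_spec(paste0("t", i), c(100, 200, 300), c(1, 2, 3)))
  cl <- cluster_spectra(trip, threshold = 0.7)
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 3)

  disj <- list(mk_spec("a", 100, 1), mk_spec("b", 200, 1), mk_spec("c", 300, 1))
  cl2 <- cluster_spectra(disj, threshold = 0.1)
  expect_length(cl2, 3)

  # partition property: members equal the input spectrum set exactly
  sp <- gen_spectra(60, 3, c(A = 0.5), noise = 0.2, seed = 2)$spectra
  cl3 <- cluster_spectra(gate_by_denovo(sp, 60), threshold = 0.7)
  members <- unlist(lapply(cl3, `[[`, "members"))
  expect_equal(sort(members),
               sort(unname(vapply(gate_by_denovo(sp, 60), `[[`, "", "id"))))
  expect_false(anyDuplicated(members) > 0)
})

test_that("clustering recovers the planted partition at low noise", {
  sp <- gen_spectra(n_peptides = 120, clones_per_peptide = 3,
                    db_coverage = c(A = 0.8), noise = 0.1, seed = 4)
  gated <- gate_by_denovo(sp$spectra, 60)
  cl <- cluster_spectra(gated, threshold = 0.7)
  ids <- vapply(gated, `[[`, "", "id")
  truth <- sp$truth$cluster[match(ids, sp$truth$spectrum_id)]
  assigned <- rep(NA_character_, length(ids))
  for (c in cl) assigned[match(c$members, ids)] <- c$id
  expect_gte(mclust::adjustedRandIndex(truth, assigned), 0.95)
})

test_that("cluster identification rates count clusters with a passing member", {
  clusters <- lapply(1:10, function(i)
    list(id = paste0("cl", i), members = paste0("s", i)))
  psm <- data.frame(spectrum_id = paste0("s", 1:7),
                    probability = rep(0.99, 7))
  r <- cluster_id_rate(clusters, psm)
  expect_equal(r$rate, 0.7)
  expect_equal(r$n_identified, 7)
  r0 <- cluster_id_rate(clusters, psm[0, ])
  expect_equal(r0$rate, 0)
  # monotonicity: adding PSMs can never decrease the rate
  psm2 <- rbind(psm, data.frame(spectrum_id = "s9", probability = 0.96))
  expect_gte(cluster_id_rate(clusters, psm2)$rate, r$rate)
  # PSMs for unknown spectra are ignored but counted
  psm3 <- rbind(psm, data.frame(spectrum_id = "zz", probability = 0.99))
  r3 <- cluster_id_rate(clusters, psm3)
  expect_equal(r3$rate, 0.7)
  expect_equal(r3$n_unmatched_psms, 1)
})

test_that("database coverage drives the identification-rate difference", {
  diffs <- numeric(10)
  for (s in 1:10) {
    sp <- gen_spectra(n_peptides = 100, clones_per_peptide = 2,
                      db_coverage = c(A = 0.8, B = 0.5), noise = 0.1,
                      seed = 100 + s)
    gated <- gate_by_denovo(sp$spectra, 60)
    cl <- cluster_spectra(gated, threshold = 0.7)
    ra <- cluster_id_rate(cl, sp$psm$A)$rate
    rb <- cluster_id_rate(cl, sp$psm$B)$rate
    expect_gt(ra, rb)
    diffs[s] <- ra - rb
  }
  expect_lt(abs(mean(diffs) - 0.3), 0.12)
})

test_that("score-distribution matching shrinks the KS distance", {
  set.seed(6)
  ctrl <- lapply(seq_len(4000), function(i)
    mk_spec(paste0("c", i), 100, 1, score = rnorm(1, 70, 12)))
  ref <- rnorm(4000, 60, 8)
  m <- match_score_distribution(ctrl, ref, seed = 3)
  expect_lt(m$ks_after, 0.05)
  expect_lt(m$ks_after, m$ks_before)
  # reference == control scores: resample stays close to the reference
  scores <- vapply(ctrl, `[[`, 0, "denovo_score")
  m2 <- match_score_distribution(ctrl, scores, seed = 3)
  expect_lt(m2$ks_after, 0.05)
  # disjoint ranges: empty resample with a hard warning
  lo <- lapply(1:50, function(i) mk_spec(paste0("l", i), 100, 1, score = i / 10))
  expect_warning(m3 <- match_score_distribution(lo, 900 + 1:50, seed = 1),
                 "do not overlap")
  expect_equal(m3$n_selected, 0)
})
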