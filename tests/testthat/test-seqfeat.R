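test_that("segmentation masks homopolymers and leaves diverse sequence alone", {
  m <- seg_mask(strrep("A", 12))
  expect_equal(m$fraction, 1.0)
  expect_equal(m$intervals, data.frame(start = 0L, end = 12L))

  mixed <- "ACDEFGHIKLMNPQRSTVWY"              # 20 distinct residues
  expect_equal(seg_mask(mixed)$fraction, 0)

  # planted poly-Q tract inside a diverse 30-mer
  seqq <- paste0("ACDEFGHK", strrep("Q", 14), "LMNPWYRS")
  m2 <- seg_mask(seqq)
  expect_equal(m2$fraction, oracle_seg_fraction(seqq))
  expect_gt(m2$fraction, 14 / 30 - 0.2)
  expect_error(seg_mask("AAZB"), "non-amino-acid character 'Z' at position 3")
})

test_that("segmentation equals the all-windows oracle on random sequences", {
  set.seed(101)
  for (rep in 1:120) {
    len <- sample(5:60, 1)
    s <- if (runif(1) < 0.5) random_protein(len) else
      paste(sample(c("A", "P", "S", "Q"), len, replace = TRUE), collapse = "")
    expect_equal(seg_mask(s)$fraction, oracle_seg_fraction(s), info = s)
  }
})

test_that("masked fraction is invariant under sequence reversal", {
  set.seed(55)
  for (rep in 1:40) {
    s <- paste(sample(c("A", "P", "S", "G", "K", "L"), sample(15:70, 1),
                      replace = TRUE), collapse = "")
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(seg_mask(s)$fraction, seg_mask(rs)$fraction)
  }
})

test_that("disorder fractions reflect the propensity scale", {
  expect_equal(disorder_fraction(strrep("E", 40))$fraction, 1.0)
  expect_equal(disorder_fraction(strrep("I", 40))$fraction, 0.0)
  chimera <- paste0(strrep("I", 40), strrep("E", 40))
  expect_equal(disorder_fraction(chimera)$fraction, 0.5, tolerance = 0.1)
  short <- disorder_fraction("EEE")
  expect_true(short$window_shrunk)
  expect_equal(short$fraction, 1.0)
  prof <- disorder_fraction(strrep("E", 30))
  expect_identical(prof$call, prof$score > 0)
})

test_that("bias regions match the direct binomial sum and merge runs", {
  # 10 P in a 12-residue window at f_P = 0.05
  s <- "PPPPPPPPPPKL"
  bg <- setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  bg["A"] <- 1 - 0.05 * 19
  res <- bias_regions(s, bg, window = 12)
  p_expected <- sum(sapply(10:12, function(k) choose(12, k) * 0.05^k * 0.95^(12 - k)))
  prow <- res[res$residue == "P", ]
  expect_equal(prow$p, p_expected, tolerance = 1e-15)
  expect_equal(nrow(prow), 1)                      # merged into one run

  # pure background composition: nothing significant
  set.seed(2)
  s0 <- random_protein(60)
  res0 <- bias_regions(s0, window = 15, p_max = 1e-9)
  expect_equal(nrow(res0), 0)

  # zero-background residue observed -> p = 0 sentinel, flagged
  bg0 <- bg; bg0["W"] <- 0; bg0["A"] <- bg0["A"] + 0.05
  resw <- bias_regions("WKLMNPQRSTVYAH", bg0, window = 14)
  wrow <- resw[resw$residue == "W", ]
  expect_equal(wrow$p, 0)
  expect_true(wrow$zero_background)
})

test_that("bias-region false positives follow the binomial error budget", {
  set.seed(31)
  p_max <- 1e-3
  n_seq <- 60
  n_runs <- 0
  n_tests <- 0
  for (i in seq_len(n_seq)) {
    s <- random_protein(120)
    res <- bias_regions(s, window = 15, p_max = p_max)
    n_runs <- n_runs + nrow(res)
    n_tests <- n_tests + (120 - 15 + 1) * 20
  }
  lambda <- p_max * n_tests
  expect_lte(n_runs, lambda + 3 * sqrt(lambda) + 3)  # 3 sigma + merge slack
})

test_that("motif discovery recovers a planted S..PPP motif and controls type I", {
  set.seed(12)
  bg_windows <- replicate(1000, random_protein(5))
  fg <- c(replicate(100, paste0("S", random_protein(1), "PPP")),
          sample(bg_windows, 200))
  res <- motif_enrich(fg, bg_windows, min_occ = 20, p_per_step = 1e-6)
  expect_gte(nrow(res), 1)
  expect_match(res$pattern[1], "^S.PPP$")

  # foreground == background: nothing
  expect_equal(nrow(motif_enrich(bg_windows[1:100], bg_windows,
                                 min_occ = 20, p_per_step = 1e-6)), 0)
  expect_warning(res5 <- motif_enrich(bg_windows[1:5], bg_windows), "min_occ")
  expect_equal(nrow(res5), 0)

  # label permutation: motifs in < 5% of permutations
  pool <- replicate(400, random_protein(5))
  hits <- 0
  for (perm in 1:60) {
    idx <- sample(length(pool), 150)
    if (nrow(motif_enrich(pool[idx], pool[-idx],
                          min_occ = 20, p_per_step = 1e-6)) > 0)
      hits <- hits + 1
  }
  expect_lte(hits / 60, 0.05)
})

test_that("Ser-Pro repeats are located and destroyed by shuffling", {
  r <- find_sp_repeats("SPPPSPPPP")
  expect_equal(r, data.frame(start = 0L, end = 9L, n_units = 2L))
  expect_equal(nrow(find_sp_repeats("SPP")), 0)
  expect_equal(nrow(find_sp_repeats("SPPPA")), 0)   # one unit < min_units

  set.seed(77)
  seq <- paste0("MA", strrep("SPPP", 6), "KLH", strrep("SPPPP", 3), "GG")
  orig_units <- sum(find_sp_repeats(seq)$n_units)
  chars <- strsplit(seq, "")[[1]]
  worse <- 0
  for (i in 1:300) {
    sh <- paste(sample(chars), collapse = "")
    if (sum(find_sp_repeats(sh)$n_units) < orig_units) worse <- worse + 1
  }
  expect_gte(worse / 300, 0.95)
})

test_that("targeting gate applies SP > SA > TM precedence", {
  expect_equal(targeting_gate(data.frame(sp = TRUE, sa = FALSE, tm = TRUE)),
               "SECRETORY_SP")
  expect_equal(targeting_gate(data.frame(sp = FALSE, sa = TRUE, tm = TRUE)),
               "SECRETORY_SA")
  expect_equal(targeting_gate(data.frame(sp = FALSE, sa = FALSE, tm = TRUE)),
               "MEMBRANE_TM")
  expect_equal(targeting_gate(data.frame(sp = FALSE, sa = FALSE, tm = FALSE)),
               "NONE")
  expect_warning(g <- targeting_gate(NULL), "missing")
  expect_equal(g, "NONE")

  # 23 SP/SA + 3 TM-only pass the gate; unsignalled proteins do not
  ann <- data.frame(sp = c(rep(TRUE, 21), rep(FALSE, 5)),
                    sa = c(rep(FALSE, 21), TRUE, TRUE, rep(FALSE, 3)),
                    tm = c(rep(FALSE, 23), rep(TRUE, 3)))
  gates <- vapply(seq_len(nrow(ann)), function(i) targeting_gate(ann[i, ]), "")
  expect_equal(sum(gates != "NONE"), 26)
})

test_that("the built-in heuristic separates obvious signal sequences", {
  sp_seq <- paste0("MKL", strrep("L", 10), "AGA", random_protein(40))
  none_seq <- paste0("MDE", strrep("KD", 30))
  expect_true(predict_targeting(sp_seq)$sp)
  ann <- predict_targeting(none_seq)
  expect_false(any(unlist(ann)))
})
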