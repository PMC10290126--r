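paper_class_counts <- c(copro_sp = 21, copro_sa = 2, copro_tm = 3,
                        copro_expanded = 42, coccolith_contaminant = 14,
                        cs_exclusive = 78, cs_shared = 17, cs_contaminant = 15,
                        cv = 14, cv_contaminant = 4)

test_that("contaminant screening flags exactly the planted contaminants", {
  det <- gen_detection_tables(250, paper_class_counts, seed = 40)
  screen <- screen_contaminants(unique(det$evidence$protein), det$homology_hits)
  planted <- det$truth$protein[grepl("contaminant", det$truth$class)]
  detected_planted <- intersect(planted, det$evidence$protein)
  expect_setequal(screen$flagged, detected_planted)
  expect_equal(nrow(screen$justification), length(screen$flagged))
  # no hits table: no flags, loud warning
  expect_warning(s0 <- screen_contaminants("p", NULL), "disabled")
  expect_length(s0$flagged, 0)
  # proteins without hits are never flagged
  expect_false("never_seen" %in%
    screen_contaminants("never_seen", det$homology_hits)$flagged)
})

test_that("the coccolith filter applies PEP, replicate, contaminant and targeting stages", {
  cfg <- pipeline_config()
  ev <- data.frame(protein = c(rep("good_sp", 2), rep("weak", 3), rep("one_rep", 1)),
                   dataset = "coccolith", condition = "coccolith",
                   replicate = c(1, 2, 1, 2, 3, 1),
                   pep = c(0.009, 0.009, 0.02, 0.02, 0.02, 0.005))
  ev <- rbind(ev, data.frame(protein = "pad", dataset = "coccolith",
                             condition = "coccolith", replicate = 3,
                             pep = 0.5))
  ann <- data.frame(protein = c("good_sp", "weak", "one_rep", "pad"),
                    sp = c(TRUE, TRUE, TRUE, FALSE),
                    sa = FALSE, tm = FALSE)
  res <- filter_coccolith(ev, ann, character(), cfg)
  expect_equal(res$copros$members, "good_sp")       # 2/3 at PEP <= 0.01
  expect_true("weak" %in% res$excluded$protein)     # PEP 0.02 fails in all reps
  expect_true("one_rep" %in% res$excluded$protein)  # below replicate rule
  expect_equal(res$counts[["input"]],
               length(res$copros$members) + length(res$expanded_pool$members) +
                 nrow(res$excluded))
  expect_error(filter_coccolith(ev[ev$replicate == 1, ], ann),
               "3 required")
})

test_that("planted candidate classes are recovered exactly with reconciled exclusions", {
  det <- gen_detection_tables(250, paper_class_counts, seed = 41)
  screen <- screen_contaminants(unique(det$evidence$protein), det$homology_hits)
  tr <- det$truth

  lith <- filter_coccolith(det$evidence, det$annotations, screen$flagged)
  expect_setequal(lith$copros$members,
                  tr$protein[tr$class %in% c("copro_sp", "copro_sa", "copro_tm")])
  expect_setequal(lith$expanded_pool$members,
                  tr$protein[tr$class == "copro_expanded"])

  sphere <- filter_coccosphere(det$evidence, screen$flagged)
  expect_setequal(sphere$candidates$members, tr$protein[tr$class == "cs_exclusive"])
  expect_setequal(sphere$shared, tr$protein[tr$class == "cs_shared"])
  expect_length(sphere$low_only, 0)

  cv <- filter_cv(det$evidence, screen$flagged)
  expect_setequal(cv$candidates$members, tr$protein[tr$class == "cv"])

  for (res in list(lith, sphere)) {
    kept <- if (!is.null(res$copros))
      length(res$copros$members) + length(res$expanded_pool$members)
    else length(res$candidates$members)
    expect_equal(res$counts[["input"]], kept + nrow(res$excluded))
  }
})

test_that("the filters reproduce the study marginal counts from a matched fixture", {
  det <- gen_detection_tables(220, paper_class_counts, seed = 42)
  screen <- screen_contaminants(unique(det$evidence$protein), det$homology_hits)

  # coccolith arithmetic: 82 identified = 26 COPRO + 42 expanded + 14 contaminant
  lith <- filter_coccolith(det$evidence, det$annotations, screen$flagged)
  expect_equal(lith$counts[["identified"]], 82)
  expect_equal(lith$counts[["contaminant"]], 14)
  expect_equal(length(lith$copros$members), 26)
  expect_equal(length(lith$expanded_pool$members), 42)

  # coccosphere: 110 identified, 15 contaminants, 78 exclusive, 17 shared,
  # none exclusive to low-Ca
  sphere <- filter_coccosphere(det$evidence, screen$flagged)
  expect_equal(sphere$counts[["identified"]], 110)
  expect_equal(sphere$counts[["contaminant"]], 15)
  expect_equal(sphere$counts[["exclusive"]], 78)
  expect_equal(sphere$counts[["shared"]], 17)
  expect_equal(sphere$counts[["low_only"]], 0)

  # CV: 14 candidates after contaminant removal and N-cell exclusivity
  cv <- filter_cv(det$evidence, screen$flagged)
  expect_equal(length(cv$candidates$members), 14)
})

test_that("filters are monotone in the PEP ceiling and replicate minimum", {
  det <- gen_detection_tables(250, paper_class_counts, seed = 43)
  strict <- pipeline_config()
  loose_pep <- pipeline_config(pep_max = 0.05)
  loose_reps <- pipeline_config(min_reps_coccolith = 1, min_reps_coccosphere = 1)
  base <- filter_coccolith(det$evidence, det$annotations, config = strict)
  expect_true(all(base$identified %in%
    filter_coccolith(det$evidence, det$annotations, config = loose_pep)$identified))
  expect_true(all(base$identified %in%
    filter_coccolith(det$evidence, det$annotations, config = loose_reps)$identified))
  s_base <- filter_coccosphere(det$evidence, config = strict)
  s_loose <- filter_coccosphere(det$evidence, config = loose_reps)
  expect_true(all(s_base$identified %in% s_loose$identified))
})

test_that("boundary semantics: PEP at the ceiling passes, just above fails", {
  ev <- data.frame(protein = "p", dataset = "coccolith", condition = "coccolith",
                   replicate = 1:3, pep = c(0.01, 0.01, 0.01))
  ann <- data.frame(protein = "p", sp = TRUE, sa = FALSE, tm = FALSE)
  expect_equal(filter_coccolith(ev, ann)$copros$members, "p")
  ev$pep <- 0.0100001
  expect_length(filter_coccolith(ev, ann)$copros$members, 0)
})

test_that("coccosphere and CV filters demand their control conditions", {
  det <- gen_detection_tables(100, c(cs_exclusive = 5, cv = 3), seed = 44)
  ev_no_low <- det$evidence[det$evidence$condition != "low_ca", ]
  ev_no_low <- ev_no_low[ev_no_low$dataset == "coccosphere", ]
  expect_error(filter_coccosphere(ev_no_low), "low_ca")
  ev_no_n <- det$evidence[det$evidence$dataset == "cv" &
                            det$evidence$condition == "c_cells", ]
  expect_error(filter_cv(ev_no_n), "n_cells")
  # protein observed in both gradients is excluded with provenance
  both <- rbind(ev_no_n[1, ],
                transform(ev_no_n[1, ], condition = "n_cells"))
  r <- filter_cv(both)
  expect_length(r$candidates$members, 0)
  expect_equal(r$excluded$reason, "also_in_n_cells")
})

test_that("overlap analysis enumerates intersections with inclusion-exclusion", {
  ov <- overlap_analysis(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                              C = "3"))
  pw <- ov$pairwise
  expect_equal(pw$n[pw$set_a == "A" & pw$set_b == "B"], 2)
  expect_equal(pw$n[pw$set_a == "A" & pw$set_b == "C"], 1)
  expect_equal(pw$n[pw$set_a == "B" & pw$set_b == "C"], 1)
  expect_setequal(ov$multi, c("2", "3"))
  expect_equal(ov$n_multi, 2)
  expect_equal(sum(ov$patterns$n), 4)            # union size

  disj <- overlap_analysis(list(A = "1", B = "2"))
  expect_equal(disj$n_multi, 0)
  expect_true(all(disj$pairwise$n == 0))
  expect_error(overlap_analysis(list(A = "1")), "at least 2")
  expect_error(overlap_analysis(stats::setNames(list("1", "2"), c("A", "A"))),
               "unique names")
})
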