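test_that("origin assignment matches hand-checked cases", {
  tr <- read_guide_tree(text = "((A,B)AB,(C,D)CD)Root;")
  expect_equal(assign_origin("A", tr), "A")                 # species-specific
  expect_equal(assign_origin(c("A", "B", "C", "D"), tr), "Root")
  expect_equal(assign_origin(c("A", "C"), tr), "Root")
  expect_equal(assign_origin(c("A", "B"), tr), "AB")
  expect_error(assign_origin(c("A", "Z"), tr), "not in tree: Z")
  expect_error(assign_origin(character(), tr), "empty")
})

test_that("origin assignment agrees with the path-intersection oracle on random trees", {
  set.seed(42)
  for (rep in 1:60) {
    tr <- random_guide_tree(sample(5:20, 1))
    presence <- sample(tr$tip.label, sample(seq_len(ape::Ntip(tr)), 1))
    expect_equal(assign_origin(presence, tr), oracle_lca_label(tr, presence))
  }
})

test_that("adding a species never moves the origin toward the tips", {
  set.seed(7)
  tr <- random_guide_tree(15)
  depth <- function(lab) length(oracle_path_from_root(
    tr, match(lab, c(tr$tip.label, tr$node.label))))
  for (rep in 1:50) {
    presence <- sample(tr$tip.label, sample(13, 1))
    extra <- sample(setdiff(tr$tip.label, presence), 1)
    expect_lte(depth(assign_origin(c(presence, extra), tr)),
               depth(assign_origin(presence, tr)))
  }
})

test_that("stratification recovers planted origins without loss and conserves counts", {
  tr <- demo_guide_tree()
  og <- gen_orthogroups(tr, c(Root = 10, Haptophyta = 8, Gephyrocapsa = 5, Ehux = 4),
                        loss_prob = 0, focal_species = "Ehux", seed = 11)
  st <- stratify_orthogroups(og$orthogroups, tr, "Ehux")
  planted <- og$truth$origin[match(st$assignment$orthogroup, og$truth$orthogroup)]
  expect_equal(st$assignment$origin, planted)               # 100% at loss_prob 0
  expect_equal(sum(st$counts$count), nrow(st$assignment))
  # per-node counts equal planted per-node totals
  expect_equal(st$counts$count[st$counts$node == "Root"], 10L)
  expect_equal(st$counts$count[st$counts$node == "Ehux"], 4L)
})

test_that("with losses the assigned origin is descendant-or-equal of the planted origin", {
  tr <- demo_guide_tree()
  og <- gen_orthogroups(tr, c(Root = 40, Haptophyta = 40, Calcihaptophycidae = 30),
                        loss_prob = 0.3, focal_species = "Ehux", seed = 5)
  st <- stratify_orthogroups(og$orthogroups, tr, "Ehux")
  all_lab <- c(tr$tip.label, tr$node.label)
  for (i in seq_len(nrow(st$assignment))) {
    planted <- og$truth$origin[og$truth$orthogroup == st$assignment$orthogroup[i]]
    planted_idx <- match(planted, all_lab)
    assigned_idx <- match(st$assignment$origin[i], all_lab)
    expect_true(planted_idx %in% oracle_path_from_root(tr, assigned_idx))
  }
  # empty orthogroup set
  empty <- orthogroup_table(setNames(list(), character()),
                            species = tr$tip.label)
  st0 <- stratify_orthogroups(empty, tr, "Ehux")
  expect_equal(nrow(st0$assignment), 0)
  expect_equal(sum(st0$counts$count), 0L)
})

test_that("loss detection returns exactly the planted qualifying losses", {
  tr <- demo_guide_tree()
  og <- gen_orthogroups(tr, c(Root = 20, Haptophyta = 30, Calcihaptophycidae = 30,
                              Gephyrocapsa = 10, Ehux = 10),
                        loss_prob = 0.25, focal_species = "Ehux", seed = 3)
  got <- detect_losses(og$orthogroups, tr, lost_in = "Igal",
                       min_age_node = "Haptophyta", focal_species = "Ehux")
  expect_setequal(got, oracle_expected_losses(og, tr, "Igal", "Haptophyta", "Ehux"))
  # an orthogroup present in the lost lineage is never returned
  present_in_igal <- Filter(function(id)
    "Igal" %in% presence_set(og$orthogroups, id), og$orthogroups$id)
  expect_length(intersect(got, present_in_igal), 0)
  # focal-specific orthogroups are never returned
  ehux_only <- og$truth$orthogroup[og$truth$origin == "Ehux"]
  expect_length(intersect(got, ehux_only), 0)
  expect_error(detect_losses(og$orthogroups, tr, "Igal", "Gephyrocapsa", "Ehux"),
               "not ancestral")
})

test_that("hypergeometric enrichment matches hand and boundary cases", {
  # urn N=10, K=4, n=5, k=4 -> 6/252
  background <- sprintf("p%02d", 1:10)
  stratum <- background[1:5]
  dom <- data.frame(protein = c(background[1:4]), domain = "PF1",
                    ievalue = 1e-6, stringsAsFactors = FALSE)
  res <- suppressMessages(enrich_domains(stratum, background, dom))
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$k, 4L)

  # stratum == background -> p = 1; k = 0 -> p = 1
  res2 <- suppressMessages(enrich_domains(background, background, dom))
  expect_equal(res2$p, 1)
  dom0 <- data.frame(protein = background[6:9], domain = "PF2",
                     ievalue = 1e-6, stringsAsFactors = FALSE)
  res3 <- suppressMessages(enrich_domains(background[1:2], background, dom0))
  expect_equal(res3$p, 1)
  expect_equal(res3$k, 0L)

  # i-Evalue gate excludes weak hits; domains counted once per protein
  dom_dup <- data.frame(protein = c("p01", "p01", "p02"),
                        domain = c("PF3", "PF3", "PF3"),
                        ievalue = c(1e-6, 1e-6, 0.5), stringsAsFactors = FALSE)
  res4 <- suppressMessages(enrich_domains(background[1:2], background, dom_dup))
  expect_equal(res4$K, 1L)
  expect_equal(res4$k, 1L)
  expect_error(suppressMessages(enrich_domains(c("p01", "zz"), background, dom)),
               "subset")
})

test_that("enrichment p-values equal exhaustive enumeration on small urns", {
  set.seed(1)
  background <- sprintf("p%02d", 1:12)
  for (rep in 1:40) {
    N <- sample(3:12, 1)
    n <- sample(N, 1)
    K <- sample(0:N, 1)
    bg <- background[1:N]
    stratum <- sample(bg, n)
    dom <- if (K > 0)
      data.frame(protein = sample(bg, K), domain = "PF", ievalue = 1e-9)
    else data.frame(protein = character(), domain = character(),
                    ievalue = numeric())
    res <- suppressMessages(enrich_domains(stratum, bg, dom))
    if (K == 0) { expect_equal(nrow(res), 0); next }
    k <- res$k
    expect_equal(res$p, oracle_hyper_upper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("property profiles flag compositionally shifted strata", {
  tr <- read_guide_tree(text = "((A,B)AB,(C,Ehux)CE)Root;")
  set.seed(9)
  # old stratum: diverse sequences; young stratum: P/S-rich (low complexity,
  # disorder promoting)
  old_seqs <- replicate(25, random_protein(80))
  young_seqs <- replicate(25, paste(sample(c("P", "S", "P", "S", "A", "G"),
                                           80, replace = TRUE), collapse = ""))
  members <- c(
    setNames(lapply(seq_along(old_seqs), function(i)
      list(A = "x", Ehux = sprintf("old_%d", i))), sprintf("OGo%d", seq_along(old_seqs))),
    setNames(lapply(seq_along(young_seqs), function(i)
      list(Ehux = sprintf("young_%d", i))), sprintf("OGy%d", seq_along(young_seqs))))
  og <- orthogroup_table(members, species = tr$tip.label)
  st <- stratify_orthogroups(og, tr, "Ehux")
  seqs <- seq_records(c(sprintf("old_%d", seq_along(old_seqs)),
                        sprintf("young_%d", seq_along(young_seqs))),
                      c(old_seqs, young_seqs))
  prof <- stratum_property_profile(st, seqs)
  young_row <- prof$per_stratum[prof$per_stratum$stratum == "Ehux", ]
  expect_gt(young_row$ks_disorder, 0.3)
  expect_gt(mean(prof$per_protein$disorder_fraction[
    prof$per_protein$stratum == "Ehux"]),
    mean(prof$per_protein$disorder_fraction[prof$per_protein$stratum == "Root"]))
})
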