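# End-to-end orchestration: run_study() drives the stages over supplied
# inputs; run_demo() generates synthetic inputs with planted truth,
# routes them through run_study() and scores the results.

.adjusted_rand <- function(a, b) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("the adjusted Rand index requires the 'mclust' package")
  mclust::adjustedRandIndex(a, b)
}

#' Run the candidate-discovery pipeline on supplied inputs
#'
#' Orchestrates every stage for which inputs are present and skips the
#' rest with a notice. Recognized `inputs` elements:
#'
#' * `tree`, `orthogroups`, `focal_species` (+ optional `lost_in`,
#'   `min_age_node`) — phylostratigraphy and loss detection.
#' * `sequences` — per-stratum low-complexity/disorder profiles.
#' * `domain_table` — per-stratum hypergeometric domain enrichment.
#' * `spectra`, `psm` (named list of PSM tables) — de novo gating,
#'   clustering, per-database cluster identification rates.
#' * `evidence`, `annotations`, `homology_hits` — contaminant screen
#'   and the coccolith / coccosphere / CV candidate filters.
#' * `tmt` — named list of quantitative comparisons, each
#'   `list(matrix =, design =)`, run through normalization, the
#'   moderated t-test and BH counting.
#'
#' The final report cross-references candidate sets and regulated lists
#' through [overlap_analysis()] and assigns priority tiers: tier 1 =
#' membership in at least two datasets; tier 2 = single-dataset
#' membership with a stratum at or below `young_stratum`; tier 3 =
#' remainder.
#'
#' @param inputs named list as above.
#' @param config a [pipeline_config()].
#' @param young_stratum node label bounding "young" strata for tier 2
#'   (default `"Calcihaptophycidae"` when present in the tree).
#' @param output_dir optional directory; when given, stage outputs, the
#'   candidate table and a JSON run manifest are written there.
#' @return A list of class `calciproteo_run` with per-stage results,
#'   `candidate_table`, `overlap` and `manifest`.
#' @export
run_study <- function(inputs, config = pipeline_config(),
                      young_stratum = "Calcihaptophycidae",
                      output_dir = NULL) {
  res <- list(config = config)
  counts <- list()

  # --- phylostratigraphy ----------------------------------------------
  if (!is.null(inputs$tree) && !is.null(inputs$orthogroups)) {
    if (is.null(inputs$focal_species))
      stop("phylostratigraphy requires inputs$focal_species")
    res$strata <- stratify_orthogroups(inputs$orthogroups, inputs$tree,
                                       inputs$focal_species)
    counts$orthogroups_stratified <- nrow(res$strata$assignment)
    if (!is.null(inputs$lost_in)) {
      min_age <- inputs$min_age_node
      if (is.null(min_age)) min_age <- res$strata$counts$node[[1L]]
      res$losses <- detect_losses(inputs$orthogroups, inputs$tree,
                                  inputs$lost_in, min_age,
                                  inputs$focal_species)
      counts$losses <- length(res$losses)
    }
    if (!is.null(inputs$sequences))
      res$property_profile <- stratum_property_profile(res$strata,
                                                       inputs$sequences)
    if (!is.null(inputs$domain_table)) {
      background <- res$strata$protein_strata$protein
      strata <- unique(res$strata$protein_strata$stratum)
      res$enrichment <- lapply(stats::setNames(strata, strata), function(st) {
        sp <- res$strata$protein_strata$protein[
          res$strata$protein_strata$stratum == st]
        suppressMessages(enrich_domains(sp, background, inputs$domain_table,
                                        config))
      })
    }
  } else message("phylostratigraphy skipped: tree/orthogroups not supplied")

  # --- spectral QC -----------------------------------------------------
  if (!is.null(inputs$spectra) && !is.null(inputs$psm)) {
    gated <- gate_by_denovo(inputs$spectra, config$denovo_score_cutoff)
    clusters <- cluster_spectra(gated, config$cluster_similarity_threshold)
    rates <- do.call(rbind, lapply(names(inputs$psm), function(db)
      cluster_id_rate(clusters, inputs$psm[[db]],
                      config$peptide_prob_cutoff, database_id = db)))
    res$spectral_qc <- list(n_gated = length(gated), clusters = clusters,
                            id_rates = rates)
    counts$spectra_gated <- length(gated)
    counts$clusters <- length(clusters)
  } else message("spectral QC skipped: spectra/PSM tables not supplied")

  # --- candidate filters ----------------------------------------------
  sets <- list()
  if (!is.null(inputs$evidence)) {
    screen <- if (is.null(inputs$homology_hits)) {
      warning("no homology hits supplied: contaminant screening disabled")
      list(flagged = character(), justification = data.frame())
    } else screen_contaminants(unique(inputs$evidence$protein),
                               inputs$homology_hits)
    res$contaminants <- screen
    ann <- inputs$annotations
    if (is.null(ann)) ann <- data.frame(protein = character(), sp = logical(),
                                        sa = logical(), tm = logical())
    if ("coccolith" %in% inputs$evidence$dataset) {
      res$coccolith <- filter_coccolith(inputs$evidence, ann,
                                        screen$flagged, config)
      sets$COPRO <- res$coccolith$copros$members
      counts$copros <- length(sets$COPRO)
    }
    if ("coccosphere" %in% inputs$evidence$dataset) {
      res$coccosphere <- filter_coccosphere(inputs$evidence,
                                            screen$flagged, config)
      sets$coccosphere <- res$coccosphere$candidates$members
      counts$coccosphere <- length(sets$coccosphere)
    }
    if ("cv" %in% inputs$evidence$dataset) {
      res$cv <- filter_cv(inputs$evidence, screen$flagged, config)
      sets$CV <- res$cv$candidates$members
      counts$cv <- length(sets$CV)
    }
  } else message("candidate filters skipped: evidence not supplied")

  # --- quantitative comparisons ---------------------------------------
  if (!is.null(inputs$tmt)) {
    res$diffabund <- lapply(stats::setNames(names(inputs$tmt), names(inputs$tmt)),
                            function(nm) {
      x <- inputs$tmt[[nm]]
      norm <- normalize_md(x$matrix)
      fit <- moderated_t(norm, x$design)
      reg <- count_regulated(fit, config$adj_p_cutoff)
      list(fit = fit, regulated = reg)
    })
    for (nm in names(res$diffabund)) {
      sets[[nm]] <- res$diffabund[[nm]]$regulated$proteins$protein
      counts[[paste0("regulated_", nm)]] <- res$diffabund[[nm]]$regulated$n
    }
  } else message("quantitative comparisons skipped: tmt not supplied")

  # --- overlap and priority tiers -------------------------------------
  if (length(sets) >= 2L) {
    res$overlap <- overlap_analysis(sets)
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
    memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L)
      memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, names(sets)))
    tab <- data.frame(protein = universe, memb, check.names = FALSE,
                      stringsAsFactors = FALSE)
    tab$n_datasets <- rowSums(memb)
    if (!is.null(res$strata)) {
      ps <- res$strata$protein_strata
      tab$stratum <- ps$stratum[match(tab$protein, ps$protein)]
    } else tab$stratum <- NA_character_
    young <- character()
    if (!is.null(inputs$tree) && !is.null(young_stratum) &&
        young_stratum %in% c(inputs$tree$tip.label, inputs$tree$node.label)) {
      yi <- .label_index(inputs$tree, young_stratum)
      below <- c(yi, which(vapply(
        seq_len(ape::Ntip(inputs$tree) + inputs$tree$Nnode),
        function(n) .is_ancestor(inputs$tree, yi, n), TRUE)))
      young <- unique(.node_label(inputs$tree, below))
    }
    tab$tier <- ifelse(tab$n_datasets >= 2L, 1L,
                       ifelse(!is.na(tab$stratum) & tab$stratum %in% young, 2L, 3L))
    tab <- tab[order(tab$tier, -tab$n_datasets, tab$protein), , drop = FALSE]
    rownames(tab) <- NULL
    res$candidate_table <- tab
    counts$candidates_tier1 <- sum(tab$tier == 1L)
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("calciproteo")),
    config = unclass(config), seed = config$rng_seed,
    stages_run = setdiff(names(res), c("config", "manifest")),
    row_counts = counts, timestamp = format(Sys.time(), tz = "UTC"))
  class(res) <- "calciproteo_run"
  if (!is.null(output_dir)) .write_run(res, output_dir, config)
  res
}

.write_run <- function(res, output_dir, config) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv(df, file.path(output_dir, name),
                                    config = config)
  if (!is.null(res$strata)) {
    w(res$strata$assignment, "orthogroup_origins.tsv")
    w(res$strata$counts, "stratum_counts.tsv")
  }
  if (!is.null(res$spectral_qc)) w(res$spectral_qc$id_rates, "id_rates.tsv")
  if (!is.null(res$coccolith))
    w(data.frame(protein = res$coccolith$copros$members), "copros.tsv")
  if (!is.null(res$coccosphere))
    w(data.frame(protein = res$coccosphere$candidates$members),
      "coccosphere_candidates.tsv")
  if (!is.null(res$cv))
    w(data.frame(protein = res$cv$candidates$members), "cv_candidates.tsv")
  for (nm in names(res$diffabund))
    w(res$diffabund[[nm]]$fit$table, sprintf("diffabund_%s.tsv", nm))
  if (!is.null(res$candidate_table)) w(res$candidate_table, "candidate_table.tsv")
  if (!is.null(res$overlap)) w(res$overlap$pairwise, "overlap_pairwise.tsv")
  jsonlite::write_json(res$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' Demo guide tree used by the synthetic pipeline run
#'
#' A small rooted species tree mirroring the clade structure relevant
#' to coccolithophore phylostratigraphy: the focal calcifier inside the
#' Gephyrocapsa clade, a non-calcifying Isochrysidales sister, further
#' calcifying haptophytes, non-calcifying haptophytes, and outgroups.
#'
#' @return An `ape::phylo` guide tree.
#' @export
demo_guide_tree <- function() {
  read_guide_tree(text = paste0(
    "(((((Ehux,Goce)Gephyrocapsa,Igal)Isochrysidales,",
    "(Cbra,Saps)Coccolithales)Calcihaptophycidae,",
    "(Chry,Pavl)OtherHaptophytes)Haptophyta,",
    "(Tpse,Ptri)Outgroup)Root;"))
}

#' Run the full pipeline end-to-end on synthetic data
#'
#' Generates seeded synthetic inputs with planted truth for every
#' stage, routes them through [run_study()], and scores each stage
#' against its planted truth: origin assignments must be
#' descendant-or-equal of the planted origins, detected losses must
#' match the planted qualifying set, spectral clustering must reach an
#' adjusted Rand index of at least 0.95 against the planted partition
#' with the higher-coverage database scoring the higher identification
#' rate, the candidate filters must recover the planted classes
#' exactly, and the moderated t stage must recover the planted
#' differential proteins with high recall and controlled false
#' discovery.
#'
#' @param seed integer root seed.
#' @param output_dir optional output directory (passed to [run_study()]).
#' @return A `calciproteo_run` with an additional `scorecard` data
#'   frame (`check`, `pass`) and `truth` list.
#' @export
run_demo <- function(seed = 1L, output_dir = NULL) {
  config <- pipeline_config(rng_seed = seed)
  tree <- demo_guide_tree()
  focal <- "Ehux"

  og <- gen_orthogroups(
    tree,
    n_per_node = c(Root = 30, Haptophyta = 40, Calcihaptophycidae = 35,
                   Isochrysidales = 25, Gephyrocapsa = 20, Ehux = 30),
    loss_prob = 0.15, focal_species = focal, seed = seed)
  focal_proteins <- unlist(lapply(og$orthogroups$members,
                                  function(m) m[[focal]]), use.names = FALSE)
  sp <- gen_spectra(n_peptides = 150, clones_per_peptide = 3,
                    db_coverage = c(dbA = 0.8, dbB = 0.5),
                    noise = 0.1, seed = seed + 1L)
  class_counts <- c(copro_sp = 21, copro_sa = 2, copro_tm = 3,
                    copro_expanded = 42, coccolith_contaminant = 14,
                    cs_exclusive = 30, cs_shared = 8, cs_contaminant = 6,
                    cv = 10, cv_contaminant = 3)
  n_prot <- length(focal_proteins)
  stopifnot(n_prot >= sum(class_counts))
  det <- gen_detection_tables(n_prot, class_counts, config, seed = seed + 2L,
                              protein_ids = focal_proteins)
  # planted differential proteins drawn from the same protein universe,
  # overlapping the planted candidate classes so tier-1 candidates exist
  tmt1 <- gen_tmt(min(400L, n_prot), n_de = 30, lfc = 3, sigma = 0.3,
                  seed = seed + 3L,
                  protein_ids = focal_proteins[seq_len(min(400L, n_prot))])
  tmt2 <- gen_tmt(min(400L, n_prot), n_de = 20, lfc = 3, sigma = 0.3,
                  seed = seed + 4L,
                  protein_ids = focal_proteins[seq_len(min(400L, n_prot))])

  inputs <- list(tree = tree, orthogroups = og$orthogroups,
                 focal_species = focal, lost_in = "Igal",
                 min_age_node = "Haptophyta",
                 spectra = sp$spectra, psm = sp$psm,
                 evidence = det$evidence, annotations = det$annotations,
                 homology_hits = det$homology_hits,
                 tmt = list(CvsN = list(matrix = tmt1$matrix, design = tmt1$design),
                            LvsD = list(matrix = tmt2$matrix, design = tmt2$design)))
  res <- suppressMessages(run_study(inputs, config, output_dir = output_dir))

  # ---- scorecard against planted truth -------------------------------
  checks <- list()
  add_check <- function(name, pass)
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass)

  planted <- og$truth$origin[match(res$strata$assignment$orthogroup,
                                   og$truth$orthogroup)]
  ok_origin <- vapply(seq_len(nrow(res$strata$assignment)), function(i) {
    po <- .label_index(tree, planted[i])
    ao <- .label_index(tree, res$strata$assignment$origin[i])
    .is_ancestor(tree, po, ao)
  }, TRUE)
  add_check("origins_descend_from_planted", all(ok_origin))
  add_check("origin_counts_conserved",
            sum(res$strata$counts$count) == nrow(res$strata$assignment))

  expected_losses <- .expected_losses(og, tree, "Igal", "Haptophyta", focal)
  add_check("losses_match_planted", setequal(res$losses, expected_losses))

  gated_ids <- vapply(gate_by_denovo(sp$spectra, config$denovo_score_cutoff),
                      `[[`, "", "id")
  truth_part <- sp$truth$cluster[match(gated_ids, sp$truth$spectrum_id)]
  assigned <- rep(NA_character_, length(gated_ids))
  for (cl in res$spectral_qc$clusters)
    assigned[match(cl$members, gated_ids)] <- cl$id
  add_check("clustering_ari_ge_0.95",
            .adjusted_rand(truth_part, assigned) >= 0.95)
  rates <- res$spectral_qc$id_rates
  add_check("higher_coverage_higher_id_rate",
            rates$rate[rates$database_id == "dbA"] >
              rates$rate[rates$database_id == "dbB"])

  tr <- det$truth
  add_check("copros_match_planted",
            setequal(res$coccolith$copros$members,
                     tr$protein[tr$class %in% c("copro_sp", "copro_sa", "copro_tm")]))
  add_check("expanded_pool_matches_planted",
            setequal(res$coccolith$expanded_pool$members,
                     tr$protein[tr$class == "copro_expanded"]))
  add_check("coccosphere_matches_planted",
            setequal(res$coccosphere$candidates$members,
                     tr$protein[tr$class == "cs_exclusive"]))
  add_check("cv_matches_planted",
            setequal(res$cv$candidates$members, tr$protein[tr$class == "cv"]))

  for (nm in c("CvsN", "LvsD")) {
    tt <- if (nm == "CvsN") tmt1$truth else tmt2$truth
    hits <- res$diffabund[[nm]]$regulated$proteins$protein
    recall <- mean(tt$protein[tt$is_de] %in% hits)
    fdr <- if (length(hits)) mean(!hits %in% tt$protein[tt$is_de]) else 0
    add_check(paste0("tmt_", nm, "_recall_ge_0.9"), recall >= 0.9)
    add_check(paste0("tmt_", nm, "_fdr_le_0.2"), fdr <= 0.2)
  }
  if (!is.null(res$candidate_table)) {
    multi <- res$candidate_table$protein[res$candidate_table$n_datasets >= 2L]
    add_check("tier1_equals_multi_dataset",
              setequal(multi, res$candidate_table$protein[
                res$candidate_table$tier == 1L]))
  }

  res$scorecard <- do.call(rbind, checks)
  res$truth <- list(orthogroups = og$truth, spectra = sp$truth,
                    detection = det$truth, tmt = list(CvsN = tmt1$truth,
                                                      LvsD = tmt2$truth))
  if (!is.null(output_dir))
    write_tsv(res$scorecard, file.path(output_dir, "scorecard.tsv"),
              config = config)
  res
}

# enumerate, from planted truth, the orthogroups whose absence in
# `lost_in` qualifies as a loss (origin on the qualifying path, focal
# present, lost_in absent)
.expected_losses <- function(og, tree, lost_in, min_age_node, focal) {
  pv <- .parent_vec(tree)
  lca <- assign_origin(c(lost_in, focal), tree)
  path <- .path_to_root(tree, .label_index(tree, lca), pv)
  stop_at <- match(.label_index(tree, min_age_node), path)
  qualifying <- .node_label(tree, path[seq_len(stop_at)])
  keep <- vapply(og$orthogroups$id, function(id) {
    pres <- presence_set(og$orthogroups, id)
    origin <- og$truth$origin[og$truth$orthogroup == id]
    focal %in% pres && !lost_in %in% pres &&
      assign_origin(pres, tree) %in% qualifying
  }, TRUE)
  og$orthogroups$id[keep]
}
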