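# Seeded generators with planted ground truth for every pipeline stage.
# All randomness is local: the caller's RNG state is saved and restored,
# so the same seed always yields bit-identical output.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate orthogroups by single-gain / multiple-loss evolution on a tree
#'
#' Each orthogroup gains once at its assigned origin node and is then
#' lost independently on each descendant branch with probability
#' `loss_prob` (a loss prunes the whole subtree below that branch). The
#' focal species is never lost, matching the analysis's conditioning on
#' focal-containing orthogroups. The planted truth records every origin
#' and the pruned branches.
#'
#' @param tree guide tree from [read_guide_tree()].
#' @param n_per_node named integer vector: origin node label -> number
#'   of orthogroups gained there.
#' @param loss_prob per-branch loss probability in `[0,1)` for clades
#'   containing the focal species.
#' @param focal_species focal leaf label (never lost).
#' @param seed integer seed.
#' @return List: `orthogroups` (an [orthogroup_table]), `truth` (data
#'   frame `orthogroup`, `origin`, `lost_branches`).
#' @export
gen_orthogroups <- function(tree, n_per_node, loss_prob, focal_species, seed) {
  stopifnot(loss_prob >= 0, loss_prob <= 1, all(n_per_node >= 0))
  if (!focal_species %in% tree$tip.label)
    stop("focal species not a leaf: ", focal_species)
  origin_idx <- .label_index(tree, names(n_per_node))
  pv <- .parent_vec(tree)
  focal_idx <- match(focal_species, tree$tip.label)
  focal_path <- .path_to_root(tree, focal_idx, pv)
  ntip <- ape::Ntip(tree)
  .with_seed(seed, {
    members <- list(); truth <- list()
    og_i <- 0L
    for (oi in seq_along(n_per_node)) {
      o <- origin_idx[[oi]]
      focal_under <- focal_idx %in% .clade_tips(tree, o)
      if (loss_prob == 1 && focal_under)
        stop("loss_prob = 1 with the focal species inside the origin clade is inconsistent")
      for (rep_i in seq_len(n_per_node[[oi]])) {
        og_i <- og_i + 1L
        og_id <- sprintf("OG%04d", og_i)
        lost <- character()
        retained_tips <- integer()
        # depth-first descent from the origin; a loss prunes the subtree,
        # except on the path protecting the focal species
        walk <- function(node) {
          if (node <= ntip) { retained_tips <<- c(retained_tips, node); return(invisible()) }
          for (child in tree$edge[tree$edge[, 1L] == node, 2L]) {
            protected <- focal_under && child %in% focal_path
            if (!protected && stats::runif(1) < loss_prob) {
              lost <<- c(lost, .node_label(tree, child))
            } else walk(child)
          }
        }
        walk(o)
        species <- tree$tip.label[sort(retained_tips)]
        m <- lapply(species, function(s) sprintf("%s_%s_p1", s, og_id))
        names(m) <- species
        members[[og_id]] <- m
        truth[[og_id]] <- data.frame(
          orthogroup = og_id, origin = .node_label(tree, o),
          lost_branches = paste(lost, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    list(orthogroups = orthogroup_table(members, species = sort(tree$tip.label)),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Generate spectra with planted cluster structure and database coverage
#'
#' Creates `n_peptides` template spectra (20-60 peaks on a 0.05 m/z
#' grid) and `clones_per_peptide` noisy copies of each (m/z jitter
#' uniform within `noise` times half a grid bin; multiplicative
#' intensity noise), plus a fraction of unclustered junk spectra. De
#' novo scores are drawn from a two-component mixture — Normal(75, 8)
#' for peptide-derived spectra and Normal(40, 10) for junk, truncated at
#' 0 — straddling the quality gate at 60. Each database covers a random
#' peptide subset of the requested fraction; its PSM table assigns
#' probability >= 0.95 exactly to spectra of covered peptides.
#'
#' @param n_peptides number of distinct peptides.
#' @param clones_per_peptide replicate spectra per peptide.
#' @param db_coverage named numeric vector: database id -> covered
#'   fraction in `[0,1]`.
#' @param noise noise amplitude in `[0,1]` (0 = identical clones).
#' @param seed integer seed.
#' @param junk_frac junk spectra as a fraction of peptide spectra
#'   (default 0.2).
#' @return List: `spectra` (list of [peaklist]), `psm` (named list of
#'   per-database PSM data frames), `truth` (per-spectrum data frame
#'   with peptide, cluster and per-database coverage flags),
#'   `covered_peptides` (named list).
#' @export
gen_spectra <- function(n_peptides, clones_per_peptide, db_coverage, noise,
                        seed, junk_frac = 0.2) {
  stopifnot(all(db_coverage >= 0), all(db_coverage <= 1),
            noise >= 0, noise <= 1, n_peptides >= 1, clones_per_peptide >= 1)
  if (is.null(names(db_coverage))) stop("db_coverage must be named by database id")
  grid <- 0.05
  .with_seed(seed, {
    peptide_ids <- sprintf("pep%04d", seq_len(n_peptides))
    templates <- lapply(peptide_ids, function(p) {
      n_peaks <- sample(20:60, 1L)
      mz <- sort(sample(seq(100, 1500, by = grid), n_peaks))
      list(mz = mz, intensity = stats::runif(n_peaks, 10, 100),
           precursor = stats::runif(1, 300, 1600))
    })
    names(templates) <- peptide_ids
    spectra <- list(); truth <- list()
    rtnorm <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)
    for (p in peptide_ids) {
      tm <- templates[[p]]
      for (k in seq_len(clones_per_peptide)) {
        id <- sprintf("%s_c%02d", p, k)
        mz <- tm$mz + stats::runif(length(tm$mz), -1, 1) * noise * grid / 2
        int <- tm$intensity * exp(stats::rnorm(length(tm$mz), 0, noise * 0.2))
        spectra[[id]] <- peaklist(id, tm$precursor, mz, int,
                                  charge = 2L, denovo_score = rtnorm(1, 75, 8))
        truth[[id]] <- data.frame(spectrum_id = id, peptide = p, cluster = p,
                                  real = TRUE, stringsAsFactors = FALSE)
      }
    }
    n_junk <- round(junk_frac * n_peptides * clones_per_peptide)
    for (j in seq_len(n_junk)) {
      id <- sprintf("junk%04d", j)
      n_peaks <- sample(20:60, 1L)
      spectra[[id]] <- peaklist(id, stats::runif(1, 300, 1600),
                                sort(sample(seq(100, 1500, by = grid), n_peaks)),
                                stats::runif(n_peaks, 10, 100),
                                charge = 2L, denovo_score = rtnorm(1, 40, 10))
      truth[[id]] <- data.frame(spectrum_id = id, peptide = NA_character_,
                                cluster = paste0("junk_", j), real = FALSE,
                                stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    covered <- lapply(db_coverage, function(frac)
      sort(sample(peptide_ids, round(frac * n_peptides))))
    psm <- lapply(names(db_coverage), function(db) {
      prob <- ifelse(truth$real & truth$peptide %in% covered[[db]],
                     stats::runif(nrow(truth), 0.95, 1),
                     ifelse(truth$real, stats::runif(nrow(truth), 0, 0.9),
                            stats::runif(nrow(truth), 0, 0.5)))
      data.frame(spectrum_id = truth$spectrum_id,
                 peptide = ifelse(is.na(truth$peptide), "decoy", truth$peptide),
                 probability = prob,
                 protein_group = ifelse(is.na(truth$peptide), NA_character_,
                                        paste0("prot_", truth$peptide)),
                 database_id = db, stringsAsFactors = FALSE)
    })
    names(psm) <- names(db_coverage)
    for (db in names(db_coverage))
      truth[[paste0("covered_", db)]] <- !is.na(truth$peptide) &
        truth$peptide %in% covered[[db]]
    list(spectra = spectra, psm = psm, truth = truth, covered_peptides = covered)
  })
}

#' Generate detection-evidence tables with planted candidate classes
#'
#' Builds protein-level detection tables for the three presence/absence
#' experiments — coccolith (one condition, 3 replicates), coccosphere
#' (std-Ca vs low-Ca, 4 replicates each) and coccolith-vesicle gradient
#' (C-cells vs N-cells) — with planted candidate classes that respect
#' each filter's rule margins, planted contaminants carrying homology
#' flags, and sporadic sub-threshold background detections.
#'
#' Planted classes (named counts in `class_counts`): `copro_sp`,
#' `copro_sa`, `copro_tm` (coccolith candidates by targeting signal),
#' `copro_expanded` (coccolith-identified, no targeting signal),
#' `coccolith_contaminant`, `cs_exclusive`, `cs_shared`,
#' `cs_contaminant` (coccosphere classes), `cv`, `cv_contaminant`, and
#' `background` for the remainder up to `n_proteins`.
#'
#' @param n_proteins total proteins (>= sum of class counts).
#' @param class_counts named integer vector of planted class sizes;
#'   missing classes default to 0.
#' @param config a [pipeline_config()] whose thresholds set the rule
#'   margins.
#' @param seed integer seed.
#' @param protein_ids optional character vector of protein ids (length
#'   `n_proteins`); defaults to synthetic gene-model style ids.
#' @return List: `evidence` (data frame `protein`, `dataset`,
#'   `condition`, `replicate`, `pep`, `spectral_count`), `annotations`
#'   (data frame `protein`, `sp`, `sa`, `tm`), `homology_hits` (data
#'   frame for [screen_contaminants()]), `truth` (`protein`, `class`).
#' @export
gen_detection_tables <- function(n_proteins, class_counts,
                                 config = pipeline_config(), seed = 1L,
                                 protein_ids = NULL) {
  all_classes <- c("copro_sp", "copro_sa", "copro_tm", "copro_expanded",
                   "coccolith_contaminant", "cs_exclusive", "cs_shared",
                   "cs_contaminant", "cv", "cv_contaminant")
  counts <- stats::setNames(integer(length(all_classes)), all_classes)
  counts[names(class_counts)] <- as.integer(class_counts)
  if (length(setdiff(names(class_counts), all_classes)))
    stop("unknown class: ",
         paste(setdiff(names(class_counts), all_classes), collapse = ", "))
  if (sum(counts) > n_proteins)
    stop("class counts exceed n_proteins")
  .with_seed(seed, {
    cls <- c(rep(names(counts), counts),
             rep("background", n_proteins - sum(counts)))
    protein <- if (is.null(protein_ids)) sprintf("EhG%05d.1", seq_len(n_proteins))
               else as.character(protein_ids)
    if (length(protein) != n_proteins || anyDuplicated(protein))
      stop("protein_ids must be ", n_proteins, " unique ids")
    truth <- data.frame(protein = protein, class = cls, stringsAsFactors = FALSE)
    good_pep <- function(n) stats::runif(n, 1e-4, config$pep_max * 0.9)
    bad_pep <- function(n) stats::runif(n, config$pep_max * 2, 0.3)
    ev <- list()
    add <- function(protein, dataset, condition, reps, pep) {
      for (r in reps)
        ev[[length(ev) + 1L]] <<- data.frame(
          protein = protein, dataset = dataset, condition = condition,
          replicate = r, pep = pep, spectral_count = sample(1:50, 1L),
          stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_proteins)) {
      p <- protein[i]
      switch(cls[i],
        copro_sp = , copro_sa = , copro_tm = , copro_expanded = ,
        coccolith_contaminant = {
          k <- sample(config$min_reps_coccolith:3, 1L)
          add(p, "coccolith", "coccolith", sample(1:3, k), good_pep(1))
        },
        cs_exclusive = , cs_shared = , cs_contaminant = {
          k <- sample(config$min_reps_coccosphere:4, 1L)
          add(p, "coccosphere", "std_ca", sample(1:4, k), good_pep(1))
          if (cls[i] == "cs_shared")
            add(p, "coccosphere", "low_ca", sample(1:4, sample(1:4, 1L)), good_pep(1))
        },
        cv = , cv_contaminant = {
          add(p, "cv", "c_cells", sample(1:3, sample(1:3, 1L)), good_pep(1))
          if (cls[i] == "cv_contaminant")
            add(p, "cv", "n_cells", sample(1:3, 1L), good_pep(1))
        },
        background = {
          # sporadic detections that never satisfy a filter rule:
          # single-replicate or high-PEP hits; CV hits always in both gradients
          if (stats::runif(1) < 0.5)
            add(p, "coccolith", "coccolith", sample(1:3, 1L), bad_pep(1))
          if (stats::runif(1) < 0.5)
            add(p, "coccosphere", "std_ca", sample(1:4, 1L), bad_pep(1))
          if (stats::runif(1) < 0.3)
            add(p, "coccosphere", "low_ca", sample(1:4, 1L), bad_pep(1))
          if (stats::runif(1) < 0.3) {
            add(p, "cv", "c_cells", sample(1:3, 1L), good_pep(1))
            add(p, "cv", "n_cells", sample(1:3, 1L), good_pep(1))
          }
        })
    }
    evidence <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
    annotations <- data.frame(
      protein = protein,
      sp = cls == "copro_sp",
      sa = cls == "copro_sa",
      tm = cls == "copro_tm",
      stringsAsFactors = FALSE)
    contam <- cls %in% c("coccolith_contaminant", "cs_contaminant", "cv_contaminant")
    homology_hits <- data.frame(
      protein = protein[contam],
      hit = sprintf("UniProt_%04d", seq_len(sum(contam))),
      evalue = stats::runif(sum(contam), 1e-80, 1e-20),
      category = sample(c("conserved_process", "common_lab_contaminant"),
                        sum(contam), replace = TRUE),
      stringsAsFactors = FALSE)
    list(evidence = evidence, annotations = annotations,
         homology_hits = homology_hits, truth = truth)
  })
}

#' Generate a TMT-style log2 abundance matrix with planted differences
#'
#' Log2 intensities are protein baseline + condition effect + Gaussian
#' noise; the first `n_de` proteins receive a condition effect of
#' `+/- lfc` (alternating sign). Per-protein noise standard deviations
#' are drawn from a scaled inverse-chi-square prior
#' (`sigma^2 * d0 / chisq(d0)`), so empirical-Bayes variance shrinkage
#' is exercised and the prior parameters are recoverable.
#'
#' @param n_proteins number of proteins.
#' @param n_de number of differential proteins (<= `n_proteins`).
#' @param lfc absolute log2 effect size.
#' @param sigma prior noise standard deviation (> 0).
#' @param design integer vector of length 2: replicates per condition
#'   (default `c(4, 4)`).
#' @param seed integer seed.
#' @param d0 prior degrees of freedom of the variance distribution
#'   (default 4).
#' @param protein_ids optional character vector of protein ids (length
#'   `n_proteins`); the first `n_de` of these are the planted
#'   differential proteins.
#' @return List: `matrix` (proteins x samples, dimnames set), `design`
#'   (factor of conditions), `truth` (`protein`, `is_de`, `effect`),
#'   `d0`, `s0_2`.
#' @export
gen_tmt <- function(n_proteins, n_de, lfc, sigma, design = c(4L, 4L),
                    seed = 1L, d0 = 4, protein_ids = NULL) {
  stopifnot(n_de <= n_proteins, sigma > 0, length(design) == 2L)
  .with_seed(seed, {
    cond <- factor(rep(c("A", "B"), design), levels = c("A", "B"))
    protein <- if (is.null(protein_ids)) sprintf("protein_%04d", seq_len(n_proteins))
               else as.character(protein_ids)
    stopifnot(length(protein) == n_proteins)
    effect <- numeric(n_proteins)
    if (n_de > 0) effect[seq_len(n_de)] <- lfc * rep_len(c(1, -1), n_de)
    s2 <- sigma^2 * d0 / stats::rchisq(n_proteins, d0)
    baseline <- stats::rnorm(n_proteins, 20, 2)
    mat <- matrix(NA_real_, n_proteins, length(cond),
                  dimnames = list(protein,
                                  paste0(rep(c("A", "B"), design), "_rep",
                                         c(seq_len(design[1L]), seq_len(design[2L])))))
    for (i in seq_len(n_proteins)) {
      mu <- baseline[i] + ifelse(cond == "B", effect[i], 0)
      mat[i, ] <- stats::rnorm(length(cond), mu, sqrt(s2[i]))
    }
    list(matrix = mat, design = cond,
         truth = data.frame(protein = protein, is_de = effect != 0,
                            effect = effect, stringsAsFactors = FALSE),
         d0 = d0, s0_2 = sigma^2)
  })
}
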