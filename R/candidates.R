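# Rule-based candidate definitions: coccolith (COPRO), coccosphere and
# coccolith-vesicle filters with contaminant screening, plus the
# cross-dataset overlap analysis.

.reason_df <- function(proteins, reason) {
  data.frame(protein = as.character(proteins),
             reason = rep_len(reason, length(proteins)),
             stringsAsFactors = FALSE)
}

.check_evidence <- function(evidence) {
  req <- c("protein", "dataset", "condition", "replicate", "pep")
  missing <- setdiff(req, names(evidence))
  if (length(missing))
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(evidence$pep < 0 | evidence$pep > 1, na.rm = TRUE))
    stop("PEP values must lie in [0,1]")
  invisible(evidence)
}

# replicates in which a protein is identified at pep <= pep_max,
# per (protein) within one dataset/condition slice
.reps_passing <- function(evidence, dataset, condition, pep_max) {
  sel <- evidence$dataset == dataset & evidence$condition == condition &
    evidence$pep <= pep_max
  sub <- evidence[sel, c("protein", "replicate")]
  sub <- unique(sub)
  tab <- table(sub$protein)
  stats::setNames(as.integer(tab), names(tab))
}

#' Flag likely contaminants by homology
#'
#' Mechanizes the contaminant judgment as a rule: a protein is flagged
#' when it has a homology hit in one of the configured categories
#' (common laboratory contaminants or evolutionarily conserved
#' processes) below the e-value ceiling. Every flag carries its
#' justification row. A missing hits table yields no flags with a loud
#' warning.
#'
#' @param proteins character vector of protein ids to screen.
#' @param homology_hits data frame `protein`, `hit`, `evalue`,
#'   `category`, or `NULL`.
#' @param categories flagging categories (default the two above).
#' @param evalue_max e-value ceiling (default 1e-10).
#' @return List: `flagged` (character vector), `justification` (data
#'   frame of the supporting hit rows).
#' @export
screen_contaminants <- function(proteins, homology_hits,
                                categories = c("common_lab_contaminant",
                                               "conserved_process"),
                                evalue_max = 1e-10) {
  if (is.null(homology_hits)) {
    warning("no homology hits table supplied: contaminant screening disabled")
    homology_hits <- data.frame(protein = character(), hit = character(),
                                evalue = numeric(), category = character())
  }
  if (!nrow(homology_hits)) {
    return(list(flagged = character(),
                justification = data.frame(protein = character(),
                                           hit = character(), evalue = numeric(),
                                           category = character())))
  }
  stopifnot(all(c("protein", "hit", "evalue", "category") %in% names(homology_hits)))
  sel <- homology_hits$protein %in% proteins &
    homology_hits$category %in% categories &
    homology_hits$evalue < evalue_max
  just <- homology_hits[sel, , drop = FALSE]
  rownames(just) <- NULL
  list(flagged = unique(just$protein), justification = just)
}

.candidate_set <- function(name, members, provenance) {
  structure(list(name = name, members = members, provenance = provenance),
            class = "candidate_set")
}

#' Coccolith (COPRO) candidate filter
#'
#' Three stages over the coccolith dataset (3 biological replicates):
#' (1) identification at PEP <= `pep_max` in at least
#' `min_reps_coccolith` replicates; (2) removal of contaminant-flagged
#' proteins; (3) split by the targeting gate into COPROs (signal
#' peptide, signal anchor, or transmembrane domain) and the expanded
#' pool (no targeting signal). Every excluded protein carries a
#' machine-readable reason, and input = kept + excluded reconciles
#' exactly.
#'
#' @param evidence detection-evidence data frame (see
#'   [gen_detection_tables()] for the layout); must contain a
#'   `"coccolith"` dataset with 3 replicates.
#' @param annotations data frame `protein`, `sp`, `sa`, `tm`.
#' @param contaminants character vector of contaminant-flagged proteins
#'   (from [screen_contaminants()]).
#' @param config a [pipeline_config()].
#' @return List: `copros` (candidate_set), `expanded_pool`
#'   (candidate_set), `identified` (stage-1 survivors), `excluded`
#'   (data frame `protein`, `reason`), `counts` (named vector).
#' @export
filter_coccolith <- function(evidence, annotations, contaminants = character(),
                             config = pipeline_config()) {
  .check_evidence(evidence)
  sub <- evidence[evidence$dataset == "coccolith", , drop = FALSE]
  if (!nrow(sub)) stop("no evidence rows for dataset 'coccolith'")
  n_reps <- length(unique(sub$replicate))
  if (n_reps < 3L)
    stop("dataset 'coccolith' has ", n_reps, " replicates; 3 required")
  reps <- .reps_passing(evidence, "coccolith", "coccolith", config$pep_max)
  all_prot <- sort(unique(sub$protein))
  identified <- sort(names(reps)[reps >= config$min_reps_coccolith])
  excluded <- .reason_df(setdiff(all_prot, identified),
                         "below_replicate_or_pep_rule")
  contam <- intersect(identified, contaminants)
  if (length(contam))
    excluded <- rbind(excluded, .reason_df(contam, "contaminant"))
  survivors <- setdiff(identified, contam)
  gate <- vapply(survivors, function(p) {
    row <- annotations[annotations$protein == p, , drop = FALSE]
    if (!nrow(row)) targeting_gate(NULL) else targeting_gate(row[1L, ])
  }, "")
  copros <- survivors[gate != "NONE"]
  expanded <- survivors[gate == "NONE"]
  prov <- data.frame(protein = survivors, gate = unname(gate),
                     reps_passing = unname(reps[survivors]),
                     stringsAsFactors = FALSE)
  counts <- c(input = length(all_prot), identified = length(identified),
              contaminant = length(contam), copro = length(copros),
              expanded_pool = length(expanded))
  stopifnot(counts[["input"]] ==
              length(copros) + length(expanded) + nrow(excluded))
  list(copros = .candidate_set("COPRO", copros, prov[prov$gate != "NONE", ]),
       expanded_pool = .candidate_set("COPRO_expanded", expanded,
                                      prov[prov$gate == "NONE", ]),
       identified = identified, excluded = excluded, counts = counts)
}

#' Coccosphere candidate filter
#'
#' Proteins must be identified in at least `min_reps_coccosphere` of the
#' 4 replicates at PEP <= `pep_max`, per condition. Candidates are
#' non-contaminant proteins included under std-Ca with zero detections
#' in any low-Ca sample (strictest exclusivity reading; set
#' `shared_rule = "inclusion"` to require only failing the low-Ca
#' inclusion rule instead). The std-Ca/low-Ca shared set and the
#' low-Ca-only set are reported separately.
#'
#' @inheritParams filter_coccolith
#' @param shared_rule `"any_detection"` (default) or `"inclusion"`.
#' @return List: `candidates` (candidate_set of std-Ca-exclusive
#'   proteins), `shared` (std-Ca and low-Ca), `low_only`, `identified`
#'   (std-Ca inclusion list before contaminant removal), `excluded`,
#'   `counts`.
#' @export
filter_coccosphere <- function(evidence, contaminants = character(),
                               config = pipeline_config(),
                               shared_rule = c("any_detection", "inclusion")) {
  .check_evidence(evidence)
  shared_rule <- match.arg(shared_rule)
  sub <- evidence[evidence$dataset == "coccosphere", , drop = FALSE]
  for (cond in c("std_ca", "low_ca"))
    if (!any(sub$condition == cond))
      stop("coccosphere dataset lacks condition '", cond, "'")
  reps_std <- .reps_passing(evidence, "coccosphere", "std_ca", config$pep_max)
  reps_low <- .reps_passing(evidence, "coccosphere", "low_ca", config$pep_max)
  incl_std <- sort(names(reps_std)[reps_std >= config$min_reps_coccosphere])
  incl_low <- sort(names(reps_low)[reps_low >= config$min_reps_coccosphere])
  all_prot <- sort(unique(sub$protein))
  contam <- intersect(incl_std, contaminants)
  survivors <- setdiff(incl_std, contam)
  low_detected <- if (shared_rule == "any_detection")
    unique(sub$protein[sub$condition == "low_ca"]) else incl_low
  exclusive <- setdiff(survivors, low_detected)
  shared <- intersect(survivors, low_detected)
  low_only <- setdiff(incl_low, incl_std)
  excluded <- rbind(
    .reason_df(setdiff(all_prot, incl_std), "below_replicate_or_pep_rule"),
    .reason_df(contam, "contaminant"),
    .reason_df(shared, "also_detected_low_ca"))
  counts <- c(input = length(all_prot), identified = length(incl_std),
              contaminant = length(contam), exclusive = length(exclusive),
              shared = length(shared), low_only = length(low_only))
  stopifnot(counts[["input"]] == length(exclusive) + nrow(excluded))
  prov <- data.frame(protein = exclusive,
                     reps_passing_std = unname(reps_std[exclusive]),
                     stringsAsFactors = FALSE)
  list(candidates = .candidate_set("coccosphere", exclusive, prov),
       shared = shared, low_only = low_only, identified = incl_std,
       excluded = excluded, counts = counts)
}

#' Coccolith-vesicle (CV) candidate filter
#'
#' Candidates are non-contaminant proteins identified in the bottom
#' fractions of the calcifying (C-cell) density gradients and absent
#' from every non-calcifying (N-cell) control fraction. The rule is
#' defined relative to the control, so a missing N-cell condition is an
#' error.
#'
#' @inheritParams filter_coccolith
#' @return List: `candidates` (candidate_set), `excluded`, `counts`.
#' @export
filter_cv <- function(evidence, contaminants = character(),
                      config = pipeline_config()) {
  .check_evidence(evidence)
  sub <- evidence[evidence$dataset == "cv", , drop = FALSE]
  if (!any(sub$condition == "c_cells"))
    stop("cv dataset lacks condition 'c_cells'")
  if (!any(sub$condition == "n_cells"))
    stop("cv dataset lacks the N-cell control condition 'n_cells'")
  in_c <- sort(unique(sub$protein[sub$condition == "c_cells" &
                                    sub$pep <= config$pep_max]))
  in_n <- unique(sub$protein[sub$condition == "n_cells"])
  all_prot <- sort(unique(sub$protein))
  exclusive <- setdiff(in_c, in_n)
  contam <- intersect(exclusive, contaminants)
  candidates <- setdiff(exclusive, contam)
  excluded <- rbind(
    .reason_df(setdiff(all_prot, in_c), "not_identified_in_c_cells"),
    .reason_df(intersect(in_c, in_n), "also_in_n_cells"),
    .reason_df(contam, "contaminant"))
  counts <- c(input = length(all_prot), c_identified = length(in_c),
              contaminant = length(contam), candidates = length(candidates))
  stopifnot(counts[["input"]] == length(candidates) + nrow(excluded))
  prov <- data.frame(protein = candidates, stringsAsFactors = FALSE)
  list(candidates = .candidate_set("CV", candidates, prov),
       excluded = excluded, counts = counts)
}

#' Cross-dataset overlap analysis
#'
#' Computes, for named candidate sets, all pairwise (and every observed
#' higher-order) intersection, and the union of proteins appearing in
#' at least two sets. Internal consistency is verified by
#' inclusion-exclusion: each protein's membership pattern is counted
#' once, and the pattern counts sum to the union of all sets.
#'
#' @param sets named list of character vectors or `candidate_set`
#'   objects (at least 2; unique names).
#' @return A list of class `overlap_report`: `pairwise` (data frame
#'   `set_a`, `set_b`, `n`, `members`), `patterns` (data frame of
#'   exclusive membership patterns with counts), `multi` (proteins in
#'   >= 2 sets), `n_multi`.
#' @export
overlap_analysis <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s)
    unique(if (inherits(s, "candidate_set")) s$members else as.character(s)))
  nm <- names(sets)
  pairs <- utils::combn(nm, 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    inter <- intersect(sets[[a]], sets[[b]])
    data.frame(set_a = a, set_b = b, n = length(inter),
               members = paste(sort(inter), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, nm))
  pattern <- apply(memb, 1L, function(r) paste(nm[r], collapse = "+"))
  patterns <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(patterns) <- c("pattern", "n")
  n_sets <- rowSums(memb)
  multi <- universe[n_sets >= 2L]
  stopifnot(sum(patterns$n) == length(universe))  # inclusion-exclusion check
  structure(list(pairwise = pairwise, patterns = patterns,
                 multi = multi, n_multi = length(multi)),
            class = "overlap_report")
}
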