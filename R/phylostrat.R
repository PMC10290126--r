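#' Construct an orthogroup table
#'
#' An orthogroup table maps each orthogroup to its member protein ids per
#' species, in the wide layout produced by orthology inference. The
#' presence set of an orthogroup is the set of species with at least one
#' member.
#'
#' @param members named list (one element per orthogroup) of named lists
#'   (species -> character vector of member protein ids; empty vectors
#'   allowed and dropped).
#' @param species optional character vector fixing the species universe;
#'   defaults to the union observed in `members`.
#' @return A list of class `orthogroup_table` with elements `id`,
#'   `members` and `species`.
#' @export
orthogroup_table <- function(members, species = NULL) {
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("every orthogroup must be named")
  if (anyDuplicated(names(members)))
    stop("duplicate orthogroup id")
  members <- lapply(members, function(m) {
    m <- m[vapply(m, length, 1L) > 0L]
    lapply(m, as.character)
  })
  seen <- unique(unlist(lapply(members, names), use.names = FALSE))
  if (is.null(species)) species <- sort(seen)
  if (length(setdiff(seen, species)))
    stop("species in members but not in species universe: ",
         paste(setdiff(seen, species), collapse = ", "))
  prot <- unlist(members, use.names = FALSE)
  structure(list(id = names(members), members = members, species = species),
            class = "orthogroup_table")
}

#' @rdname orthogroup_table
#' @param x an `orthogroup_table`.
#' @param og orthogroup id.
#' @return `presence_set()`: character vector of species with members.
#' @export
presence_set <- function(x, og) {
  stopifnot(inherits(x, "orthogroup_table"))
  names(x$members[[og]])
}

#' Read / write orthogroup tables
#'
#' Wide tab-separated layout with a header row:
#' `Orthogroup<TAB>speciesA<TAB>speciesB...`, cells holding
#' comma-separated member protein ids (empty cell = absent).
#'
#' @param path TSV file.
#' @return An [orthogroup_table].
#' @export
read_orthogroups <- function(path) {
  df <- read_tsv(path)
  if (names(df)[[1L]] != "Orthogroup")
    stop("first column must be 'Orthogroup'")
  species <- names(df)[-1L]
  members <- lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(species, function(s) {
      cell <- as.character(df[[s]][[i]])
      if (is.na(cell) || !nzchar(cell)) character() else
        trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
    })
    names(row) <- species
    row
  })
  names(members) <- as.character(df$Orthogroup)
  orthogroup_table(members, species = species)
}

#' @rdname read_orthogroups
#' @param x an [orthogroup_table].
#' @param config optional `pipeline_config` recorded in the file header.
#' @export
write_orthogroups <- function(x, path, config = NULL) {
  stopifnot(inherits(x, "orthogroup_table"))
  cells <- vapply(x$id, function(og) {
    vapply(x$species, function(s) {
      m <- x$members[[og]][[s]]
      if (is.null(m)) "" else paste(m, collapse = ",")
    }, "")
  }, character(length(x$species)))
  df <- data.frame(Orthogroup = x$id, t(cells), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("Orthogroup", x$species)
  write_tsv(df, path, config = config)
}

#' Assign the evolutionary origin of a presence set
#'
#' Under single-gain (Dollo-style) parsimony the origin of an orthogroup
#' is the last common ancestor of the species in which it is present:
#' later losses can only make a group look younger, never older. The
#' implementation climbs from one presence leaf toward the root until
#' the clade below contains every presence species.
#'
#' @param presence character vector of species (leaf labels), non-empty.
#' @param tree a guide tree from [read_guide_tree()].
#' @return The label of the origin node (a leaf label if the presence
#'   set is a single species).
#' @export
assign_origin <- function(presence, tree) {
  presence <- unique(as.character(presence))
  if (!length(presence)) stop("empty presence set")
  missing <- setdiff(presence, tree$tip.label)
  if (length(missing)) stop("species not in tree: ", missing[[1L]])
  tips <- match(presence, tree$tip.label)
  pv <- .parent_vec(tree)
  node <- tips[[1L]]
  while (!all(tips %in% .clade_tips(tree, node))) node <- pv[node]
  .node_label(tree, node)
}

#' Stratify orthogroups by evolutionary origin
#'
#' Assigns every orthogroup containing the focal species an origin node
#' via [assign_origin()], labels each focal-species protein with the
#' stratum of its orthogroup, and counts origins per node root-to-tip
#' (preorder). Conservation invariant: the per-node counts sum to the
#' number of focal-containing orthogroups.
#'
#' @param orthogroups an [orthogroup_table].
#' @param tree guide tree.
#' @param focal_species leaf label of the focal species.
#' @return A list of class `stratum_assignment`: `assignment`
#'   (orthogroup, origin), `protein_strata` (protein, stratum,
#'   orthogroup), `counts` (node, count; preorder), `focal_species`.
#' @export
stratify_orthogroups <- function(orthogroups, tree, focal_species) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  if (!focal_species %in% tree$tip.label)
    stop("focal species not a leaf of the tree: ", focal_species)
  has_focal <- vapply(orthogroups$id, function(og)
    focal_species %in% presence_set(orthogroups, og), TRUE)
  ids <- orthogroups$id[has_focal]
  origin <- vapply(ids, function(og)
    assign_origin(presence_set(orthogroups, og), tree), "")
  assignment <- data.frame(orthogroup = ids, origin = unname(origin),
                           stringsAsFactors = FALSE)
  prot <- lapply(ids, function(og) orthogroups$members[[og]][[focal_species]])
  protein_strata <- data.frame(
    protein = unlist(prot, use.names = FALSE),
    stratum = rep(unname(origin), vapply(prot, length, 1L)),
    orthogroup = rep(ids, vapply(prot, length, 1L)),
    stringsAsFactors = FALSE)
  ord <- .preorder_nodes(tree)
  node_labels <- .node_label(tree, ord)
  counts <- data.frame(node = node_labels,
                       count = as.integer(table(factor(origin, levels = node_labels))),
                       stringsAsFactors = FALSE)
  structure(list(assignment = assignment, protein_strata = protein_strata,
                 counts = counts, focal_species = focal_species),
            class = "stratum_assignment")
}

#' Detect orthogroups lost in one lineage but retained in the focal species
#'
#' Returns the orthogroups that (i) contain the focal species, (ii) do
#' not contain `lost_in`, and (iii) originate on the path from
#' `min_age_node` down to the last common ancestor of `lost_in` and the
#' focal species (inclusive) — i.e. groups old enough that the `lost_in`
#' lineage descends from their origin, so their absence there is a loss.
#'
#' @param orthogroups an [orthogroup_table].
#' @param tree guide tree.
#' @param lost_in leaf label of the lineage screened for losses.
#' @param min_age_node label of the oldest admissible origin (must be an
#'   ancestor of both leaves).
#' @param focal_species focal leaf label.
#' @return Character vector of qualifying orthogroup ids.
#' @export
detect_losses <- function(orthogroups, tree, lost_in, min_age_node, focal_species) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  for (leaf in c(lost_in, focal_species))
    if (!leaf %in% tree$tip.label) stop("not a leaf of the tree: ", leaf)
  pv <- .parent_vec(tree)
  min_idx <- .label_index(tree, min_age_node)
  lost_idx <- match(lost_in, tree$tip.label)
  focal_idx <- match(focal_species, tree$tip.label)
  if (!.is_ancestor(tree, min_idx, lost_idx, pv))
    stop("min_age_node '", min_age_node, "' is not ancestral to ", lost_in)
  if (!.is_ancestor(tree, min_idx, focal_idx, pv))
    stop("min_age_node '", min_age_node, "' is not ancestral to ", focal_species)
  # qualifying origins: path from LCA(lost_in, focal) up to min_age_node
  lca_lab <- assign_origin(c(lost_in, focal_species), tree)
  lca_idx <- .label_index(tree, lca_lab)
  path <- .path_to_root(tree, lca_idx, pv)
  stop_at <- match(min_idx, path)
  if (is.na(stop_at)) stop("min_age_node is below the LCA of the two leaves")
  qualifying <- .node_label(tree, path[seq_len(stop_at)])
  keep <- vapply(orthogroups$id, function(og) {
    pres <- presence_set(orthogroups, og)
    focal_species %in% pres && !lost_in %in% pres &&
      assign_origin(pres, tree) %in% qualifying
  }, TRUE)
  orthogroups$id[keep]
}

#' Hypergeometric domain enrichment within a phylostratum
#'
#' Tests each Pfam domain for over-representation among stratum proteins
#' relative to a background set (typically the whole proteome). Domain
#' counting is per-protein presence: a protein with several copies of a
#' domain counts once, so the hypergeometric urn is over proteins. Only
#' domain hits with i-Evalue below the configured ceiling are admitted.
#' The p-value is the upper tail P(X >= k). With at least 50 tested
#' domains a local-fdr estimate (Storey-type pi0 times a p-value
#' histogram density ratio) decides enrichment; below that the BH
#' q-value is the fallback, with a notice.
#'
#' @param stratum_proteins character vector, a subset of `background_proteins`.
#' @param background_proteins character vector of all proteins in the urn.
#' @param domain_table data frame with columns `protein`, `domain` and
#'   optionally `ievalue` (taken as passing when absent).
#' @param config a [pipeline_config()].
#' @return Data frame with one row per tested domain: urn counts
#'   (`k`, `n`, `K`, `N`), `p`, `q` (BH), `local_fdr` and `enriched`.
#' @export
enrich_domains <- function(stratum_proteins, background_proteins, domain_table,
                           config = pipeline_config()) {
  stratum_proteins <- unique(as.character(stratum_proteins))
  background_proteins <- unique(as.character(background_proteins))
  if (length(setdiff(stratum_proteins, background_proteins)))
    stop("stratum proteins must be a subset of the background")
  stopifnot(all(c("protein", "domain") %in% names(domain_table)))
  if ("ievalue" %in% names(domain_table))
    domain_table <- domain_table[domain_table$ievalue < config$ievalue_max, , drop = FALSE]
  domain_table <- domain_table[domain_table$protein %in% background_proteins, , drop = FALSE]
  domain_table <- unique(domain_table[c("protein", "domain")])
  if (nrow(domain_table) == 0L)
    return(data.frame(domain = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(), q = numeric(),
                      local_fdr = numeric(), enriched = logical()))
  N <- length(background_proteins)
  n <- length(stratum_proteins)
  doms <- sort(unique(domain_table$domain))
  K <- vapply(doms, function(d)
    length(unique(domain_table$protein[domain_table$domain == d])), 1L)
  k <- vapply(doms, function(d) {
    p <- unique(domain_table$protein[domain_table$domain == d])
    sum(p %in% stratum_proteins)
  }, 1L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  if (length(doms) >= 50L) {
    lfdr <- .local_fdr(p)
    enriched <- lfdr < config$local_fdr_cutoff
  } else {
    message("fewer than 50 tested domains: falling back to BH q < ",
            config$adj_p_cutoff, " for the enriched flag")
    lfdr <- rep(NA_real_, length(p))
    enriched <- q < config$adj_p_cutoff
  }
  data.frame(domain = doms, k = k, n = n, K = K, N = N, p = p, q = q,
             local_fdr = lfdr, enriched = enriched,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Local fdr from the p-value histogram: pi0 estimated from the flat tail
# (lambda = 0.5), density by a fixed-width histogram; lfdr = pi0 / f(p),
# capped to [0,1] and made monotone non-decreasing in p.
.local_fdr <- function(p, n_bins = 20L, lambda = 0.5) {
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(p, breaks, rightmost.closed = TRUE), 1L), n_bins)
  dens <- tabulate(bin, n_bins) / length(p) * n_bins
  lfdr <- pmin(1, pi0 / pmax(dens[bin], .Machine$double.eps))
  ord <- order(p)
  lfdr[ord] <- cummax(lfdr[ord])
  lfdr
}

#' Per-stratum sequence-property distributions
#'
#' For each stratum, collects the low-complexity fraction ([seg_mask()])
#' and disorder fraction ([disorder_fraction()]) of its proteins and
#' compares each stratum distribution to the whole-collection background
#' with a two-sample Kolmogorov-Smirnov statistic. Strata with fewer
#' than two proteins get their distribution but an NA KS statistic.
#'
#' @param assignment a `stratum_assignment` from [stratify_orthogroups()].
#' @param sequences a protein [seq_records] collection covering every
#'   assigned protein.
#' @return A list with `per_protein` (protein, stratum, lc_fraction,
#'   disorder_fraction) and `per_stratum` (stratum, n, KS statistics and
#'   p-values for both properties).
#' @export
stratum_property_profile <- function(assignment, sequences) {
  stopifnot(inherits(assignment, "stratum_assignment"),
            inherits(sequences, "seq_records"))
  ps <- assignment$protein_strata
  if (nrow(ps) == 0L) {
    warning("empty stratum assignment: empty profile")
    return(list(per_protein = data.frame(), per_stratum = data.frame()))
  }
  missing <- setdiff(ps$protein, sequences$id)
  if (length(missing)) stop("no sequence for protein: ", missing[[1L]])
  seqs <- sequences$residues[match(ps$protein, sequences$id)]
  lc <- vapply(seqs, function(s) seg_mask(s)$fraction, 0, USE.NAMES = FALSE)
  dis <- vapply(seqs, function(s) disorder_fraction(s)$fraction, 0, USE.NAMES = FALSE)
  per_protein <- data.frame(protein = ps$protein, stratum = ps$stratum,
                            lc_fraction = lc, disorder_fraction = dis,
                            stringsAsFactors = FALSE)
  strata <- unique(ps$stratum)
  rows <- lapply(strata, function(st) {
    sel <- per_protein$stratum == st
    n <- sum(sel)
    if (n >= 2L && n < nrow(per_protein)) {
      ks_lc <- suppressWarnings(stats::ks.test(per_protein$lc_fraction[sel],
                                               per_protein$lc_fraction))
      ks_dis <- suppressWarnings(stats::ks.test(per_protein$disorder_fraction[sel],
                                                per_protein$disorder_fraction))
      data.frame(stratum = st, n = n,
                 ks_lc = unname(ks_lc$statistic), ks_lc_p = ks_lc$p.value,
                 ks_disorder = unname(ks_dis$statistic), ks_disorder_p = ks_dis$p.value,
                 stringsAsFactors = FALSE)
    } else if (n == nrow(per_protein)) {
      data.frame(stratum = st, n = n, ks_lc = 0, ks_lc_p = 1,
                 ks_disorder = 0, ks_disorder_p = 1, stringsAsFactors = FALSE)
    } else {
      data.frame(stratum = st, n = n, ks_lc = NA_real_, ks_lc_p = NA_real_,
                 ks_disorder = NA_real_, ks_disorder_p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  list(per_protein = per_protein, per_stratum = do.call(rbind, rows))
}
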