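#' @include calciproteo-package.R
NULL

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                  "S","T","V","W","Y","X")
.NT_ALPHABET <- c("A","C","G","T","N")

#' Construct a sequence-record collection
#'
#' A `seq_records` object is a data frame with columns `id`, `description`
#' and `residues`, carrying protein (20 amino acids plus X) or nucleotide
#' (ACGTN) sequences. Ids must be unique and residues non-empty.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (upper case enforced).
#' @param description optional free-text descriptions (default `""`).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A data frame of class `seq_records`.
#' @export
seq_records <- function(id, residues, description = "", alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("'id' and 'residues' must have equal length")
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1L]])
  if (any(!nzchar(residues))) {
    stop("empty residues for id: ", id[which(!nzchar(residues))[1L]])
  }
  allowed <- if (alphabet == "protein") .AA_ALPHABET else .NT_ALPHABET
  for (i in seq_along(residues)) {
    chars <- strsplit(residues[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   chars[bad[1L]], id[[i]], bad[1L]))
    }
  }
  out <- data.frame(id = id, description = rep_len(as.character(description), length(id)),
                    residues = residues, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into a sequence-record collection
#'
#' Headers are split at the first whitespace into id and description.
#' Lowercase residues are upper-cased with a warning; a trailing stop
#' codon (`*`) on a protein sequence is stripped with a warning.
#' Duplicate ids and out-of-alphabet characters are hard errors that
#' name the offending record (and position).
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` (default) or `"nucleotide"`.
#' @return A [seq_records] collection, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- as.character(set)
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id in ", path, ": ", dup[[1L]])
  if (any(grepl("[a-z]", res))) {
    warning("lowercase residues upper-cased on load")
    res <- toupper(res)
  }
  if (alphabet == "protein" && any(endsWith(res, "*"))) {
    warning("trailing stop codon '*' stripped from ",
            sum(endsWith(res, "*")), " record(s)")
    res <- sub("\\*$", "", res)
  }
  seq_records(id, res, desc, alphabet = alphabet)
}

#' Write sequence records as FASTA
#'
#' @param records a [seq_records] collection.
#' @param path output file.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  stopifnot(inherits(records, "seq_records"))
  nm <- ifelse(nzchar(records$description),
               paste(records$id, records$description), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a rooted guide tree from newick
#'
#' Leaf labels are species ids; internal node labels name phylostrata
#' (e.g. Haptophyta, Calcihaptophycidae). Unlabelled internal nodes are
#' auto-named `N1..Nk` in preorder (root first), deterministically across
#' re-reads of the same file. Duplicate leaf labels are a hard error; a
#' multifurcating root is accepted with a warning.
#'
#' @param path newick file, or use `text` for a literal string.
#' @param text optional newick string (overrides `path`).
#' @return An `ape::phylo` tree satisfying the guide-tree invariants.
#' @export
read_guide_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("no such file: ", path)
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse newick input")
  validate_guide_tree(tree)
}

#' @rdname read_guide_tree
#' @param tree an `ape::phylo` object to validate/normalize in place.
#' @export
validate_guide_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate leaf label: ", dup[[1L]])
  root_children <- tree$edge[tree$edge[, 1L] == ape::Ntip(tree) + 1L, 2L]
  if (length(root_children) > 2L)
    warning("multifurcating root accepted (", length(root_children), " children)")
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  ord <- .preorder_nodes(tree)
  internal_pre <- ord[ord > ape::Ntip(tree)] - ape::Ntip(tree)
  k <- 0L
  for (i in internal_pre) {
    if (!nzchar(lab[[i]])) {
      repeat {
        k <- k + 1L
        cand <- paste0("N", k)
        if (!cand %in% c(tree$tip.label, lab)) break
      }
      lab[[i]] <- cand
    }
  }
  dupn <- lab[duplicated(lab)]
  if (length(dupn)) stop("duplicate stratum (internal node) label: ", dupn[[1L]])
  clash <- intersect(lab, tree$tip.label)
  if (length(clash)) stop("label used for both a leaf and an internal node: ", clash[[1L]])
  tree$node.label <- lab
  tree
}

# preorder node indices (root first), deterministic for a given edge matrix
.preorder_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- ape::Ntip(tree) + 1L
  c(root, tree$edge[, 2L])[!duplicated(c(root, tree$edge[, 2L]))]
}

#' Assembly summary statistics
#'
#' Computes total size, scaffold count, N50 and GC percentage for a set
#' of nucleotide contigs/scaffolds. N50 is the length L such that
#' contigs of length >= L cover at least half the assembly (inclusive
#' rule when the cumulative sum hits exactly 50%). GC% is computed over
#' non-N bases.
#'
#' @param contigs a nucleotide [seq_records] collection.
#' @return A list with `size`, `n_scaffolds`, `n50` and `gc_percent`.
#' @export
assembly_stats <- function(contigs) {
  stopifnot(inherits(contigs, "seq_records"))
  if (nrow(contigs) == 0L) stop("empty contig collection")
  if (!identical(attr(contigs, "alphabet"), "nucleotide"))
    stop("assembly_stats expects nucleotide records")
  len <- nchar(contigs$residues)
  total <- sum(len)
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1L]]
  chars <- strsplit(paste(contigs$residues, collapse = ""), "", fixed = TRUE)[[1L]]
  nonN <- chars[chars != "N"]
  gc <- 100 * sum(nonN %in% c("G", "C")) / length(nonN)
  list(size = total, n_scaffolds = nrow(contigs), n50 = n50, gc_percent = gc)
}

#' Pipeline configuration
#'
#' Central container for the thresholds used across the pipeline:
#' de novo score gate, peptide/protein probability cutoffs, posterior
#' error probability ceiling, Pfam i-Evalue ceiling, BH-adjusted p and
#' local-fdr cutoffs, replicate minima for the coccolith (2 of 3) and
#' coccosphere (3 of 4) filters, the spectral clustering similarity
#' threshold, and the root RNG seed.
#'
#' @param denovo_score_cutoff de novo quality gate (default 60).
#' @param peptide_prob_cutoff peptide probability cutoff (default 0.95).
#' @param protein_prob_cutoff protein probability cutoff (default 0.99).
#' @param pep_max posterior error probability ceiling (default 0.01).
#' @param ievalue_max Pfam i-Evalue ceiling (default 1e-3).
#' @param adj_p_cutoff BH-adjusted p cutoff (default 0.05).
#' @param local_fdr_cutoff local-fdr cutoff for enrichment (default 0.05).
#' @param min_reps_coccolith replicates required of 3 (default 2).
#' @param min_reps_coccosphere replicates required of 4 (default 3).
#' @param cluster_similarity_threshold spectral clustering threshold
#'   in `[0,1]` (default 0.7).
#' @param rng_seed integer root seed (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(denovo_score_cutoff = 60,
                            peptide_prob_cutoff = 0.95,
                            protein_prob_cutoff = 0.99,
                            pep_max = 0.01,
                            ievalue_max = 1e-3,
                            adj_p_cutoff = 0.05,
                            local_fdr_cutoff = 0.05,
                            min_reps_coccolith = 2L,
                            min_reps_coccosphere = 3L,
                            cluster_similarity_threshold = 0.7,
                            rng_seed = 1L) {
  cfg <- list(denovo_score_cutoff = denovo_score_cutoff,
              peptide_prob_cutoff = peptide_prob_cutoff,
              protein_prob_cutoff = protein_prob_cutoff,
              pep_max = pep_max,
              ievalue_max = ievalue_max,
              adj_p_cutoff = adj_p_cutoff,
              local_fdr_cutoff = local_fdr_cutoff,
              min_reps_coccolith = as.integer(min_reps_coccolith),
              min_reps_coccosphere = as.integer(min_reps_coccosphere),
              cluster_similarity_threshold = cluster_similarity_threshold,
              rng_seed = as.integer(rng_seed))
  probs <- c("peptide_prob_cutoff", "protein_prob_cutoff", "pep_max",
             "adj_p_cutoff", "local_fdr_cutoff", "cluster_similarity_threshold")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(p, " must be a probability in [0,1]")
  }
  if (cfg$min_reps_coccolith < 1L || cfg$min_reps_coccolith > 3L)
    stop("min_reps_coccolith must be in 1..3")
  if (cfg$min_reps_coccosphere < 1L || cfg$min_reps_coccosphere > 4L)
    stop("min_reps_coccosphere must be in 1..4")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take package defaults.
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a data frame as TSV with a provenance header
#'
#' All tabular outputs of the pipeline carry a `#`-prefixed header block
#' recording the package version, the RNG seed and any config values
#' passed, so every file is self-describing.
#'
#' @param df data frame.
#' @param path output file.
#' @param config optional `pipeline_config` whose values go in the header.
#' @param extra optional named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, config = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# calciproteo %s",
                     as.character(utils::packageVersion("calciproteo"))), con)
  if (!is.null(config)) {
    for (k in names(unclass(config)))
      writeLines(sprintf("# config %s: %s", k, format(config[[k]])), con)
  }
  if (!is.null(extra)) {
    for (k in names(extra))
      writeLines(sprintf("# %s: %s", k, format(extra[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline (or any headered TSV)
#'
#' `#` comment lines are skipped; required columns are validated.
#' The returned data frame carries a `provenance` attribute with the
#' source path and load time.
#'
#' @param path TSV file with a header row.
#' @param required character vector of required column names.
#' @return A data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  attr(df, "provenance") <- list(source = path, loaded = Sys.time())
  df
}
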