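# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the LCA oracle intersects explicit
# root-to-leaf paths on the raw edge matrix, the hypergeometric oracle
# enumerates draws, the segmentation oracle recomputes every window
# entropy from scratch.

# root-to-leaf path of node indices (root first), from the edge matrix only
oracle_path_from_root <- function(tree, tip_idx) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- tip_idx
  while (parent[path[1]] != 0) path <- c(parent[path[1]], path)
  path
}

# brute-force LCA: intersect all root-to-leaf paths, take the deepest
# shared node (the last element of the common prefix)
oracle_lca_label <- function(tree, presence) {
  tips <- match(presence, tree$tip.label)
  paths <- lapply(tips, oracle_path_from_root, tree = tree)
  shared <- Reduce(intersect, paths)
  deepest <- shared[which.max(vapply(shared, function(n)
    length(oracle_path_from_root(tree, n)), 1L))]
  # oracle_path_from_root works for internal nodes too (walks parents)
  ntip <- length(tree$tip.label)
  if (deepest <= ntip) tree$tip.label[deepest] else
    tree$node.label[deepest - ntip]
}

# random labelled guide tree with n leaves
random_guide_tree <- function(n) {
  tr <- ape::rtree(n, br = NULL)
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  validate_guide_tree(tr)
}

# exhaustive upper-tail hypergeometric: enumerate all C(N, n) draws from
# an urn with K marked balls and count draws with >= k marked
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# all-windows segmentation oracle: recompute every window entropy with
# table(), classify windows, mark residues of extendable runs holding a
# trigger window
oracle_seg_fraction <- function(seq, window = 12, trigger = 2.2, extension = 2.5) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  w <- min(window, L)
  ent <- sapply(seq_len(L - w + 1), function(i) {
    win <- chars[i:(i + w - 1)]
    win <- win[win != "X"]
    if (!length(win)) return(0)
    f <- table(win) / length(win)
    -sum(f * log2(f))
  })
  masked <- rep(FALSE, L)
  run_start <- NA
  for (i in seq_along(ent)) {
    if (ent[i] <= extension) {
      if (is.na(run_start)) run_start <- i
    }
    if ((ent[i] > extension || i == length(ent))) {
      run_end <- if (ent[i] > extension) i - 1 else i
      if (!is.na(run_start) && run_end >= run_start &&
          any(ent[run_start:run_end] <= trigger))
        masked[run_start:(run_end + w - 1)] <- TRUE
      run_start <- NA
    }
  }
  mean(masked)
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# expected loss set enumerated from planted truth with the brute-force
# LCA (origin of the *observed* presence set must fall on the
# qualifying path between min_age and the lost_in/focal ancestor)
oracle_expected_losses <- function(og, tree, lost_in, min_age, focal) {
  lca <- oracle_lca_label(tree, c(lost_in, focal))
  ntip <- length(tree$tip.label)
  lab_of <- function(i) if (i <= ntip) tree$tip.label[i] else tree$node.label[i - ntip]
  lca_idx <- match(lca, c(tree$tip.label, tree$node.label))
  up <- rev(oracle_path_from_root(tree, lca_idx))
  qualifying <- sapply(up[seq_len(match(
    match(min_age, c(tree$tip.label, tree$node.label)), up))], lab_of)
  Filter(function(id) {
    pres <- presence_set(og$orthogroups, id)
    focal %in% pres && !lost_in %in% pres &&
      oracle_lca_label(tree, pres) %in% qualifying
  }, og$orthogroups$id)
}
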