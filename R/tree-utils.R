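# Internal helpers over ape::phylo guide trees. Nodes are addressed by
# label strings in the public API and by ape's integer indices here
# (tips 1..Ntip, internals Ntip+1..Ntip+Nnode, root = Ntip+1).

.parent_vec <- function(tree) {
  pv <- integer(ape::Ntip(tree) + tree$Nnode)
  pv[tree$edge[, 2L]] <- tree$edge[, 1L]
  pv  # root keeps 0
}

.node_label <- function(tree, idx) {
  c(tree$tip.label, tree$node.label)[idx]
}

.label_index <- function(tree, label) {
  ntip <- ape::Ntip(tree)
  idx <- match(label, c(tree$tip.label, tree$node.label))
  if (anyNA(idx)) stop("label not in tree: ", label[which(is.na(idx))[1L]])
  idx
}

# tip indices under node idx (idx itself if a tip)
.clade_tips <- function(tree, idx) {
  ntip <- ape::Ntip(tree)
  if (idx <= ntip) return(idx)
  kids <- tree$edge[tree$edge[, 1L] == idx, 2L]
  unlist(lapply(kids, .clade_tips, tree = tree), use.names = FALSE)
}

# path of node indices from idx up to the root (inclusive both ends)
.path_to_root <- function(tree, idx, pv = .parent_vec(tree)) {
  out <- idx
  while (pv[idx] != 0L) {
    idx <- pv[idx]
    out <- c(out, idx)
  }
  out
}

# is 'anc' an ancestor-or-equal of 'node'?
.is_ancestor <- function(tree, anc, node, pv = .parent_vec(tree)) {
  anc %in% .path_to_root(tree, node, pv)
}
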