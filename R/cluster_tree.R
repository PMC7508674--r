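# Greedy identity clustering of RdRP proteins, Poisson-corrected distance
# trees, and delineation of metagenome clades: a node is accepted when at
# least 90% of its leaves are metagenome-derived (near-monophyly) or when its
# depth (node to deepest descendant leaf) is below 1.0 substitutions/site
# (shallow mixed group). Accepted calls are maximal and non-nested.

#' Pairwise protein identity
#'
#' Global alignment (BLOSUM62, affine gaps open 11 / extend 1); identity is
#' the number of identical aligned residue pairs over the chosen denominator
#' (default: length of the shorter sequence, MMseqs-like).
#'
#' @param a,b Protein strings.
#' @param denominator `"min"` (default) or `"alignment"` (aligned columns).
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, denominator = c("min", "alignment")) {
  denominator <- match.arg(denominator)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  nid <- Biostrings::nmatch(pa)
  den <- if (denominator == "min") min(nchar(a), nchar(b))
  else Biostrings::nchar(Biostrings::alignedPattern(pa))
  nid / den
}

#' Greedy identity clustering
#'
#' Sequences are sorted by length descending (ties by id ascending); each is
#' assigned to the first existing representative with identity >= threshold,
#' else founds a new cluster. The internal sort makes the result invariant to
#' input order.
#'
#' @param proteins data.frame with columns `id` and `seq`.
#' @param threshold Identity threshold in (0, 1].
#' @param denominator Passed to [pairwise_identity()].
#' @return List of class `cluster_set`: `threshold`, `clusters` (list of
#'   `list(representative, members)`), `membership` (named representative per
#'   input id).
#' @export
greedy_cluster <- function(proteins, threshold,
                           denominator = c("min", "alignment")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(proteins$seq), proteins$id)
  p <- proteins[ord, , drop = FALSE]
  reps <- character(0)
  rep_seqs <- character(0)
  members <- list()
  membership <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    assigned <- NA_integer_
    for (r in seq_along(reps)) {
      if (pairwise_identity(p$seq[i], rep_seqs[r],
                            denominator = denominator) >= threshold) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, p$id[i])
      rep_seqs <- c(rep_seqs, p$seq[i])
      members[[length(reps)]] <- p$id[i]
      membership[i] <- p$id[i]
    } else {
      members[[assigned]] <- c(members[[assigned]], p$id[i])
      membership[i] <- reps[assigned]
    }
  }
  structure(list(
    threshold = threshold,
    clusters = lapply(seq_along(reps), function(r) {
      list(representative = reps[r], members = members[[r]])
    }),
    membership = setNames(membership, p$id)
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d clusters at identity >= %.2f (%d sequences)\n",
              length(x$clusters), x$threshold, length(x$membership)))
  invisible(x)
}

#' Poisson-corrected distance matrix from protein identities
#'
#' d = -ln(1 - p) with p = 1 - identity, capped at p <= 0.95.
#'
#' @param proteins data.frame with `id` and `seq`.
#' @param denominator Passed to [pairwise_identity()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
protein_distances <- function(proteins, denominator = c("min", "alignment")) {
  denominator <- match.arg(denominator)
  n <- nrow(proteins)
  D <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- min(1 - pairwise_identity(proteins$seq[i], proteins$seq[j],
                                     denominator = denominator), 0.95)
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param D Symmetric non-negative matrix with zero diagonal (row/col names
#'   become leaf labels).
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix must be symmetric")
  stopifnot(all(diag(D) == 0))
  if (nrow(D) == 2L) {
    return(read_newick(text = sprintf("(%s:%.10g,%s:%.10g);",
                                      rownames(D)[1], D[1, 2] / 2,
                                      rownames(D)[2], D[1, 2] / 2)))
  }
  ape::nj(stats::as.dist(D))
}

# children list per node of a phylo tree (indices in ape numbering: tips
# 1..n, internals n+1..), plus parent edge lengths.
tree_children <- function(tree) {
  n_node <- max(tree$edge)
  ch <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  ch
}

#' Delineate metagenome clades on a labeled tree
#'
#' Traverses internal nodes from the root in preorder; a node is accepted if
#' its metagenome leaf fraction is >= `min_frac` (rule "monophyly") or its
#' depth -- the maximum path length from the node to any descendant leaf --
#' is < `max_depth` (rule "shallow"). Accepted subtrees are pruned from
#' further traversal, so calls are maximal and mutually non-nested. Unrooted
#' trees are midpoint-rooted first.
#'
#' @param tree `ape::phylo` tree.
#' @param origin Named character vector mapping every leaf label to
#'   `"metagenome"` or `"reference"`.
#' @param min_frac Metagenome-fraction threshold (default 0.90, inclusive).
#' @param max_depth Depth threshold in substitutions/site (default 1.0,
#'   exclusive).
#' @return List with `calls` (data.frame: node, n_leaves,
#'   metagenome_fraction, depth, rule, accepted) and `unassigned` (leaf
#'   labels not under any accepted node).
#' @export
delineate_clades <- function(tree, origin, min_frac = 0.90, max_depth = 1.0) {
  if (!all(tree$tip.label %in% names(origin))) {
    bad <- setdiff(tree$tip.label, names(origin))
    stop("unlabeled leaf: ", bad[1])
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  n_tip <- length(tree$tip.label)
  ch <- tree_children(tree)
  n_node <- max(tree$edge)
  n_meta <- numeric(n_node)
  n_leaf <- numeric(n_node)
  depth <- numeric(n_node)
  n_leaf[seq_len(n_tip)] <- 1
  n_meta[seq_len(n_tip)] <- as.numeric(origin[tree$tip.label] == "metagenome")
  # postorder accumulation over edges (children before parents)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    v <- po$edge[e, 2L]
    n_leaf[p] <- n_leaf[p] + n_leaf[v]
    n_meta[p] <- n_meta[p] + n_meta[v]
    depth[p] <- max(depth[p], po$edge.length[e] + depth[v])
  }
  root <- n_tip + 1L
  calls <- list()
  covered <- logical(n_tip)
  visit <- function(v) {
    if (v <= n_tip) return(invisible())
    frac <- n_meta[v] / n_leaf[v]
    mono <- frac >= min_frac
    shallow <- depth[v] < max_depth
    if (mono || shallow) {
      calls[[length(calls) + 1L]] <<- data.frame(
        node = v, n_leaves = n_leaf[v], metagenome_fraction = frac,
        depth = depth[v], rule = if (mono) "monophyly" else "shallow",
        accepted = TRUE, stringsAsFactors = FALSE)
      tips <- subtree_tips(v, ch, n_tip)
      covered[tips] <<- TRUE
      return(invisible())
    }
    for (k in ch[[v]]) visit(k)
  }
  visit(root)
  calls_df <- if (length(calls)) do.call(rbind, calls) else
    data.frame(node = integer(0), n_leaves = numeric(0),
               metagenome_fraction = numeric(0), depth = numeric(0),
               rule = character(0), accepted = logical(0))
  list(calls = calls_df, unassigned = tree$tip.label[!covered],
       tree = tree)
}

subtree_tips <- function(v, ch, n_tip) {
  if (v <= n_tip) return(v)
  unlist(lapply(ch[[v]], subtree_tips, ch = ch, n_tip = n_tip))
}
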