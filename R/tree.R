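#' Pairwise PAV distances between accessions
#'
#' Hamming distance is the proportion of genes whose presence state
#' differs between two accessions (shared absence counts as agreement);
#' Jaccard distance is one minus intersection over union of the two
#' presence sets (shared absence ignored). Hamming is the default: under
#' clade-structured gene loss, shared absence is phylogenetically
#' informative.
#'
#' @param pav A [pav_matrix()].
#' @param metric `"hamming"` or `"jaccard"`.
#'
#' @return Symmetric numeric matrix with zero diagonal, accession ids as
#'   dimnames.
#' @export
pav_distance <- function(pav, metric = c("hamming", "jaccard")) {
  stopifnot_pav(pav)
  metric <- match.arg(metric)
  pav_distance_matrix(t(pav$presence), metric)
}

# rows = accessions, cols = genes
pav_distance_matrix <- function(m, metric) {
  n_genes <- ncol(m)
  s11 <- tcrossprod(m)
  n1 <- diag(s11)
  both <- outer(n1, n1, "+")
  if (metric == "hamming") {
    d <- (both - 2 * s11) / n_genes
  } else {
    union <- both - s11
    d <- ifelse(union == 0, 0, 1 - s11 / union)
    if (any(union == 0 & row(union) != col(union))) {
      warning("accession pair(s) with empty gene-set union; ",
              "jaccard distance set to 0")
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the smallest (i, j) index pair in the current matrix order,
#' making the output deterministic. Negative branch lengths are clamped
#' to zero with the deficit transferred to the sibling edge, preserving
#' the path length between the joined pair. The final three nodes are
#' resolved exactly, giving an unrooted tree with a basal trifurcation.
#'
#' @param d Square symmetric numeric matrix with zero diagonal and
#'   row/column names; at least 3 taxa.
#'
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be square")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (is.null(rownames(d))) stop("`d` must carry taxon names")
  labels <- rownames(d)
  # subtree newick fragments, one per active node
  sub <- labels
  act <- d
  while (nrow(act) > 3) {
    n <- nrow(act)
    r <- rowSums(act)
    q <- (n - 2) * act - outer(r, r, "+")
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    hit <- which(q == min(q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    bi <- hit[1, 1]
    bj <- hit[1, 2]
    li <- act[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    lj <- act[bi, bj] - li
    lens <- clamp_pair(li, lj)
    new_d <- (act[bi, ] + act[bj, ] - act[bi, bj]) / 2
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[bi], lens[1],
                       sub[bj], lens[2])
    keep <- setdiff(seq_len(n), c(bi, bj))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], new_d[keep]),
                 c(new_d[keep], 0))
    sub <- c(sub[keep], new_sub)
  }
  dd <- act
  la <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  lb <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  lc <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1], la, sub[2], lb, sub[3], lc)
  ape::read.tree(text = nwk)
}

clamp_pair <- function(li, lj) {
  if (li < 0) {
    lj <- lj + li
    li <- 0
  }
  if (lj < 0) {
    li <- li + lj
    lj <- 0
  }
  c(max(li, 0), max(lj, 0))
}

#' Nontrivial splits of an unrooted tree
#'
#' Returns the bipartitions induced by internal edges, each encoded as a
#' canonical string: the side not containing the alphabetically first
#' leaf, sorted and joined with `"|"`. Trivial splits (single leaf vs
#' rest) are omitted.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n_tip - 2) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of nontrivial splits present in exactly one of the two
#' unrooted trees (symmetric difference of their split sets).
#'
#' @param tree_a,tree_b `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets")
  }
  sa <- tree_splits(tree_a)
  sb <- tree_splits(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Bootstrap support for the splits of a PAV tree
#'
#' Builds the point-estimate neighbor-joining tree from the full PAV
#' matrix, then resamples gene columns with replacement `n_reps` times,
#' rebuilds the tree for each replicate, and reports for every internal
#' split of the point tree the percentage of replicates containing it.
#'
#' @param pav A [pav_matrix()].
#' @param n_reps Number of bootstrap replicates.
#' @param metric Distance metric (see [pav_distance()]).
#' @param seed Integer seed for the resampling.
#'
#' @return List with `tree` (the point-estimate `phylo`, with supports
#'   attached as `node.label` where defined) and `split_support` (named
#'   numeric vector, split key -> support percentage).
#' @export
bootstrap_support <- function(pav, n_reps = 100,
                              metric = c("hamming", "jaccard"),
                              seed = 1) {
  stopifnot_pav(pav)
  metric <- match.arg(metric)
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- t(pav$presence)
  point <- neighbor_joining(pav_distance_matrix(m, metric))
  point_splits <- tree_splits(point)
  hits <- setNames(numeric(length(point_splits)), point_splits)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_tree <- neighbor_joining(pav_distance_matrix(m[, cols,
                                                       drop = FALSE],
                                                     metric))
    rs <- tree_splits(rep_tree)
    present <- point_splits %in% rs
    hits[present] <- hits[present] + 1
  }
  support <- 100 * hits / n_reps
  list(tree = attach_supports(point, support), split_support = support)
}

attach_supports <- function(tree, support) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  labels <- rep("", n_node)
  anchor <- sort(tree$tip.label)[1]
  for (node in seq_len(n_node) + n_tip) {
    tips <- tree$tip.label[descendant_tips(tree, node)]
    side <- tips
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[node - n_tip] <- sprintf("%g", support[[key]])
    }
  }
  tree$node.label <- labels
  tree
}

descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Test clade monophyly and compare against a truth tree
#'
#' A clade is monophyletic in an unrooted tree when its leaf set forms a
#' split of the tree (clades of size 1, n-1 or n are trivially
#' monophyletic). Optionally also reports the Robinson-Foulds distance
#' to a reference tree.
#'
#' @param tree An `ape::phylo`.
#' @param clade_map Named character vector mapping every leaf to a clade.
#' @param truth_tree Optional reference `phylo` over the same leaves.
#'
#' @return List with `monophyletic` (named logical vector per clade) and
#'   `rf` (integer or NA).
#' @export
clade_recovery <- function(tree, clade_map, truth_tree = NULL) {
  leaves <- tree$tip.label
  missing <- setdiff(leaves, names(clade_map))
  if (length(missing) > 0) {
    stop("leaf/leaves without clade: ",
         paste(head(missing, 5), collapse = ", "))
  }
  splits <- tree_splits(tree)
  anchor <- sort(leaves)[1]
  clades <- sort(unique(unname(clade_map[leaves])))
  mono <- vapply(clades, function(cl) {
    side <- leaves[clade_map[leaves] == cl]
    k <- length(side)
    if (k <= 1 || k >= length(leaves) - 1) return(TRUE)
    if (anchor %in% side) side <- setdiff(leaves, side)
    paste(sort(side), collapse = "|") %in% splits
  }, logical(1))
  rf <- if (is.null(truth_tree)) NA_integer_ else
    rf_distance(tree, truth_tree)
  list(monophyletic = mono, rf = rf)
}

#' Principal component analysis of a PAV matrix
#'
#' Centers each gene column and projects accessions onto the leading
#' principal components of the accession-by-gene matrix (via
#' `stats::prcomp`, no scaling). Component signs are fixed by making the
#' largest-magnitude gene loading of each component positive, so results
#' are reproducible across platforms.
#'
#' @param pav A [pav_matrix()].
#' @param n_components Number of components to return.
#'
#' @return Object of class `pav_pca`: list with `scores` (accessions x
#'   components), `loadings` (genes x components), `explained_variance`
#'   (fractions of total variance) and `total_variance`.
#' @export
pav_pca <- function(pav, n_components = 2) {
  stopifnot_pav(pav)
  x <- t(pav$presence)
  max_comp <- min(dim(x))
  if (n_components > max_comp) {
    stop("n_components exceeds min(accessions, genes) = ", max_comp)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = pc$sdev[keep]^2 / total_var,
                 total_variance = total_var),
            class = "pav_pca")
}

#' @export
print.pav_pca <- function(x, ...) {
  cat(sprintf("pav_pca: %d accessions, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance),
            collapse = ", "), "\n")
  invisible(x)
}
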