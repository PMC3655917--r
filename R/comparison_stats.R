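# Library comparison machinery: pairwise Pearson correlation of profiles,
# UPGMA (average-linkage) clustering of 1 - r distances, and ordinary
# bootstrap support (BP%) per internal node, obtained by resampling profile
# positions with replacement.

#' Pairwise Pearson correlation matrix of library profiles
#'
#' @param profiles a numeric matrix with one row per library (rownames are
#'   library ids), or a named list of equal-length numeric vectors. At least
#'   two profiles of length >= 3; each must have nonzero variance.
#' @return Symmetric correlation matrix with unit diagonal and library ids as
#'   dimnames.
#' @examples
#' pearson_matrix(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))
#' @export
pearson_matrix <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("lib_%d", seq_len(nrow(profiles)))
  if (nrow(profiles) < 2) stop("need at least two profiles")
  if (ncol(profiles) < 3) stop("profiles must have length >= 3")
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  r <- cor(t(profiles))
  diag(r) <- 1
  r
}

#' Distance from correlation
#'
#' The standard transform `d = 1 - r`: self-correlation maps to distance 0 and
#' `d >= 0` for all `r <= 1`.
#'
#' @param r a correlation matrix.
#' @return A distance matrix.
#' @export
correlation_distance <- function(r) {
  d <- 1 - r
  diag(d) <- 0
  d
}

# tie-break key for a candidate merge: the two clusters' smallest member ids,
# sorted; compared lexicographically
pair_key <- function(a_ids, b_ids) {
  k <- sort(c(min(a_ids), min(b_ids)))
  paste(k[1], k[2], sep = "\r")
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the inter-cluster
#' distance is the unweighted arithmetic mean of all member-pair distances
#' from the original matrix, and a merge at distance `d` sits at height
#' `d / 2` (so leaf-to-node path lengths are ultrametric). Ties are broken by
#' the lexicographically smallest pair of cluster-minimum member ids, making
#' the result independent of input row order.
#'
#' @param d symmetric, non-negative distance matrix with zero diagonal and
#'   library ids as dimnames.
#' @return An `upgma_tree`: list with `labels`, `merge` (hclust-style matrix:
#'   negative = leaf index, positive = earlier merge), `height` (per merge),
#'   and `clusters` (leaf-label sets below each internal node, in merge
#'   order).
#' @examples
#' d <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$height  # 0.05, 0.20
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("lib_%d", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be non-negative with zero diagonal")
  if (n < 2) stop("need at least two items")
  labels <- rownames(d)

  # active clusters: member leaf indices and node reference (hclust signs)
  members <- as.list(seq_len(n))
  noderef <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  clusters <- vector("list", n - 1L)

  cluster_dist <- function(a, b) mean(d[a, b])

  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        dij <- cluster_dist(members[[i]], members[[j]])
        key <- pair_key(labels[members[[i]]], labels[members[[j]]])
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 && key < best$key)) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(noderef[i], noderef[j])
    height[step] <- best$d / 2
    new_members <- c(members[[i]], members[[j]])
    clusters[[step]] <- sort(labels[new_members])
    members[[i]] <- new_members
    noderef[i] <- step
    members[[j]] <- NULL
    noderef <- noderef[-j]
  }
  structure(list(labels = labels, merge = merge, height = height,
                 clusters = clusters),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Serialise a tree to Newick
#'
#' Branch lengths are height differences between a node and its parent
#' (leaves sit at height 0); internal node labels carry bootstrap support
#' when supplied.
#'
#' @param tree an `upgma_tree`.
#' @param supports optional numeric vector of supports, one per internal node
#'   in merge order (as produced by [bootstrap_support()]).
#' @param digits significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, supports = NULL, digits = 6) {
  node_height <- function(k) if (k < 0) 0 else tree$height[k]
  fmt <- function(x) sprintf("%.*g", digits, x)
  build <- function(k) {
    if (k < 0) return(tree$labels[-k])
    l <- tree$merge[k, 1]; r <- tree$merge[k, 2]
    lab <- if (!is.null(supports)) fmt(supports[k]) else ""
    sprintf("(%s:%s,%s:%s)%s",
            build(l), fmt(tree$height[k] - node_height(l)),
            build(r), fmt(tree$height[k] - node_height(r)), lab)
  }
  paste0(build(nrow(tree$merge)), ";")
}

# canonical keys for the leaf sets below each internal node
cluster_keys <- function(tree) {
  vapply(tree$clusters, paste, character(1), collapse = "\r")
}

#' Bootstrap support for UPGMA clusters of library profiles
#'
#' Builds the base tree from `d = 1 - r` (Pearson) distances, then resamples
#' the profile positions (bins / protein clusters) with replacement `n_boot`
#' times, recomputing correlation, distance and UPGMA each time. The support
#' of an internal node is the percentage of replicates whose tree contains
#' the same set of leaves as a cluster (ordinary bootstrap proportions,
#' BP\%).
#'
#' @param profiles libraries x positions numeric matrix (rownames = ids),
#'   >= 3 rows.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed; results are reproducible given (profiles,
#'   n_boot, seed).
#' @return An `upgma_bootstrap`: list with `tree` (the base `upgma_tree`),
#'   `supports` (BP\% per internal node, merge order; root = 100 by
#'   construction), `r` (base correlation matrix) and `n_boot`.
#' @export
bootstrap_support <- function(profiles, n_boot = 100L, seed = 1L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop("need at least three profiles to bootstrap")
  if (n_boot < 1) stop("n_boot must be >= 1")
  r <- pearson_matrix(profiles)
  tree <- upgma(correlation_distance(r))
  keys <- cluster_keys(tree)
  hits <- setNames(numeric(length(keys)), keys)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in 1:100) {
        idx <- sample.int(ncol(profiles), replace = TRUE)
        sub <- profiles[, idx, drop = FALSE]
        if (all(apply(sub, 1, sd) > 0)) break
        if (attempt == 100) stop("could not draw a non-degenerate bootstrap sample")
      }
      bt <- upgma(correlation_distance(pearson_matrix(sub)))
      bk <- cluster_keys(bt)
      present <- keys %in% bk
      hits[present] <- hits[present] + 1
    }
  })
  structure(list(tree = tree, supports = unname(100 * hits / n_boot),
                 r = r, n_boot = n_boot),
            class = "upgma_bootstrap")
}

#' @export
print.upgma_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrapped UPGMA (%d replicates, BP%%):\n", x$n_boot))
  cat(to_newick(x$tree, supports = x$supports), "\n")
  invisible(x)
}

#' Support for the cluster joining a given set of leaves
#'
#' @param boot an `upgma_bootstrap`.
#' @param leaves character vector of leaf labels.
#' @return The BP\% support of the internal node whose leaf set equals
#'   `leaves`, or `NA` if no such node exists in the base tree.
#' @export
support_for <- function(boot, leaves) {
  key <- paste(sort(leaves), collapse = "\r")
  i <- match(key, cluster_keys(boot$tree))
  if (is.na(i)) NA_real_ else boot$supports[i]
}

#' Convert an `upgma_tree` to an `ape` phylo object
#'
#' @param tree an `upgma_tree`.
#' @param supports optional supports used as node labels.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(tree, supports = NULL) {
  ape::read.tree(text = to_newick(tree, supports = supports))
}
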