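#' Spearman rank-correlation distance
#'
#' Distance between two cytological profiles: \code{d = 1 - rho} with rho the
#' Spearman rank correlation (average ranks for ties), so \code{d} ranges
#' from 0 (identical rankings) to 2 (exactly reversed rankings). The
#' \code{"half"} scale divides by two for tools that normalise correlation
#' distances to [0, 1].
#'
#' @param x,y Numeric vectors of equal length >= 3 (profile values over the
#'   shared parameter index).
#' @param scale \code{"one_minus_rho"} (default) or \code{"half"}.
#' @return A single distance value.
#' @export
spearman_distance <- function(x, y, scale = c("one_minus_rho", "half")) {
  scale <- match.arg(scale)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("need at least 3 shared parameters")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance: Spearman correlation undefined")
  d <- 1 - stats::cor(x, y, method = "spearman")
  if (scale == "half") d <- d / 2
  d
}

#' Pairwise Spearman distance matrix over profiles
#'
#' @param profiles Profile matrix (samples x parameters).
#' @inheritParams spearman_distance
#' @return Symmetric matrix with zero diagonal; entries in [0, 2] (or [0, 1]
#'   on the \code{"half"} scale).
#' @export
profile_distance_matrix <- function(profiles,
                                    scale = c("one_minus_rho", "half")) {
  scale <- match.arg(scale)
  if (ncol(profiles) < 3L) stop("need at least 3 parameters")
  rk <- t(apply(profiles, 1L, rank))
  rv <- apply(rk, 1L, stats::var)
  if (any(rv == 0))
    stop("zero rank variance for sample(s): ",
         paste(rownames(profiles)[rv == 0], collapse = ", "))
  d <- 1 - stats::cor(t(rk))   # Pearson on ranks == Spearman with tie averaging
  if (scale == "half") d <- d / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance must be a square matrix or dist object")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- as.character(seq_len(nrow(d)))
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates the samples of a distance matrix bottom-up with the complete
#' (maximum) linkage rule: the distance between two clusters is the largest
#' pairwise distance between their members. When several cluster pairs tie
#' for the minimum distance, the pair whose (smallest-leaf-index, other
#' smallest-leaf-index) key is lexicographically smallest is merged, so the
#' tree is fully deterministic and invariant to input order up to leaf
#' relabelling.
#'
#' @param d Symmetric distance matrix (or \code{dist}) with >= 2 samples.
#' @return An object of class \code{cluster_tree}: list with \code{merge}
#'   (hclust-style n-1 x 2 matrix, negative entries are leaves),
#'   \code{height} (non-decreasing merge heights), \code{labels} and
#'   \code{method}.
#' @export
complete_linkage <- function(d) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples")
  labels <- rownames(D)

  W <- D
  diag(W) <- Inf
  active <- rep(TRUE, n)
  minleaf <- seq_len(n)          # smallest original leaf index per slot
  node_id <- -seq_len(n)         # hclust coding: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (k in seq_len(n - 1L)) {
    m <- min(W[active, active])
    cand <- which(W == m & upper.tri(W), arr.ind = TRUE)
    cand <- cand[active[cand[, 1L]] & active[cand[, 2L]], , drop = FALSE]
    # tie-break on sorted smallest-leaf keys
    key1 <- pmin(minleaf[cand[, 1L]], minleaf[cand[, 2L]])
    key2 <- pmax(minleaf[cand[, 1L]], minleaf[cand[, 2L]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    pair <- sort(c(node_id[i], node_id[j]))
    merge[k, ] <- pair
    height[k] <- m

    upd <- pmax(W[i, ], W[j, ])
    W[i, ] <- upd; W[, i] <- upd
    W[i, i] <- Inf
    W[j, ] <- Inf; W[, j] <- Inf
    active[j] <- FALSE
    minleaf[i] <- min(minleaf[i], minleaf[j])
    node_id[i] <- k
  }

  structure(list(merge = merge, height = height, labels = labels,
                 method = "complete", dist.method = "spearman"),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("Complete-linkage cluster tree: ", length(x$labels), " leaves, ",
      length(x$height), " merges, heights [",
      sprintf("%.3g", min(x$height)), ", ",
      sprintf("%.3g", max(x$height)), "]\n", sep = "")
  invisible(x)
}

#' Convert a cluster tree to \code{hclust} / Newick
#'
#' \code{as.hclust} enables the standard dendrogram toolbox;
#' \code{write_dendrogram_newick} exports a Newick string with merge heights
#' as branch lengths.
#'
#' @param x A \code{cluster_tree}.
#' @param ... Unused.
#' @return An \code{hclust} object, or (invisibly) the output path.
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  n <- length(x$labels)
  structure(list(merge = x$merge, height = x$height,
                 order = tree_leaf_order(x$merge, n),
                 labels = x$labels, method = x$method,
                 dist.method = x$dist.method, call = match.call()),
            class = "hclust")
}

tree_leaf_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(n - 1L)
}

#' @rdname as.hclust.cluster_tree
#' @param tree A \code{cluster_tree}.
#' @param path Output file path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cut a cluster tree at a distance threshold
#'
#' Flat clusters are the leaf groups connected by merges with height
#' \code{<= threshold}; everything joining above the threshold stays
#' separate. With complete linkage every pair inside a flat cluster is
#' within the cophenetic threshold, matching the "fell within a distance
#' threshold" reading of cluster membership.
#'
#' @param tree A \code{cluster_tree}.
#' @param threshold Positive cut height (the published analysis used 0.7).
#' @return Named integer vector of cluster ids (numbered by first leaf
#'   appearance), one per leaf.
#' @export
cut_tree <- function(tree, threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric")
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(tree$labels)
  grp <- seq_len(n)
  members <- vector("list", n - 1L)
  for (k in seq_len(max(n - 1L, 0L))) {
    get_leaves <- function(node)
      if (node < 0L) -node else members[[node]]
    lv <- c(get_leaves(tree$merge[k, 1L]), get_leaves(tree$merge[k, 2L]))
    members[[k]] <- lv
    if (tree$height[k] <= threshold) grp[lv] <- n + k
  }
  ids <- match(grp, grp[!duplicated(grp)])
  stats::setNames(as.integer(ids), tree$labels)
}

#' Reference compounds co-clustering with venom samples
#'
#' Given a flat clustering, returns every reference compound that shares a
#' cluster with at least one venom sample, together with the matching venom
#' id(s). This membership step precedes any pathway annotation of the
#' references.
#'
#' @param clusters Named integer vector from \code{\link{cut_tree}}.
#' @param venom_ids,reference_ids Disjoint subsets of the clustered leaves.
#' @return Object of class \code{cocluster_result}: list with
#'   \code{references} (sorted), \code{pairs} (data frame reference_id /
#'   venom_id), \code{by_venom} (named list) and the \code{clusters} vector.
#' @export
coclustered_references <- function(clusters, venom_ids, reference_ids) {
  leaves <- names(clusters)
  if (length(intersect(venom_ids, reference_ids)) > 0L)
    stop("venom_ids and reference_ids must be disjoint")
  if (!all(venom_ids %in% leaves))
    stop("venom id(s) not among clustered samples: ",
         paste(setdiff(venom_ids, leaves), collapse = ", "))
  if (!all(reference_ids %in% leaves))
    stop("reference id(s) not among clustered samples: ",
         paste(setdiff(reference_ids, leaves), collapse = ", "))

  pairs <- data.frame(reference_id = character(0), venom_id = character(0),
                      stringsAsFactors = FALSE)
  for (v in sort(venom_ids)) {
    mates <- intersect(leaves[clusters == clusters[[v]]], reference_ids)
    if (length(mates) > 0L)
      pairs <- rbind(pairs, data.frame(reference_id = sort(mates),
                                       venom_id = v,
                                       stringsAsFactors = FALSE))
  }
  finish_cocluster(pairs, clusters)
}

#' Pairwise-distance co-clustering mode
#'
#' Alternative membership rule: a reference co-clusters with a venom sample
#' when their pairwise profile distance is at most \code{cut}, with no
#' dendrogram involved. Unlike a flat partition, this allows the reference
#' sets of two venoms to overlap partially.
#'
#' @param d Distance matrix over all samples.
#' @param venom_ids,reference_ids Disjoint subsets of the samples.
#' @param cut Distance threshold (default 0.7).
#' @return A \code{cocluster_result} (see
#'   \code{\link{coclustered_references}}).
#' @export
coclustered_references_pairwise <- function(d, venom_ids, reference_ids,
                                            cut = 0.7) {
  D <- as_dist_matrix(d)
  leaves <- rownames(D)
  if (length(intersect(venom_ids, reference_ids)) > 0L)
    stop("venom_ids and reference_ids must be disjoint")
  if (!all(c(venom_ids, reference_ids) %in% leaves))
    stop("ids not among samples in the distance matrix")
  pairs <- data.frame(reference_id = character(0), venom_id = character(0),
                      stringsAsFactors = FALSE)
  for (v in sort(venom_ids)) {
    mates <- reference_ids[D[v, reference_ids] <= cut]
    if (length(mates) > 0L)
      pairs <- rbind(pairs, data.frame(reference_id = sort(mates),
                                       venom_id = v,
                                       stringsAsFactors = FALSE))
  }
  finish_cocluster(pairs, clusters = NULL)
}

finish_cocluster <- function(pairs, clusters) {
  by_venom <- lapply(split(pairs$reference_id, pairs$venom_id), sort)
  structure(list(references = sort(unique(pairs$reference_id)),
                 pairs = pairs, by_venom = by_venom, clusters = clusters),
            class = "cocluster_result")
}

#' @export
print.cocluster_result <- function(x, ...) {
  cat("Co-clustered reference compounds: ", length(x$references),
      " across ", length(x$by_venom), " venom sample(s)\n", sep = "")
  for (v in names(x$by_venom))
    cat("  ", v, ": ", length(x$by_venom[[v]]), " reference(s)\n", sep = "")
  invisible(x)
}
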