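# Agglomerative clustering of feature vectors with optimal leaf ordering.

#' Hierarchical clustering with optimal leaf ordering
#'
#' Agglomerative clustering under Euclidean distance with average (UPGMA) or
#' McQuitty (WPGMA) linkage — the two linkages used for the phospho/
#' transcript correlation analyses — followed by leaf ordering that
#' maximizes the similarity of adjacent leaves. Ordering is exact
#' (Bar-Joseph style dynamic programming over all orderings consistent with
#' the tree) up to `max_exact` leaves and falls back to the tree's native
#' order above that, with a message.
#'
#' @param x what to cluster: a `correlation_matrix` (rows of correlation
#'   vectors), an [new_omics_matrix()] (feature rows), or a plain numeric
#'   matrix of feature vectors.
#' @param linkage `"average"` (UPGMA) or `"mcquitty"` (WPGMA).
#' @param order `"optimal"` or `"none"` (native hclust order).
#' @param max_exact largest leaf count for exact ordering (the dynamic
#'   program is cubic-to-quartic in the leaf count).
#' @return An `msipk_dendrogram`: the underlying `hclust` (with the chosen
#'   leaf order), `merge_heights`, `leaf_order`, `labels`, `linkage`.
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "mcquitty"),
                                 order = c("optimal", "none"),
                                 max_exact = 40) {
  linkage <- match.arg(linkage)
  order <- match.arg(order)
  feats <- if (inherits(x, "correlation_matrix")) x$r
  else if (inherits(x, "omics_matrix")) x$values
  else {
    assert_that(is.matrix(x), "`x` must be a matrix-like object")
    x
  }
  assert_that(nrow(feats) >= 2, "need at least 2 features to cluster")
  if (is.null(rownames(feats))) {
    rownames(feats) <- sprintf("f%d", seq_len(nrow(feats)))
  }
  d <- stats::dist(feats, method = "euclidean")
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- unique(rownames(dm)[which(is.na(dm), arr.ind = TRUE)[, 1]])
    abort_msipk(sprintf("NaN distances involving feature(s): %s",
                        paste(utils::head(bad, 5), collapse = ", ")),
                "msipk_invalid_argument")
  }
  hc <- stats::hclust(d, method = linkage)
  if (order == "optimal") {
    if (nrow(feats) <= max_exact) {
      hc$order <- optimal_leaf_order(hc, as.matrix(d))
    } else {
      message(sprintf(
        "%d leaves exceed max_exact = %d; keeping native leaf order",
        nrow(feats), max_exact))
    }
  }
  structure(list(
    hclust = hc,
    merge_heights = hc$height,
    leaf_order = hc$order,
    labels = hc$labels,
    linkage = linkage
  ), class = "msipk_dendrogram")
}

# Exact optimal leaf ordering: for every subtree, a table M[i, j] holds the
# minimum summed adjacent-leaf distance of any ordering consistent with the
# tree that starts at leaf i and ends at leaf j (i and j necessarily lie in
# different children). Parent tables combine child tables through a min-plus
# step over the boundary pair; fine at fixture scale (O(n^3)-ish).
optimal_leaf_order <- function(hc, D) {
  n <- length(hc$order)
  nodes <- vector("list", nrow(hc$merge))
  leaf_node <- function(i) {
    M <- matrix(0, 1, 1, dimnames = list(as.character(i), as.character(i)))
    list(leaves = i, M = M, K = NULL, L = NULL,
         left_leaves = NULL, right_leaves = NULL)
  }
  get_node <- function(ref) if (ref < 0) leaf_node(-ref) else nodes[[ref]]

  for (v in seq_len(nrow(hc$merge))) {
    Lc <- get_node(hc$merge[v, 1])
    Rc <- get_node(hc$merge[v, 2])
    ll <- Lc$leaves; rl <- Rc$leaves
    leaves <- c(ll, rl)
    nm <- as.character(leaves)
    M <- matrix(Inf, length(leaves), length(leaves),
                dimnames = list(nm, nm))
    K <- matrix(NA_integer_, length(leaves), length(leaves),
                dimnames = list(nm, nm))
    Lb <- K
    for (i in as.character(ll)) for (j in as.character(rl)) {
      # path: i ... k | l ... j with k in left child, l in right child
      best <- Inf; bk <- NA_integer_; bl <- NA_integer_
      for (k in as.character(ll)) {
        cl <- Lc$M[i, k]
        if (!is.finite(cl)) next
        for (l in as.character(rl)) {
          cr <- Rc$M[l, j]
          if (!is.finite(cr)) next
          cost <- cl + D[as.integer(k), as.integer(l)] + cr
          if (cost < best) {
            best <- cost; bk <- as.integer(k); bl <- as.integer(l)
          }
        }
      }
      M[i, j] <- best
      M[j, i] <- best  # reversed path has identical cost
      K[i, j] <- bk; Lb[i, j] <- bl
      K[j, i] <- bk; Lb[j, i] <- bl
    }
    nodes[[v]] <- list(leaves = leaves, M = M, K = K, L = Lb,
                       left = Lc, right = Rc,
                       left_leaves = ll, right_leaves = rl)
  }

  root <- nodes[[nrow(hc$merge)]]
  idx <- which(root$M == min(root$M), arr.ind = TRUE)[1, ]
  start <- root$leaves[idx[1]]; end <- root$leaves[idx[2]]

  reconstruct <- function(node, i, j) {
    if (length(node$leaves) == 1) return(node$leaves)
    ni <- as.character(i); nj <- as.character(j)
    k <- node$K[ni, nj]; l <- node$L[ni, nj]
    i_left <- i %in% node$left_leaves
    if (i_left) {
      c(reconstruct(node$left, i, k), reconstruct(node$right, l, j))
    } else {
      # the stored choice is for the (left-start, right-end) orientation;
      # reverse it for a right-start path
      rev(c(reconstruct(node$left, j, k), reconstruct(node$right, l, i)))
    }
  }
  reconstruct(root, start, end)
}

#' @export
print.msipk_dendrogram <- function(x, ...) {
  cat(sprintf("<msipk_dendrogram> %d leaves, %s linkage\n",
              length(x$leaf_order), x$linkage))
  invisible(x)
}

#' @export
as.hclust.msipk_dendrogram <- function(x, ...) x$hclust

#' Cut a dendrogram into k modules
#' @param dend an [hierarchical_cluster()] result.
#' @param k number of modules.
#' @return Named integer vector of module labels.
#' @export
cut_modules <- function(dend, k) {
  assert_that(inherits(dend, "msipk_dendrogram"),
              "`dend` must come from hierarchical_cluster()")
  stats::cutree(dend$hclust, k = k)
}

#' Export a dendrogram as Newick
#' @param dend an [hierarchical_cluster()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

# Summed distance between adjacent leaves for a given order (lower = more
# similar neighbours); used to score leaf orderings.
adjacent_path_cost <- function(D, order) {
  sum(D[cbind(order[-length(order)], order[-1])])
}
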