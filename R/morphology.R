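#' Dotprops: a point cloud with local tangent vectors
#'
#' The substrate of NBLAST-style morphological comparison: each skeleton node
#' becomes a point with a unit tangent fitted by PCA over its k nearest
#' nodes, plus a colinearity weight alpha = lambda1 / (lambda1 + lambda2 +
#' lambda3) in \[0, 1\].
#'
#' @param skel a \code{skeleton} (typically pruned and resampled first).
#' @param k number of nearest nodes (including the node itself) used for the
#'   local PCA; clamped to the node count. Default 5, the common choice for
#'   micrometre-scale resampled neurons.
#' @return an object of class \code{dotprops}: list with \code{neuron_id},
#'   \code{points} (N x 3), \code{tangents} (N x 3, unit rows), \code{alpha}.
#' @export
make_dotprops <- function(skel, k = 5) {
  validate_skeleton(skel)
  pts <- skeleton_xyz(skel)
  n <- nrow(pts)
  if (n == 0) abort("skeleton has no nodes", "argument_error")
  k <- min(as.integer(k), n)
  tangents <- matrix(0, n, 3)
  alpha <- numeric(n)
  if (n == 1 || k == 1) {
    tangents[, 1] <- 1
    alpha[] <- 1
  } else {
    d2 <- as.matrix(stats::dist(pts))^2
    for (i in seq_len(n)) {
      nb <- order(d2[i, ])[seq_len(k)]
      p <- pts[nb, , drop = FALSE]
      p <- sweep(p, 2, colMeans(p))
      ev <- eigen(crossprod(p), symmetric = TRUE)
      lam <- pmax(ev$values, 0)
      if (sum(lam) < .Machine$double.eps) { # coincident points: degenerate
        tangents[i, ] <- c(1, 0, 0)
        alpha[i] <- 1
      } else {
        v <- ev$vectors[, 1]
        tangents[i, ] <- v / sqrt(sum(v^2))
        alpha[i] <- lam[1] / sum(lam)
      }
    }
  }
  # canonical sign: first component with |.| > tol made positive
  for (i in seq_len(n)) {
    v <- tangents[i, ]
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) tangents[i, ] <- -v
  }
  structure(list(neuron_id = skel$neuron_id, points = pts,
                 tangents = tangents, alpha = alpha),
            class = "dotprops")
}

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf("<dotprops> %s: %d points, mean alpha %.3f\n",
              x$neuron_id, nrow(x$points), mean(x$alpha)))
  invisible(x)
}

#' Default NBLAST scoring function
#'
#' Parametric stand-in for the published data-trained score matrix:
#' each matched point pair contributes \code{exp(-d / sigma) * |u . v|},
#' rewarding close, parallel segments. \code{sigma} sets the distance scale
#' in micrometres.
#'
#' @param sigma distance decay constant in micrometres (default 3).
#' @return a function of (distance vector, |tangent dot| vector).
#' @export
nblast_score_fn <- function(sigma = 3) {
  force(sigma)
  function(dist, absdot) exp(-dist / sigma) * absdot
}

#' Raw NBLAST score of a query against a target
#'
#' For every query point, the single nearest target point is found (k-d
#' tree); the raw score is the sum of \code{score_fn(distance,
#' |tangent dot product|)} over query points. Asymmetric by construction.
#'
#' @param query,target \code{dotprops} objects.
#' @param score_fn scoring function as from \code{\link{nblast_score_fn}}.
#' @return a single raw score.
#' @export
nblast_raw <- function(query, target, score_fn = nblast_score_fn()) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  nn <- cpp_nn1(query$points, target$points)
  absdot <- abs(rowSums(query$tangents * target$tangents[nn$idx, , drop = FALSE]))
  sum(score_fn(nn$dist, absdot))
}

#' All-by-all normalized NBLAST similarity matrix
#'
#' Mean of the forward and reverse self-score-normalized raw scores:
#' \code{S_ij = (raw(i,j)/raw(i,i) + raw(j,i)/raw(j,j)) / 2}, diagonal 1.
#'
#' @param neurons list of \code{dotprops}.
#' @param score_fn scoring function.
#' @return a \code{similarity_matrix} (symmetric, unit diagonal).
#' @export
nblast_matrix <- function(neurons, score_fn = nblast_score_fn()) {
  n <- length(neurons)
  if (n < 2) abort("need at least 2 neurons", "argument_error")
  ids <- vapply(neurons, function(d) d$neuron_id, "")
  if (anyDuplicated(ids)) abort("duplicate neuron ids", "argument_error")
  self <- vapply(neurons, function(d) nblast_raw(d, d, score_fn), 1)
  if (any(self <= 0)) abort("neuron with non-positive self score", "argument_error")
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    raw[i, j] <- if (i == j) self[i] else nblast_raw(neurons[[i]], neurons[[j]], score_fn)
  }
  norm <- raw / self # row-normalize by query self-score
  s <- (norm + t(norm)) / 2
  diag(s) <- 1
  similarity_matrix(s, ids)
}

#' Similarity matrix container
#'
#' @param values square numeric matrix, symmetric within 1e-9, diagonal 1.
#' @param ids neuron ids for rows/columns.
#' @return the matrix with dimnames set and class \code{similarity_matrix}.
#' @export
similarity_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  if (max(abs(values - t(values))) > 1e-9)
    abort("similarity matrix not symmetric", "argument_error")
  if (max(abs(diag(values) - 1)) > 1e-9)
    abort("similarity matrix diagonal must be 1", "argument_error")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  class(values) <- c("similarity_matrix", "matrix")
  values
}

#' Ward hierarchical clustering of a similarity matrix
#'
#' Clusters on the distance \code{d = 1 - S} with Ward's minimum-variance
#' criterion (the \code{ward.D2} update, i.e. the Lance-Williams recurrence
#' on squared distances). Merge heights are non-decreasing.
#'
#' @param sim a \code{similarity_matrix}.
#' @return a \code{cluster_result}: list with \code{ids} and the
#'   \code{hclust} linkage.
#' @export
ward_cluster <- function(sim) {
  if (!inherits(sim, "similarity_matrix"))
    sim <- similarity_matrix(sim)
  d <- as.dist(1 - unclass(sim))
  hc <- stats::hclust(d, method = "ward.D2")
  structure(list(ids = rownames(sim), hclust = hc), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d items, top merge height %.4g\n",
              length(x$ids), max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram into flat clusters
#'
#' Exactly one of \code{height} or \code{k} must be given. Cutting at height
#' h keeps merges with height strictly below h (so duplicates merged at 0
#' stay together for any h > 0).
#'
#' @param result a \code{cluster_result}.
#' @param height cut height.
#' @param k desired number of clusters.
#' @return named integer vector of cluster labels, names = ids.
#' @export
cut_clusters <- function(result, height = NULL, k = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(height) == is.null(k))
    abort("give exactly one of height or k", "argument_error")
  n <- length(result$ids)
  if (!is.null(k)) {
    if (k > n) abort("k larger than number of items", "argument_error")
    labels <- cutree(result$hclust, k = k)
  } else {
    kk <- n - sum(result$hclust$height < height)
    labels <- cutree(result$hclust, k = kk)
  }
  names(labels) <- result$ids
  labels
}

#' Export a dendrogram as a Newick tree
#'
#' Merge heights become branch lengths (ultrametric tree).
#'
#' @param result a \code{cluster_result}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  hc <- result$hclust
  hc$labels <- result$ids
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
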