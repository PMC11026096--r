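#' Build postsynaptic connectivity profiles
#'
#' Rows are focal (BMN) neurons, columns their non-BMN postsynaptic
#' partners, cells the synapse count of the edge. Edges onto any BMN
#' (focal-to-focal in the broad sense) are dropped before thresholding;
#' edges below the synapse threshold are zeroed. Rows left all-zero are
#' excluded from clustering and recorded in attribute \code{"excluded"}.
#'
#' The threshold is applied per edge by default; \code{per_column_total =
#' TRUE} instead drops whole partner columns whose total input is below the
#' threshold (the alternative reading of "partners with fewer than six
#' synapses").
#'
#' @param edges an \code{edge_list} (cleft-filtered upstream).
#' @param ann annotation table covering the focal neurons.
#' @param focal_types type labels whose neurons form the rows.
#' @param edge_min synapse threshold (>= 1). Presets used in the analyses:
#'   3 (low, InOm-like pass), 7 (main pass), 6 (figure variant).
#' @param bmn_types all BMN type labels; edges onto these neurons are
#'   excluded. Defaults to \code{focal_types}.
#' @param per_column_total apply the threshold to partner column totals
#'   instead of single edges.
#' @return object of class \code{connectivity_profile}: list with
#'   \code{weights} (rows focal, columns partners), \code{excluded} ids,
#'   and the parameters used.
#' @export
build_profiles <- function(edges, ann, focal_types, edge_min,
                           bmn_types = focal_types, per_column_total = FALSE) {
  ann <- as_annotation_table(ann)
  stopifnot(edge_min >= 1)
  if (!length(focal_types)) abort("empty focal type set", "argument_error")
  focal_ids <- ann$neuron_id[ann$type %in% focal_types]
  if (!length(focal_ids)) abort("no neurons of the focal types", "argument_error")
  bmn_ids <- ann$neuron_id[ann$type %in% bmn_types]
  e <- edges[edges$pre_id %in% focal_ids & !(edges$post_id %in% bmn_ids), , drop = FALSE]
  if (per_column_total && nrow(e)) {
    tot <- tapply(e$count, e$post_id, sum)
    e <- e[tot[e$post_id] >= edge_min, , drop = FALSE]
  } else {
    e <- e[e$count >= edge_min, , drop = FALSE]
  }
  partners <- sort(unique(e$post_id))
  w <- matrix(0, length(focal_ids), length(partners),
              dimnames = list(sort(focal_ids), partners))
  if (nrow(e)) w[cbind(match(e$pre_id, rownames(w)), match(e$post_id, partners))] <- e$count
  zero <- rowSums(w) == 0
  structure(list(weights = w[!zero, , drop = FALSE],
                 excluded = rownames(w)[zero],
                 edge_min = edge_min,
                 per_column_total = per_column_total),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf("<connectivity_profile> %d neurons x %d partners (threshold %d%s, %d excluded)\n",
              nrow(x$weights), ncol(x$weights), x$edge_min,
              if (x$per_column_total) ", column-total" else "", length(x$excluded)))
  invisible(x)
}

#' Cosine similarity of connectivity profiles
#'
#' \code{S_ij = w_i . w_j / (|w_i| |w_j|)}; with non-negative synapse counts
#' all values lie in \[0, 1\]. Rows must have been zero-excluded upstream.
#'
#' @param profile a \code{connectivity_profile}.
#' @return a \code{similarity_matrix}.
#' @export
cosine_matrix <- function(profile) {
  stopifnot(inherits(profile, "connectivity_profile"))
  w <- profile$weights
  if (nrow(w) < 2) abort("need at least 2 non-excluded rows", "argument_error")
  nrm <- row_norms(w)
  if (any(nrm == 0)) abort("zero-norm row reached cosine_matrix", "internal_error")
  s <- tcrossprod(w / nrm)
  s[s > 1] <- 1
  diag(s) <- 1
  similarity_matrix(s, rownames(w))
}

#' Ward clustering of a connectivity similarity matrix
#'
#' Convenience wrapper: Ward linkage on \code{1 - S} followed by a flat cut.
#'
#' @param sim a \code{similarity_matrix}.
#' @param height,k cut specification, exactly one given.
#' @return list with the \code{cluster_result} (\code{$tree}) and flat
#'   \code{$labels}.
#' @export
cluster_connectivity <- function(sim, height = NULL, k = NULL) {
  tree <- ward_cluster(sim)
  list(tree = tree, labels = cut_clusters(tree, height = height, k = k))
}

#' Cluster composition by neuron type
#'
#' For every (type, cluster) pair, the count and fraction of that type's
#' clustered neurons falling in the cluster; fractions below
#' \code{min_fraction} are flagged minor (the "at least 20%" reporting
#' rule). The per-cluster type makeup is attached as attribute
#' \code{"cluster_makeup"}.
#'
#' @param labels named cluster labels (names = neuron ids).
#' @param ann annotation table covering all labelled neurons.
#' @param min_fraction reporting threshold (default 0.20).
#' @return data.frame \code{type, cluster, n, fraction, minor}.
#' @export
composition <- function(labels, ann, min_fraction = 0.20) {
  ann <- as_annotation_table(ann)
  ids <- names(labels)
  unk <- setdiff(ids, ann$neuron_id)
  if (length(unk))
    abort(paste("labelled neurons without annotation:", paste(unk, collapse = ", ")),
          "annotation_error")
  type_of <- setNames(ann$type, ann$neuron_id)
  tab <- table(type = type_of[ids], cluster = labels)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  df <- df[df$n > 0, , drop = FALSE]
  per_type <- rowSums(tab)
  df$fraction <- df$n / per_type[df$type]
  df$minor <- df$fraction < min_fraction
  df <- df[order(df$type, df$cluster), , drop = FALSE]
  rownames(df) <- NULL
  makeup <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(makeup)[3] <- "n"
  makeup <- makeup[makeup$n > 0, , drop = FALSE]
  per_cluster <- colSums(tab)
  makeup$fraction_of_cluster <- makeup$n / per_cluster[makeup$cluster]
  rownames(makeup) <- NULL
  attr(df, "cluster_makeup") <- makeup
  df
}
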