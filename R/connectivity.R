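#' Read a synapse table
#'
#' CSV/TSV with header \code{pre_id,post_id,cleft_score,x,y,z}, one row per
#' predicted synapse. Neuron ids are read as character (EM segmentation root
#' ids are 64-bit; strings avoid precision loss).
#'
#' @param path file path; delimiter inferred from extension (.tsv = tab).
#' @return data.frame with the six columns, class \code{synapse_table}.
#' @export
read_synapse_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(pre_id = "character", post_id = "character"),
                          stringsAsFactors = FALSE)
  as_synapse_table(df)
}

#' Coerce a data.frame to a synapse table
#'
#' @param df data.frame with columns \code{pre_id, post_id, cleft_score, x, y, z}.
#' @return validated \code{synapse_table}.
#' @export
as_synapse_table <- function(df) {
  required <- c("pre_id", "post_id", "cleft_score", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste("synapse table missing column(s):", paste(missing, collapse = ", ")),
          "schema_error")
  df$pre_id <- as.character(df$pre_id)
  df$post_id <- as.character(df$post_id)
  if (nrow(df) && (any(df$pre_id == "") || any(df$post_id == "")))
    abort("empty pre_id/post_id", "schema_error")
  if (nrow(df) && any(df$cleft_score < 0))
    abort("negative cleft_score", "schema_error")
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' Filter synapses by cleft score
#'
#' Drops rows with \code{cleft_score} below \code{cleft_min}; the boundary
#' score is kept (scores "below 50" are the unreliable ones). Row order is
#' preserved; the number of removed rows is attached as attribute
#' \code{"removed"}.
#'
#' @param table a \code{synapse_table}.
#' @param cleft_min minimum score kept (default 50).
#' @return filtered \code{synapse_table}.
#' @export
filter_synapses <- function(table, cleft_min = 50) {
  table <- as_synapse_table(table)
  stopifnot(cleft_min >= 0)
  keep <- table$cleft_score >= cleft_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}

#' Per-neuron pre- and postsynaptic connection counts
#'
#' Counts table rows in which each neuron appears as presynaptic or
#' postsynaptic partner (row entries, not distinct presynaptic sites).
#'
#' @param table a cleft-filtered \code{synapse_table}.
#' @param ids neuron ids to count for.
#' @return data.frame \code{neuron_id, pre_count, post_count}.
#' @export
connection_counts <- function(table, ids) {
  table <- as_synapse_table(table)
  ids <- as.character(ids)
  pre <- table(factor(table$pre_id, levels = ids))
  post <- table(factor(table$post_id, levels = ids))
  data.frame(neuron_id = ids, pre_count = as.integer(pre),
             post_count = as.integer(post), stringsAsFactors = FALSE)
}

#' Aggregate a synapse table into a weighted edge list
#'
#' One row per ordered (pre, post) pair with the synapse count; counts sum
#' to the table row count. Autapses (pre == post) are kept and flagged.
#'
#' @param table a cleft-filtered \code{synapse_table}.
#' @return data.frame \code{pre_id, post_id, count, autapse}, class
#'   \code{edge_list}.
#' @export
aggregate_edges <- function(table) {
  table <- as_synapse_table(table)
  if (!nrow(table)) {
    out <- data.frame(pre_id = character(), post_id = character(),
                      count = integer(), autapse = logical())
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(table))),
                            by = list(pre_id = table$pre_id, post_id = table$post_id),
                            FUN = sum)
    agg <- agg[order(agg$pre_id, agg$post_id), , drop = FALSE]
    rownames(agg) <- NULL
    agg$autapse <- agg$pre_id == agg$post_id
    out <- agg
  }
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Type-level connectivity normalized by possible edges
#'
#' \code{M[a, b]} is the summed synaptic weight of edges from type-a neurons
#' to type-b neurons divided by the number of possible directed edges
#' between the groups: \code{n_a * n_b} off-diagonal and
#' \code{n_a * (n_a - 1)} on the diagonal (autapses excluded, and autapse
#' edges dropped from the sums accordingly). A single-neuron type has an
#' undefined diagonal, reported as \code{NA}.
#'
#' @param edges an \code{edge_list}.
#' @param ann an annotation table (see \code{\link{read_annotations}}).
#' @param types type labels defining the matrix; default all types present
#'   among annotated neurons.
#' @return T x T numeric matrix, attribute \code{"possible"} holds P(a, b).
#' @export
type_connectivity <- function(edges, ann, types = NULL) {
  ann <- as_annotation_table(ann)
  if (is.null(types)) types <- sort(unique(ann$type))
  members <- lapply(types, function(t) ann$neuron_id[ann$type == t])
  names(members) <- types
  all_ids <- unlist(members, use.names = FALSE)
  scope <- edges$pre_id %in% all_ids & edges$post_id %in% all_ids
  e <- edges[scope & !edges$autapse, , drop = FALSE]
  unk <- unique(c(setdiff(e$pre_id, ann$neuron_id), setdiff(e$post_id, ann$neuron_id)))
  if (length(unk))
    abort(paste("unannotated endpoints:", paste(unk, collapse = ", ")), "annotation_error")
  type_of <- setNames(ann$type, ann$neuron_id)
  n <- vapply(members, length, 1L)
  tt <- length(types)
  m <- matrix(0, tt, tt, dimnames = list(types, types))
  p <- outer(n, n)
  diag(p) <- n * (n - 1)
  if (nrow(e)) {
    pa <- factor(type_of[e$pre_id], levels = types)
    pb <- factor(type_of[e$post_id], levels = types)
    sums <- tapply(e$count, list(pa, pb), sum, default = 0)
    m <- m + sums
  }
  m <- ifelse(p > 0, m / p, NA_real_)
  dimnames(m) <- list(types, types)
  attr(m, "possible") <- p
  m
}

#' Read a neuron annotation table
#'
#' CSV with header \code{neuron_id,type,nerve,side} and optional bristle
#' coordinates \code{bx,by}.
#'
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          colClasses = c(neuron_id = "character"),
                          stringsAsFactors = FALSE)
  as_annotation_table(df)
}

#' Coerce to annotation table
#' @param df data.frame with at least \code{neuron_id, type}; optional
#'   \code{nerve, side, bx, by}.
#' @return validated annotation data.frame, class \code{annotation_table}.
#' @export
as_annotation_table <- function(df) {
  if (inherits(df, "annotation_table")) return(df)
  missing <- setdiff(c("neuron_id", "type"), names(df))
  if (length(missing))
    abort(paste("annotation table missing column(s):", paste(missing, collapse = ", ")),
          "schema_error")
  df$neuron_id <- as.character(df$neuron_id)
  if (anyDuplicated(df$neuron_id)) abort("duplicate neuron_id", "schema_error")
  if (any(df$type == "")) abort("empty type label", "schema_error")
  class(df) <- c("annotation_table", "data.frame")
  df
}
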