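#' Assign postsynaptic partners to their dominant presynaptic type
#'
#' For every non-BMN partner receiving input from the focal (BMN) types, the
#' input is summed by type and the partner is assigned to the type giving
#' the highest input (so a partner dominated by, say, antennal-bristle
#' neurons joins the "Ant" partner group). Ties go to the lexicographically
#' smallest type label and are flagged. Partners with zero BMN input are
#' absent from the result.
#'
#' @param edges a cleft-filtered \code{edge_list}.
#' @param ann annotation table covering the focal neurons.
#' @param bmn_types focal type labels; default all types in \code{ann}.
#' @return data.frame \code{partner_id, assigned_type, input, tie}; the full
#'   partner-by-type input matrix is attribute \code{"input_by_type"}.
#' @export
assign_partners <- function(edges, ann, bmn_types = NULL) {
  ann <- as_annotation_table(ann)
  if (is.null(bmn_types)) bmn_types <- sort(unique(ann$type))
  bmn_ids <- ann$neuron_id[ann$type %in% bmn_types]
  type_of <- setNames(ann$type, ann$neuron_id)
  e <- edges[edges$pre_id %in% bmn_ids & !(edges$post_id %in% bmn_ids), , drop = FALSE]
  if (!nrow(e)) {
    out <- data.frame(partner_id = character(), assigned_type = character(),
                      input = numeric(), tie = logical())
    attr(out, "input_by_type") <- matrix(0, 0, length(bmn_types),
                                         dimnames = list(NULL, sort(bmn_types)))
    return(out)
  }
  types <- sort(unique(bmn_types))
  inp <- tapply(e$count,
                list(partner = e$post_id, type = factor(type_of[e$pre_id], levels = types)),
                sum, default = 0)
  assigned <- apply(inp, 1, function(r) colnames(inp)[which.max(r)]) # ties: first = smallest label
  best <- apply(inp, 1, max)
  tie <- apply(inp, 1, function(r) sum(r == max(r)) > 1)
  out <- data.frame(partner_id = rownames(inp), assigned_type = assigned,
                    input = best, tie = tie, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$partner_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "input_by_type") <- inp
  out
}

#' Build the thresholded type-to-partner-group graph
#'
#' Edge weight from type a to partner group g is the summed synapse count
#' from type-a neurons onto partners assigned to g; the fraction normalizes
#' by type a's total output onto assigned partners. Edges with fraction
#' <= \code{fraction_min} are dropped (strictly greater than 5% retained,
#' by default).
#'
#' @param edges a cleft-filtered \code{edge_list}.
#' @param assignment result of \code{\link{assign_partners}}.
#' @param ann annotation table covering the focal neurons.
#' @param bmn_types focal type labels; default all types in \code{ann}.
#' @param fraction_min output-fraction threshold in \[0, 1) (default 0.05).
#' @return data.frame \code{type, partner_group, weight, fraction}, class
#'   \code{type_partner_graph}; per-type totals in attribute
#'   \code{"type_totals"}, dropped edges in attribute \code{"dropped"}.
#' @export
build_graph <- function(edges, assignment, ann, bmn_types = NULL, fraction_min = 0.05) {
  ann <- as_annotation_table(ann)
  if (fraction_min < 0 || fraction_min >= 1)
    abort("fraction_min must be in [0, 1)", "argument_error")
  if (is.null(bmn_types)) bmn_types <- sort(unique(ann$type))
  bmn_ids <- ann$neuron_id[ann$type %in% bmn_types]
  type_of <- setNames(ann$type, ann$neuron_id)
  group_of <- setNames(assignment$assigned_type, assignment$partner_id)
  e <- edges[edges$pre_id %in% bmn_ids & edges$post_id %in% assignment$partner_id, ,
             drop = FALSE]
  types <- sort(unique(bmn_types))
  if (nrow(e)) {
    w <- tapply(e$count,
                list(type = factor(type_of[e$pre_id], levels = types),
                     group = factor(group_of[e$post_id], levels = types)),
                sum, default = 0)
  } else {
    w <- matrix(0, length(types), length(types), dimnames = list(types, types))
  }
  totals <- rowSums(w)
  df <- data.frame(type = rep(rownames(w), ncol(w)),
                   partner_group = rep(colnames(w), each = nrow(w)),
                   weight = as.vector(w), stringsAsFactors = FALSE)
  df <- df[df$weight > 0, , drop = FALSE]
  df$fraction <- df$weight / totals[df$type]
  keep <- df$fraction > fraction_min
  dropped <- df[!keep, , drop = FALSE]
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$type, df$partner_group), , drop = FALSE]
  rownames(df) <- rownames(dropped) <- NULL
  class(df) <- c("type_partner_graph", "data.frame")
  attr(df, "type_totals") <- totals
  attr(df, "dropped") <- dropped
  df
}

#' Export a type-partner graph to GraphML
#'
#' @param graph a \code{type_partner_graph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "type_partner_graph"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$type, to = paste0(graph$partner_group, "_post"),
               weight = graph$weight, fraction = graph$fraction))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
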