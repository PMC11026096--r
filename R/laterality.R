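#' Classify a neuron as midline-crossing
#'
#' The midline is a plane of constant x (the mediolateral axis in a
#' symmetric brain space). A neuron is midline-crossing when any skeleton
#' node lies strictly on the contralateral side of the midline relative to
#' its side of origin; a node exactly on the midline does not count. The
#' convention is left = x < midline, right = x > midline. The excursion is
#' the maximum distance past the midline (0 when not crossing), a
#' diagnostic only — it plays no part in the classification.
#'
#' @param skel a \code{skeleton} (unpruned: the rule is over all nodes).
#' @param midline_x midline coordinate in micrometres (default 0).
#' @param origin_side \code{"left"} or \code{"right"}.
#' @return list with \code{crossing} (logical) and \code{excursion} (um).
#' @export
classify_crossing <- function(skel, midline_x = 0, origin_side) {
  if (missing(origin_side) || !origin_side %in% c("left", "right"))
    abort("origin_side must be \"left\" or \"right\"", "argument_error")
  stopifnot(is.finite(midline_x))
  x <- skel$nodes$x
  signed <- if (origin_side == "left") x - midline_x else midline_x - x
  exc <- max(signed)
  list(crossing = exc > 0, excursion = max(exc, 0))
}

#' Per-type midline-crossing summary
#'
#' @param reports data.frame \code{neuron_id, crossing, excursion_um} (one
#'   row per neuron, as assembled from \code{\link{classify_crossing}}).
#' @param ann annotation table covering all reported neurons.
#' @return data.frame \code{type, n_crossing, n_total, percent} (percent in
#'   0..100).
#' @export
percent_crossing <- function(reports, ann) {
  ann <- as_annotation_table(ann)
  unk <- setdiff(reports$neuron_id, ann$neuron_id)
  if (length(unk))
    abort(paste("unannotated neurons:", paste(unk, collapse = ", ")), "annotation_error")
  type_of <- setNames(ann$type, ann$neuron_id)
  type <- type_of[reports$neuron_id]
  n_total <- tapply(rep(1L, nrow(reports)), type, sum)
  n_cross <- tapply(as.integer(reports$crossing), type, sum)
  out <- data.frame(type = names(n_total),
                    n_crossing = as.integer(n_cross),
                    n_total = as.integer(n_total),
                    percent = 100 * as.integer(n_cross) / as.integer(n_total),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$type), , drop = FALSE]
}

#' Laterality report for a set of skeletons
#'
#' Applies \code{\link{classify_crossing}} to each skeleton using the side
#' recorded in the annotation table and summarizes per type.
#'
#' @param skeletons list of \code{skeleton} objects.
#' @param ann annotation table with a \code{side} column.
#' @param midline_x midline coordinate (default 0).
#' @return list with \code{$neurons} (per-neuron data.frame) and
#'   \code{$types} (per-type summary).
#' @export
laterality_report <- function(skeletons, ann, midline_x = 0) {
  ann <- as_annotation_table(ann)
  if (!"side" %in% names(ann)) abort("annotation table lacks side column", "schema_error")
  side_of <- setNames(ann$side, ann$neuron_id)
  rows <- lapply(skeletons, function(s) {
    side <- side_of[[s$neuron_id]]
    if (is.null(side) || is.na(side))
      abort(paste("no side annotation for", s$neuron_id), "annotation_error")
    r <- classify_crossing(s, midline_x, side)
    data.frame(neuron_id = s$neuron_id, crossing = r$crossing,
               excursion_um = r$excursion, stringsAsFactors = FALSE)
  })
  neurons <- do.call(rbind, rows)
  rownames(neurons) <- NULL
  list(neurons = neurons, types = percent_crossing(neurons, ann))
}
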