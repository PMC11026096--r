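#' Skeleton objects
#'
#' A skeleton is a rooted tree of 3-d nodes, the standard representation of a
#' traced neuron. Nodes carry \code{node_id}, coordinates (micrometres),
#' \code{radius} and \code{parent_id} (\code{-1} for a root). A skeleton is a
#' single connected component unless its \code{fragmented} flag is set (as
#' after region pruning with \code{keep = "all"}).
#'
#' @param neuron_id character scalar identifying the neuron.
#' @param nodes data.frame with columns \code{node_id, x, y, z, radius,
#'   parent_id} (an optional \code{swc_type} column is carried through I/O).
#' @param fragmented logical; allow more than one connected component.
#' @return an object of class \code{skeleton}.
#' @export
skeleton <- function(neuron_id, nodes, fragmented = FALSE) {
  obj <- structure(list(neuron_id = as.character(neuron_id),
                        nodes = as.data.frame(nodes),
                        fragmented = isTRUE(fragmented)),
                   class = "skeleton")
  validate_skeleton(obj)
}

#' Validate a skeleton's tree invariants
#'
#' Checks node-id uniqueness, parent existence, acyclicity, and (unless the
#' skeleton is flagged fragmented) connectedness.
#'
#' @param x a \code{skeleton}.
#' @return \code{x}, invisibly validated (returned unchanged on success).
#' @export
validate_skeleton <- function(x) {
  nodes <- x$nodes
  if (nrow(nodes) < 1) abort("skeleton must have at least one node", "skeleton_invalid")
  required <- c("node_id", "x", "y", "z", "radius", "parent_id")
  missing <- setdiff(required, names(nodes))
  if (length(missing))
    abort(paste("skeleton nodes missing columns:", paste(missing, collapse = ", ")),
          "skeleton_invalid")
  if (anyDuplicated(nodes$node_id))
    abort("duplicate node_id in skeleton", "skeleton_invalid")
  if (any(nodes$radius < 0)) abort("negative radius", "skeleton_invalid")
  is_root <- nodes$parent_id == -1
  dangling <- !is_root & !(nodes$parent_id %in% nodes$node_id)
  if (any(dangling))
    abort(paste0("dangling parent_id for node(s) ",
                 paste(nodes$node_id[dangling], collapse = ", ")),
          "skeleton_invalid")
  if (any(nodes$parent_id == nodes$node_id))
    abort("node is its own parent", "skeleton_invalid")
  # acyclicity + component count by walking parent chains
  parent_of <- match(nodes$parent_id, nodes$node_id) # NA for roots
  n <- nrow(nodes)
  root_of <- integer(n)
  state <- integer(n) # 0 unvisited, else index of resolved root
  for (i in seq_len(n)) {
    path <- integer(0)
    j <- i
    while (state[j] == 0L) {
      if (j %in% path) abort("cycle detected in parent links", "skeleton_invalid")
      path <- c(path, j)
      if (is.na(parent_of[j])) {
        state[path] <- j
        break
      }
      j <- parent_of[j]
    }
    if (state[i] == 0L) state[path] <- state[j]
    root_of[i] <- state[i]
  }
  n_comp <- length(unique(root_of))
  if (n_comp > 1 && !x$fragmented)
    abort(sprintf("skeleton has %d components but is not flagged fragmented", n_comp),
          "skeleton_invalid")
  x
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %s: %d nodes, %d root(s)%s\n", x$neuron_id,
              nrow(x$nodes), sum(x$nodes$parent_id == -1),
              if (x$fragmented) ", fragmented" else ""))
  invisible(x)
}

#' Read a skeleton from an SWC file
#'
#' Standard 7-column whitespace-delimited SWC
#' (\code{id type x y z radius parent}), \code{#} comments allowed.
#' Coordinates are multiplied by \code{units_scale} on input so nm-native
#' files can be brought to micrometres.
#'
#' @param path file path.
#' @param neuron_id identifier for the neuron; default is the file base name.
#' @param units_scale multiplicative factor applied to x, y, z and radius.
#' @return a \code{skeleton}.
#' @export
read_swc <- function(path, neuron_id = sub("\\.swc$", "", basename(path)),
                     units_scale = 1) {
  if (!file.exists(path)) abort(paste("no such file:", path), "io_error")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (!length(data_lines)) abort("SWC file has no data lines", "swc_parse_error")
  fields <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    abort(sprintf("malformed SWC line %d: expected 7 fields", line_no[bad[1]]),
          "swc_parse_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    abort(sprintf("malformed SWC line %d: non-numeric field", line_no[bad]),
          "swc_parse_error")
  }
  nodes <- data.frame(node_id = as.integer(m[, 1]), swc_type = as.integer(m[, 2]),
                      x = m[, 3] * units_scale, y = m[, 4] * units_scale,
                      z = m[, 5] * units_scale, radius = m[, 6] * units_scale,
                      parent_id = as.integer(m[, 7]))
  skeleton(neuron_id, nodes)
}

#' Write a skeleton to an SWC file
#'
#' @param skel a \code{skeleton}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(skel, path) {
  validate_skeleton(skel)
  nodes <- skel$nodes
  swc_type <- if ("swc_type" %in% names(nodes)) nodes$swc_type else rep(0L, nrow(nodes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC written by somamap",
               "# id type x y z radius parent"), con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nodes$node_id, swc_type, nodes$x, nodes$y, nodes$z,
                     nodes$radius, nodes$parent_id), con)
  invisible(path)
}

#' Axis-aligned region box
#'
#' Stand-in for the synapse-rich volume used to prune away the smooth nerve
#' axon: membership is closed (boundary nodes kept).
#'
#' @param min_corner,max_corner numeric length-3, micrometres;
#'   \code{min_corner <= max_corner} componentwise.
#' @return an object of class \code{region_box}.
#' @export
region_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  stopifnot(length(min_corner) == 3, length(max_corner) == 3)
  if (any(min_corner > max_corner))
    abort("region_box: min_corner must be <= max_corner componentwise", "config_error")
  structure(list(min = min_corner, max = max_corner), class = "region_box")
}

#' Bounding box of a set of 3-d points
#'
#' Convenience constructor: the axis-aligned bounding box of (typically) a
#' neuron's own filtered synapse positions, optionally padded. Used by the
#' pipeline to emulate pruning to a synapse mesh.
#'
#' @param xyz matrix or data.frame with 3 columns.
#' @param pad symmetric padding in micrometres added on every side.
#' @return a \code{region_box}.
#' @export
bounding_box <- function(xyz, pad = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  region_box(apply(xyz, 2, min) - pad, apply(xyz, 2, max) + pad)
}

node_in_box <- function(nodes, box) {
  nodes$x >= box$min[1] & nodes$x <= box$max[1] &
    nodes$y >= box$min[2] & nodes$y <= box$max[2] &
    nodes$z >= box$min[3] & nodes$z <= box$max[3]
}

#' Prune a skeleton to an axis-aligned region
#'
#' Keeps exactly the nodes inside the closed box. Surviving nodes whose
#' parent was removed become roots of their fragment (the fragment node
#' closest to the old root along the tree). With \code{keep = "largest"}
#' (default) only the largest fragment is returned; ties go to the fragment
#' containing the smallest node id. With \code{keep = "all"} all fragments
#' are returned and the result is flagged fragmented.
#'
#' @param skel a \code{skeleton}.
#' @param box a \code{region_box}.
#' @param keep \code{"largest"} or \code{"all"}.
#' @return a pruned \code{skeleton}.
#' @export
prune_to_region <- function(skel, box, keep = c("largest", "all")) {
  keep <- match.arg(keep)
  validate_skeleton(skel)
  stopifnot(inherits(box, "region_box"))
  nodes <- skel$nodes
  inside <- node_in_box(nodes, box)
  if (!any(inside))
    abort(sprintf("neuron %s has no nodes inside the region", skel$neuron_id),
          "empty_region_error")
  kept <- nodes[inside, , drop = FALSE]
  # parent links survive only if the parent is kept too
  orphan <- kept$parent_id != -1 & !(kept$parent_id %in% kept$node_id)
  kept$parent_id[orphan] <- -1L
  # fragment = connected component of surviving parent links
  parent_of <- match(kept$parent_id, kept$node_id)
  frag <- integer(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    j <- i
    while (!is.na(parent_of[j]) && frag[j] == 0L) j <- parent_of[j]
    root <- if (frag[j] != 0L) frag[j] else j
    j <- i
    while (frag[j] == 0L) {
      frag[j] <- root
      if (is.na(parent_of[j])) break
      j <- parent_of[j]
    }
  }
  frags <- unique(frag)
  if (keep == "largest" && length(frags) > 1) {
    sizes <- vapply(frags, function(f) sum(frag == f), 1L)
    best <- frags[sizes == max(sizes)]
    if (length(best) > 1) { # deterministic tie-break: smallest node id
      min_ids <- vapply(best, function(f) min(kept$node_id[frag == f]), 1)
      best <- best[which.min(min_ids)]
    } else best <- best[1]
    kept <- kept[frag == best, , drop = FALSE]
    frags <- best
  }
  rownames(kept) <- NULL
  skeleton(skel$neuron_id, kept, fragmented = length(frags) > 1)
}

edge_table <- function(nodes) {
  has_parent <- nodes$parent_id != -1
  child <- which(has_parent)
  parent <- match(nodes$parent_id[has_parent], nodes$node_id)
  data.frame(child = child, parent = parent)
}

#' Total cable length of a skeleton
#'
#' @param skel a \code{skeleton}.
#' @return summed parent-child edge length in micrometres.
#' @export
cable_length <- function(skel) {
  nodes <- skel$nodes
  e <- edge_table(nodes)
  if (!nrow(e)) return(0)
  dx <- nodes$x[e$child] - nodes$x[e$parent]
  dy <- nodes$y[e$child] - nodes$y[e$parent]
  dz <- nodes$z[e$child] - nodes$z[e$parent]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Resample a skeleton to a maximum inter-node spacing
#'
#' Subdivides every parent-child edge longer than \code{step} with linearly
#' interpolated nodes so spacing is at most \code{step}. Existing nodes
#' (branch and end points in particular) are preserved exactly, so total
#' cable length is unchanged. Equalizes point density before dotprops
#' construction so similarity scores are not dominated by densely traced
#' branches.
#'
#' @param skel a \code{skeleton}.
#' @param step maximum spacing in micrometres, > 0.
#' @return a resampled \code{skeleton}.
#' @export
resample_skeleton <- function(skel, step) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    abort("step must be a positive number", "argument_error")
  validate_skeleton(skel)
  nodes <- skel$nodes
  e <- edge_table(nodes)
  next_id <- max(nodes$node_id) + 1L
  new_rows <- list()
  for (k in seq_len(nrow(e))) {
    ci <- e$child[k]; pi <- e$parent[k]
    p0 <- c(nodes$x[pi], nodes$y[pi], nodes$z[pi])
    p1 <- c(nodes$x[ci], nodes$y[ci], nodes$z[ci])
    len <- sqrt(sum((p1 - p0)^2))
    if (len <= step) next
    nseg <- ceiling(len / step)
    t <- seq_len(nseg - 1) / nseg
    ids <- next_id + seq_along(t) - 1L
    next_id <- next_id + length(t)
    r <- nodes$radius[pi] + t * (nodes$radius[ci] - nodes$radius[pi])
    seg <- data.frame(node_id = ids,
                      x = p0[1] + t * (p1[1] - p0[1]),
                      y = p0[2] + t * (p1[2] - p0[2]),
                      z = p0[3] + t * (p1[3] - p0[3]),
                      radius = r,
                      parent_id = c(nodes$node_id[pi], ids[-length(ids)]))
    if ("swc_type" %in% names(nodes)) seg$swc_type <- nodes$swc_type[ci]
    # child now hangs off the last interpolated node
    nodes$parent_id[ci] <- ids[length(ids)]
    new_rows[[length(new_rows) + 1]] <- seg
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    nodes <- rbind(nodes, add[, names(nodes)])
  }
  rownames(nodes) <- NULL
  skeleton(skel$neuron_id, nodes, fragmented = skel$fragmented)
}

#' Node coordinates as a matrix
#' @param skel a \code{skeleton}.
#' @return numeric matrix with columns x, y, z.
#' @export
skeleton_xyz <- function(skel) {
  as.matrix(skel$nodes[, c("x", "y", "z")])
}
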