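#' Default bristle-type roster for the synthetic head
#'
#' Fifteen mechanosensory types named after the head bristle populations
#' they emulate: fourteen small types (4-26 neurons each) and one large
#' eye-bristle-like type ("InOm-like", 60 neurons, scaled down from the
#' hundreds of interommatidial bristle neurons of a real head). Each type
#' carries its nerve group and whether its projections are designated
#' midline-crossing (medial anterior and proboscis types, mirroring the
#' observed laterality logic).
#'
#' @return data.frame \code{label, n, nerve, crossing, inom_like}.
#' @export
default_roster <- function() {
  data.frame(
    label = c("InOc", "Oc", "Fr", "Ant", "Or", "FrOr", "Vib", "MaPa",
              "Taste", "Hau", "Vt", "dOcci", "dPoOr", "vOcci", "InOm"),
    n = c(4L, 4L, 12L, 16L, 12L, 8L, 14L, 8L, 26L, 6L, 8L, 8L, 6L, 10L, 60L),
    nerve = c("AntNv", "AntNv", "AntNv", "AntNv", "AntNv", "AntNv", "EyeNv",
              "LabNv", "LabNv", "LabNv", "OcciNv", "OcciNv", "OcciNv",
              "EyeNv", "EyeNv"),
    crossing = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                 TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    inom_like = c(rep(FALSE, 14), TRUE),
    stringsAsFactors = FALSE
  )
}

# deterministic near-uniform directions on the upper unit hemisphere
# (Fibonacci spiral), one per type
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  el <- asin(i / n)               # elevation in (0, pi/2)
  az <- (2 * pi * i / ((1 + sqrt(5)) / 2)) %% (2 * pi) - pi
  cbind(az = az, el = el)
}

sph_to_unit <- function(az, el) {
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' Great-circle distance between head-surface positions
#' @param a,b two-column matrices (azimuth, elevation) in radians.
#' @return matrix of pairwise angular distances (radians).
#' @export
head_surface_distance <- function(a, b = a) {
  ua <- sph_to_unit(a[, 1], a[, 2])
  ub <- sph_to_unit(b[, 1], b[, 2])
  dot <- pmin(pmax(tcrossprod(ua, ub), -1), 1)
  acos(dot)
}

#' Generate a synthetic head layout
#'
#' Places each type's bristle centroid on the unit hemisphere (deterministic
#' near-uniform spiral), samples per-neuron bristle positions around the
#' centroid, and maps centroids into brain space as projection-zone centers:
#' \code{zone = offset + zone_radius * u}, a map under which inter-zone
#' distance grows monotonically with head-surface distance between type
#' centroids. All zones lie strictly on the right of the midline plane
#' \code{x = 0}. Neighbor types are the k nearest type centroids by
#' great-circle distance.
#'
#' @param roster type roster as from \code{\link{default_roster}}.
#' @param zone_radius radius (um) of the sphere on which zone centers sit;
#'   default 40, giving minimum inter-zone separations well above the
#'   default arbor jitter.
#' @param bristle_spread angular SD (radians) of bristle positions around
#'   their type centroid (default 0.08).
#' @param n_neighbors how many nearest types count as "neighboring"
#'   (default 2; the notion is qualitative in real heads).
#' @param seed RNG seed.
#' @return object of class \code{head_layout}: list with \code{types},
#'   \code{neurons}, \code{neighbors}, and the parameters.
#' @export
generate_layout <- function(roster = default_roster(), zone_radius = 40,
                            bristle_spread = 0.08, n_neighbors = 2, seed = NULL) {
  if (nrow(roster) < 2) abort("need at least 2 types", "config_error")
  if (any(roster$n < 1)) abort("every type needs n >= 1 neurons", "config_error")
  if (anyDuplicated(roster$label)) abort("duplicate type labels", "config_error")
  if (!is.null(seed)) set.seed(seed)
  tt <- nrow(roster)
  cen <- fibonacci_hemisphere(tt)
  u <- sph_to_unit(cen[, 1], cen[, 2])
  offset <- c(zone_radius + 10, 0, 0) # keeps every zone x >= 10 um, right side
  zones <- sweep(zone_radius * u, 2, offset, "+")
  types <- cbind(roster,
                 az = cen[, 1], el = cen[, 2],
                 zone_x = zones[, 1], zone_y = zones[, 2], zone_z = zones[, 3],
                 side = "right", stringsAsFactors = FALSE)
  neurons <- do.call(rbind, lapply(seq_len(tt), function(t) {
    n <- roster$n[t]
    data.frame(neuron_id = sprintf("%s_%02d", roster$label[t], seq_len(n)),
               type = roster$label[t], side = "right",
               b_az = cen[t, 1] + rnorm(n, 0, bristle_spread),
               b_el = cen[t, 2] + rnorm(n, 0, bristle_spread),
               stringsAsFactors = FALSE)
  }))
  rownames(neurons) <- NULL
  gc_dist <- head_surface_distance(cen)
  neighbors <- lapply(seq_len(tt), function(t) {
    ord <- order(gc_dist[t, ])
    roster$label[setdiff(ord, t)][seq_len(min(n_neighbors, tt - 1))]
  })
  names(neighbors) <- roster$label
  structure(list(types = types, neurons = neurons, neighbors = neighbors,
                 params = list(zone_radius = zone_radius,
                               bristle_spread = bristle_spread,
                               n_neighbors = n_neighbors, seed = seed)),
            class = "head_layout")
}

#' @export
print.head_layout <- function(x, ...) {
  cat(sprintf("<head_layout> %d types, %d neurons\n",
              nrow(x$types), nrow(x$neurons)))
  invisible(x)
}

# nerve entry points: far from the arbors in -y so the smooth axon is
# cleanly separable by region pruning
nerve_entry <- function(nerve, zone_radius) {
  base <- c(zone_radius + 10, -120, 0)
  dz <- c(AntNv = 20, EyeNv = -20, OcciNv = 40, LabNv = -40)
  base + c(0, 0, unname(dz[nerve]))
}

#' Generate synthetic skeletons with ground truth
#'
#' Each neuron consists of a smooth entry axon (a straight sampled path from
#' its nerve's entry point; SWC type 2, carrying no synapses, removed by
#' region pruning downstream) and a branched terminal arbor of
#' \code{n_points} nodes scattered with Gaussian jitter around the type's
#' zone center (SWC type 5). Types designated midline-crossing get an extra
#' contralateral branch whose tip lies \code{cross_depth} um past the
#' midline (SWC type 3, synapse-free). Because all neurons of a type share
#' one zone center, within-type arbor overlap exceeds neighbor-type overlap,
#' which exceeds distant-type overlap, in expectation.
#'
#' @param layout a \code{head_layout}.
#' @param jitter within-zone Gaussian SD of arbor points in um (default 2).
#' @param n_points arbor nodes per neuron (default 40).
#' @param axon_step axon sampling interval in um (default 5).
#' @param cross_depth how far past the midline the contralateral branch
#'   reaches, um (default 5).
#' @param seed RNG seed.
#' @return list with \code{skeletons} (named list), \code{truth}
#'   (data.frame \code{neuron_id, type, side, crossing_truth}) and
#'   \code{annotations} (annotation table).
#' @export
generate_skeletons <- function(layout, jitter = 2, n_points = 40, axon_step = 5,
                               cross_depth = 5, seed = NULL) {
  stopifnot(inherits(layout, "head_layout"), jitter >= 0, n_points >= 2)
  if (!is.null(seed)) set.seed(seed)
  types <- layout$types
  skeletons <- list()
  for (r in seq_len(nrow(layout$neurons))) {
    nn <- layout$neurons[r, ]
    t <- match(nn$type, types$label)
    center <- c(types$zone_x[t], types$zone_y[t], types$zone_z[t])
    entry <- nerve_entry(types$nerve[t], layout$params$zone_radius)
    # smooth axon: straight chain entry -> center, spacing <= axon_step
    len <- sqrt(sum((center - entry)^2))
    nseg <- max(2, ceiling(len / axon_step))
    tfrac <- seq(0, 1, length.out = nseg + 1)[-(nseg + 1)]
    axon <- outer(tfrac, center - entry) + matrix(entry, nseg, 3, byrow = TRUE)
    # arbor: Gaussian scatter, tree built by nearest-previous attachment
    arbor <- matrix(rnorm(n_points * 3, 0, jitter), n_points, 3) +
      matrix(center, n_points, 3, byrow = TRUE)
    arbor_parent <- integer(n_points)
    arbor_parent[1] <- NA
    if (n_points > 1) for (i in 2:n_points) {
      prev <- arbor[seq_len(i - 1), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, arbor[i, ])^2)
      arbor_parent[i] <- which.min(d2)
    }
    n_axon <- nrow(axon)
    nodes <- data.frame(
      node_id = seq_len(n_axon + n_points),
      swc_type = c(rep(2L, n_axon), rep(5L, n_points)),
      x = c(axon[, 1], arbor[, 1]), y = c(axon[, 2], arbor[, 2]),
      z = c(axon[, 3], arbor[, 3]),
      radius = 0.1,
      parent_id = c(-1L, seq_len(n_axon - 1),
                    n_axon, # arbor root hangs off last axon node
                    if (n_points > 1) n_axon + arbor_parent[2:n_points] else integer(0)))
    if (types$crossing[t]) {
      tip <- c(-cross_depth, center[2], center[3])
      ncr <- 6
      tf <- seq_len(ncr) / ncr
      branch <- outer(tf, tip - center) + matrix(center, ncr, 3, byrow = TRUE)
      ids <- max(nodes$node_id) + seq_len(ncr)
      nodes <- rbind(nodes, data.frame(
        node_id = ids, swc_type = 3L,
        x = branch[, 1], y = branch[, 2], z = branch[, 3], radius = 0.1,
        parent_id = c(n_axon + 1L, ids[-ncr])))
    }
    skeletons[[nn$neuron_id]] <- skeleton(nn$neuron_id, nodes)
  }
  truth <- data.frame(neuron_id = layout$neurons$neuron_id,
                      type = layout$neurons$type,
                      side = layout$neurons$side,
                      crossing_truth = types$crossing[match(layout$neurons$type,
                                                            types$label)],
                      stringsAsFactors = FALSE)
  ann <- as_annotation_table(data.frame(
    neuron_id = layout$neurons$neuron_id,
    type = layout$neurons$type,
    nerve = types$nerve[match(layout$neurons$type, types$label)],
    side = layout$neurons$side,
    bx = layout$neurons$b_az, by = layout$neurons$b_el,
    stringsAsFactors = FALSE))
  list(skeletons = skeletons, truth = truth, annotations = ann)
}

#' Generate a synthetic synapse table with partner ground truth
#'
#' A pool of non-BMN partner neurons is created, \code{partners_per_type}
#' owned by each type. A focal neuron connects to a partner with probability
#' \code{p_same} when the partner is owned by its own type, \code{p_neighbor}
#' for a neighboring type (per the layout's neighbor map), \code{p_distant}
#' otherwise; each realized edge gets \code{1 + Poisson(mean_syn - 1)}
#' synapses. Sparse BMN-to-BMN edges are added between same- and
#' neighbor-type neuron pairs only. Cleft scores are drawn from a clipped
#' Normal(\code{cleft_mu}, \code{cleft_sd}) (defaults 70, 25, putting about
#' 21\% of scores below the 50 filter). Synapse positions sit on randomly
#' chosen presynaptic arbor nodes.
#'
#' @param layout a \code{head_layout}.
#' @param skeletons named list of skeletons from
#'   \code{\link{generate_skeletons}} (for synapse positions).
#' @param p_same,p_neighbor,p_distant connection probabilities in \[0, 1\]
#'   (defaults 0.9, 0.4, 0).
#' @param mean_syn mean synapse count per realized edge (> 1; default 5).
#' @param partners_per_type partner pool size per type (default 26).
#' @param cleft_mu,cleft_sd cleft-score distribution parameters.
#' @param p_bmn_same,p_bmn_neighbor probabilities of a BMN-to-BMN edge for
#'   same-type and neighbor-type ordered pairs (defaults 0.2, 0.05).
#' @param bmn_mean_syn mean synapse count of BMN-to-BMN edges (default 2).
#' @param seed RNG seed.
#' @return list with \code{synapses} (a \code{synapse_table}),
#'   \code{partner_truth} (data.frame \code{partner_id, owner_type}) and the
#'   parameters.
#' @export
generate_synapses <- function(layout, skeletons,
                              p_same = 0.9, p_neighbor = 0.4, p_distant = 0,
                              mean_syn = 5, partners_per_type = 26,
                              cleft_mu = 70, cleft_sd = 25,
                              p_bmn_same = 0.2, p_bmn_neighbor = 0.05,
                              bmn_mean_syn = 2, seed = NULL) {
  probs <- c(p_same, p_neighbor, p_distant, p_bmn_same, p_bmn_neighbor)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]", "config_error")
  if (mean_syn <= 1 || bmn_mean_syn < 1) abort("mean_syn must exceed 1", "config_error")
  if (!is.null(seed)) set.seed(seed)
  types <- layout$types$label
  neurons <- layout$neurons
  partner_truth <- data.frame(
    partner_id = unlist(lapply(types, function(t)
      sprintf("P_%s_%02d", t, seq_len(partners_per_type)))),
    owner_type = rep(types, each = partners_per_type),
    stringsAsFactors = FALSE)
  # type-relation probability matrix
  tt <- length(types)
  rel <- matrix(p_distant, tt, tt, dimnames = list(types, types))
  for (t in types) rel[t, layout$neighbors[[t]]] <- p_neighbor
  diag(rel) <- p_same
  ti <- match(neurons$type, types)
  oi <- match(partner_truth$owner_type, types)
  pmat <- rel[ti, oi, drop = FALSE]
  hit <- which(matrix(runif(length(pmat)), nrow(pmat)) < pmat, arr.ind = TRUE)
  edges <- data.frame(pre_id = neurons$neuron_id[hit[, 1]],
                      post_id = partner_truth$partner_id[hit[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$pre_id, edges$post_id), , drop = FALSE]
  edges$count <- 1L + rpois(nrow(edges), mean_syn - 1)
  # sparse BMN-to-BMN edges among same/neighbor types
  brel <- matrix(0, tt, tt, dimnames = list(types, types))
  for (t in types) brel[t, layout$neighbors[[t]]] <- p_bmn_neighbor
  diag(brel) <- p_bmn_same
  bp <- brel[ti, ti, drop = FALSE]
  diag_idx <- cbind(seq_len(nrow(neurons)), seq_len(nrow(neurons)))
  bp[diag_idx] <- 0 # no autapses
  bhit <- which(matrix(runif(length(bp)), nrow(bp)) < bp, arr.ind = TRUE)
  if (nrow(bhit)) {
    bedges <- data.frame(pre_id = neurons$neuron_id[bhit[, 1]],
                         post_id = neurons$neuron_id[bhit[, 2]],
                         stringsAsFactors = FALSE)
    bedges <- bedges[order(bedges$pre_id, bedges$post_id), , drop = FALSE]
    bedges$count <- 1L + rpois(nrow(bedges), bmn_mean_syn - 1)
    edges <- rbind(edges, bedges)
  }
  # expand edges into synapse rows with positions on the presynaptic arbor
  rows <- edges[rep(seq_len(nrow(edges)), edges$count), c("pre_id", "post_id")]
  n_syn <- nrow(rows)
  pos <- matrix(0, n_syn, 3)
  for (id in unique(rows$pre_id)) {
    sk <- skeletons[[id]]
    arbor <- sk$nodes[sk$nodes$swc_type == 5L, c("x", "y", "z")]
    sel <- which(rows$pre_id == id)
    pick <- sample.int(nrow(arbor), length(sel), replace = TRUE)
    pos[sel, ] <- as.matrix(arbor[pick, ])
  }
  syn <- as_synapse_table(data.frame(
    pre_id = rows$pre_id, post_id = rows$post_id,
    cleft_score = as.integer(round(pmax(rnorm(n_syn, cleft_mu, cleft_sd), 0))),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    stringsAsFactors = FALSE))
  rownames(syn) <- NULL
  list(synapses = syn, partner_truth = partner_truth,
       params = list(p_same = p_same, p_neighbor = p_neighbor,
                     p_distant = p_distant, mean_syn = mean_syn,
                     partners_per_type = partners_per_type,
                     cleft_mu = cleft_mu, cleft_sd = cleft_sd,
                     p_bmn_same = p_bmn_same, p_bmn_neighbor = p_bmn_neighbor,
                     bmn_mean_syn = bmn_mean_syn, seed = seed))
}

#' Generate a complete synthetic connectome
#'
#' Layout, skeletons and synapse table in one call, each stage seeded
#' deterministically from \code{seed}.
#'
#' @param seed master seed.
#' @param roster type roster (default \code{\link{default_roster}}).
#' @param layout_args,skeleton_args,synapse_args named lists of overrides
#'   passed to the three generators.
#' @return list with \code{layout}, \code{skeletons}, \code{truth},
#'   \code{annotations}, \code{synapses}, \code{partner_truth}.
#' @export
generate_connectome <- function(seed = 1, roster = default_roster(),
                                layout_args = list(), skeleton_args = list(),
                                synapse_args = list()) {
  layout <- do.call(generate_layout,
                    c(list(roster = roster, seed = seed), layout_args))
  sk <- do.call(generate_skeletons,
                c(list(layout = layout, seed = seed + 1000L), skeleton_args))
  sy <- do.call(generate_synapses,
                c(list(layout = layout, skeletons = sk$skeletons,
                       seed = seed + 2000L), synapse_args))
  list(layout = layout, skeletons = sk$skeletons, truth = sk$truth,
       annotations = sk$annotations, synapses = sy$synapses,
       partner_truth = sy$partner_truth,
       params = list(layout = layout$params, synapses = sy$params, seed = seed))
}

#' Write a synthetic connectome to disk
#'
#' SWC file per neuron under \code{dir/swc/}, \code{synapses.csv},
#' \code{annotations.csv}, \code{ground_truth.json} and \code{params.yaml}.
#' Byte-identical output for identical (parameters, seed).
#'
#' @param cn result of \code{\link{generate_connectome}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_connectome <- function(cn, dir) {
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  for (sk in cn$skeletons)
    write_swc(sk, file.path(dir, "swc", paste0(sk$neuron_id, ".swc")))
  utils::write.table(cn$synapses, file.path(dir, "synapses.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(cn$annotations), file.path(dir, "annotations.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(neurons = cn$truth, partners = cn$partner_truth),
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  par <- cn$params$synapses
  yaml_lines <- c("# generation parameters",
                  sprintf("seed: %d", cn$params$seed),
                  sprintf("zone_radius: %g", cn$params$layout$zone_radius),
                  sprintf("bristle_spread: %g", cn$params$layout$bristle_spread),
                  vapply(names(par), function(k)
                    sprintf("%s: %s", k,
                            if (is.null(par[[k]])) "null" else format(par[[k]])), ""))
  writeLines(yaml_lines, file.path(dir, "params.yaml"))
  invisible(dir)
}
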