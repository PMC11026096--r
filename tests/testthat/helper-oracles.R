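# Independent oracles and small fixture builders. Everything here is written
# deliberately naively (plain loops, no k-d trees, no hclust) so it can serve
# as a cross-check on the package's fast paths.

row_norms_test <- function(m) sqrt(rowSums(m^2))

# straight chain of n nodes along +z with given spacing (um)
chain_skeleton <- function(n, spacing = 1, id = "chain") {
  skeleton(id, data.frame(node_id = seq_len(n),
                          x = 0, y = 0, z = (seq_len(n) - 1) * spacing,
                          radius = 0.5,
                          parent_id = c(-1L, seq_len(n - 1))))
}

# dotprops for a straight line of n points along +x at y-offset, unit tangents
line_dotprops <- function(n, spacing = 1, y = 0, id = "line") {
  structure(list(neuron_id = id,
                 points = cbind(x = (seq_len(n) - 1) * spacing, y = y, z = 0),
                 tangents = matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE),
                 alpha = rep(1, n)),
            class = "dotprops")
}

# random Gaussian point cloud as dotprops with random unit tangents
random_dotprops <- function(n, id, center = c(0, 0, 0), sd = 5) {
  pts <- matrix(rnorm(n * 3, 0, sd), n, 3) + matrix(center, n, 3, byrow = TRUE)
  tg <- matrix(rnorm(n * 3), n, 3)
  tg <- tg / sqrt(rowSums(tg^2))
  structure(list(neuron_id = id, points = pts, tangents = tg, alpha = rep(1, n)),
            class = "dotprops")
}

# brute-force all-pairs nearest-neighbour NBLAST raw score
brute_nblast_raw <- function(query, target, score_fn = nblast_score_fn()) {
  total <- 0
  for (i in seq_len(nrow(query$points))) {
    d <- sqrt(colSums((t(target$points) - query$points[i, ])^2))
    j <- which.min(d)
    absdot <- abs(sum(query$tangents[i, ] * target$tangents[j, ]))
    total <- total + score_fn(d[j], absdot)
  }
  total
}

# step-by-step Ward agglomeration (Lance-Williams on squared distances, the
# ward.D2 criterion), naive O(n^3); returns sorted merge heights and the
# 2-cluster partition
manual_ward <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  while (sum(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) if (a < b && d2[a, b] < bestv) {
      bestv <- d2[a, b]; best <- c(a, b)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    for (k in idx) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[i, k] + (sizes[j] + sizes[k]) * d2[j, k] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    if (sum(active) == 2) two_clusters <- members[active]
  }
  list(heights = heights, two_clusters = two_clusters)
}

# random synapse table
random_synapse_table <- function(n_rows, n_neurons = 8, max_score = 100) {
  ids <- sprintf("N%02d", seq_len(n_neurons))
  as_synapse_table(data.frame(
    pre_id = sample(ids, n_rows, replace = TRUE),
    post_id = sample(ids, n_rows, replace = TRUE),
    cleft_score = sample.int(max_score, n_rows, replace = TRUE),
    x = runif(n_rows), y = runif(n_rows), z = runif(n_rows),
    stringsAsFactors = FALSE))
}

# equal-count roster of n types, used by recovery tests
flat_roster <- function(n_types, n_each, crossing = FALSE) {
  data.frame(label = sprintf("T%02d", seq_len(n_types)),
             n = as.integer(n_each),
             nerve = rep(c("AntNv", "EyeNv", "OcciNv", "LabNv"),
                         length.out = n_types),
             crossing = crossing, inom_like = FALSE,
             stringsAsFactors = FALSE)
}

# rigid motion: random rotation (QR of a Gaussian matrix) plus translation
random_rigid_motion <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- rnorm(3, 0, 10)
  function(dp) {
    dp$points <- dp$points %*% rot + matrix(shift, nrow(dp$points), 3, byrow = TRUE)
    dp$tangents <- dp$tangents %*% rot
    dp
  }
}
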