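test_that("generators are deterministic under a fixed seed", {
  a <- generate_connectome(seed = 5, roster = flat_roster(4, 3))
  b <- generate_connectome(seed = 5, roster = flat_roster(4, 3))
  expect_equal(a$layout$neurons, b$layout$neurons)
  expect_equal(lapply(a$skeletons, `[[`, "nodes"), lapply(b$skeletons, `[[`, "nodes"))
  expect_equal(as.data.frame(a$synapses), as.data.frame(b$synapses))
  d <- generate_connectome(seed = 6, roster = flat_roster(4, 3))
  expect_false(identical(as.data.frame(a$synapses), as.data.frame(d$synapses)))

  # byte-identical files
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_connectome(a, dir1); write_connectome(b, dir2)
  f1 <- list.files(dir1, recursive = TRUE)
  for (f in f1)
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
})

test_that("layout geometry: distinct zones, monotone head-to-brain map, neighbors", {
  lay <- generate_layout(seed = 151) # default 15-type roster
  z <- as.matrix(lay$types[, c("zone_x", "zone_y", "zone_z")])
  expect_equal(nrow(z), 15)
  expect_gt(min(dist(z)), 0) # all distinct
  expect_true(all(z[, 1] >= 10)) # every zone safely right of the midline
  # zone distance is monotone in head-surface distance between centroids
  gc <- head_surface_distance(as.matrix(lay$types[, c("az", "el")]))
  bd <- as.matrix(dist(z))
  ut <- upper.tri(gc)
  expect_gt(suppressWarnings(cor(gc[ut], bd[ut], method = "spearman")), 0.999)
  # neighbor map: k nearest by great-circle distance
  expect_equal(length(lay$neighbors), 15)
  expect_true(all(vapply(lay$neighbors, length, 1L) == 2))
  expect_error(generate_layout(flat_roster(1, 3)), class = "config_error")
})

test_that("skeletons implement the designated crossing construction", {
  lay <- generate_layout(flat_roster(3, 2, crossing = c(TRUE, FALSE, FALSE)),
                         seed = 161)
  sk <- generate_skeletons(lay, seed = 162)
  for (id in names(sk$skeletons)) {
    truth <- sk$truth$crossing_truth[sk$truth$neuron_id == id]
    got <- classify_crossing(sk$skeletons[[id]], 0, "right")$crossing
    expect_equal(got, truth)
  }
  # zero jitter: same-type arbors nearly identical up to sampling
  lay0 <- generate_layout(flat_roster(2, 2), seed = 163)
  sk0 <- generate_skeletons(lay0, jitter = 0, seed = 164)
  dp <- lapply(sk0$skeletons[c("T01_01", "T01_02")], function(s)
    make_dotprops(resample_skeleton(s, 1), 5))
  s <- nblast_matrix(dp)
  expect_gt(s[1, 2], 0.99)
})

test_that("distant types have near-zero morphological similarity", {
  lay <- generate_layout(flat_roster(6, 2), seed = 171)
  sk <- generate_skeletons(lay, seed = 172)
  sy <- generate_synapses(lay, sk$skeletons, seed = 173)
  syn <- filter_synapses(sy$synapses, 50)
  pruned <- lapply(sk$skeletons, function(s) {
    pos <- syn[syn$pre_id == s$neuron_id, c("x", "y", "z")]
    prune_to_region(s, bounding_box(pos, pad = 1))
  })
  dps <- lapply(pruned, function(s) make_dotprops(resample_skeleton(s, 1), 5))
  s <- nblast_matrix(dps)
  gc <- head_surface_distance(as.matrix(lay$types[, c("az", "el")]))
  type_of <- setNames(sk$truth$type, sk$truth$neuron_id)
  labels <- lay$types$label
  far_pairs <- which(gc > 1.2, arr.ind = TRUE) # well-separated on the head
  for (r in seq_len(nrow(far_pairs))) {
    ids_a <- names(type_of)[type_of == labels[far_pairs[r, 1]]]
    ids_b <- names(type_of)[type_of == labels[far_pairs[r, 2]]]
    expect_lt(max(s[ids_a, ids_b]), 0.05)
  }
})

test_that("cleft-score distribution puts the expected mass below the filter", {
  lay <- generate_layout(flat_roster(10, 4), seed = 181)
  sk <- generate_skeletons(lay, seed = 182)
  sy <- generate_synapses(lay, sk$skeletons, seed = 183,
                          p_distant = 0.1, partners_per_type = 15)
  n <- nrow(sy$synapses)
  expect_gt(n, 5000)
  frac_expected <- pnorm(50, 70, 25) # ~0.212 from the clipped normal
  below <- sum(sy$synapses$cleft_score < 50)
  tol <- 4 * sqrt(n * frac_expected * (1 - frac_expected)) # binomial 4 sigma
  expect_lt(abs(below - n * frac_expected), tol)
  # filter removes exactly those rows
  expect_equal(nrow(filter_synapses(sy$synapses, 50)), n - below)
})

test_that("generated connectivity satisfies the assumed cosine ordering", {
  lay <- generate_layout(flat_roster(8, 5), seed = 191)
  sk <- generate_skeletons(lay, seed = 192)
  sy <- generate_synapses(lay, sk$skeletons, seed = 193)
  edges <- aggregate_edges(filter_synapses(sy$synapses, 50))
  prof <- build_profiles(edges, sk$annotations, lay$types$label, 1)
  s <- unclass(cosine_matrix(prof))
  type_of <- setNames(sk$truth$type, sk$truth$neuron_id)
  tl <- type_of[rownames(s)]
  same <- neighbor <- distant <- c()
  for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
    rel <- if (tl[i] == tl[j]) "same"
    else if (tl[j] %in% lay$neighbors[[tl[i]]] ||
             tl[i] %in% lay$neighbors[[tl[j]]]) "neighbor" else "distant"
    if (rel == "same") same <- c(same, s[i, j])
    else if (rel == "neighbor") neighbor <- c(neighbor, s[i, j])
    else distant <- c(distant, s[i, j])
  }
  expect_gt(mean(same), mean(neighbor))
  expect_gt(mean(neighbor), mean(distant))
  expect_lt(mean(distant), 0.05) # p_distant = 0
})

test_that("probability and count validation", {
  lay <- generate_layout(flat_roster(2, 2), seed = 201)
  sk <- generate_skeletons(lay, seed = 202)
  expect_error(generate_synapses(lay, sk$skeletons, p_same = 1.2),
               class = "config_error")
  expect_error(generate_synapses(lay, sk$skeletons, mean_syn = 1),
               class = "config_error")
  expect_error(generate_layout(flat_roster(3, 0)), class = "config_error")
})
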