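test_that("make_dotprops: collinear, isotropic, and degenerate cases", {
  # 20 collinear points along x -> tangents (1,0,0), alpha 1
  sk <- skeleton("line", data.frame(node_id = 1:20, x = 0:19, y = 0, z = 0,
                                    radius = 0, parent_id = c(-1L, 1:19)))
  dp <- make_dotprops(sk, k = 5)
  expect_equal(dp$tangents, matrix(rep(c(1, 0, 0), 20), 20, 3, byrow = TRUE))
  expect_equal(dp$alpha, rep(1, 20))

  # near-uniform sphere shell with k = N -> alpha ~ 1/3 (isotropic covariance)
  n <- 400
  i <- seq_len(n) - 0.5
  el <- acos(1 - 2 * i / n)
  az <- pi * (1 + sqrt(5)) * i
  pts <- cbind(sin(el) * cos(az), sin(el) * sin(az), cos(el)) * 10
  shell <- skeleton("shell", data.frame(node_id = seq_len(n),
                                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                        radius = 0, parent_id = c(-1L, seq_len(n - 1)),
                                        check.names = FALSE))
  dps <- make_dotprops(shell, k = n)
  expect_lt(max(abs(dps$alpha - 1 / 3)), 0.02)

  # single point with k = 5: clamped, canonical tangent
  one <- skeleton("pt", data.frame(node_id = 1L, x = 0, y = 0, z = 0,
                                   radius = 0, parent_id = -1L))
  dp1 <- make_dotprops(one, k = 5)
  expect_equal(dp1$tangents[1, ], c(1, 0, 0))
  expect_equal(dp1$alpha, 1)
})

test_that("tangents are unit vectors with canonical sign", {
  set.seed(31)
  lay <- generate_layout(flat_roster(2, 2), seed = 31)
  sks <- generate_skeletons(lay, seed = 32)$skeletons
  for (sk in sks) {
    dp <- make_dotprops(resample_skeleton(sk, 1), k = 5)
    expect_lt(max(abs(row_norms_test(dp$tangents) - 1)), 1e-9)
    first_nz <- apply(dp$tangents, 1, function(v) v[abs(v) > 1e-12][1])
    expect_true(all(first_nz > 0))
    expect_true(all(dp$alpha >= 0 & dp$alpha <= 1))
  }
})

test_that("nblast_raw closed forms: self-match N, parallel lines N exp(-d0/sigma)", {
  n <- 25
  a <- line_dotprops(n)
  expect_equal(nblast_raw(a, a), n, tolerance = 1e-12)
  for (d0 in c(0.5, 2, 7)) {
    b <- line_dotprops(n, y = d0, id = "offset")
    expect_lt(abs(nblast_raw(a, b) - n * exp(-d0 / 3)), 1e-9)
  }
  # perpendicular far-apart lines score towards zero
  far <- line_dotprops(n, y = 1e4, id = "far")
  far$tangents <- matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE)
  expect_lt(nblast_raw(a, far), 1e-12)
})

test_that("k-d tree scoring equals brute force on random clouds", {
  set.seed(41)
  for (rep in 1:10) {
    q <- random_dotprops(sample(5:50, 1), "q")
    t <- random_dotprops(sample(5:50, 1), "t", center = rnorm(3, 0, 3))
    expect_lt(abs(nblast_raw(q, t) - brute_nblast_raw(q, t)), 1e-9)
  }
})

test_that("nblast_matrix: duplicates, symmetry, bounds, rigid-motion invariance", {
  set.seed(51)
  neurons <- c(lapply(1:4, function(i)
    random_dotprops(30, sprintf("n%d", i), center = rnorm(3, 0, 8))),
    list(local({ d <- random_dotprops(30, "dup", center = c(2, 2, 2)); d })))
  neurons[[6]] <- neurons[[5]]
  neurons[[6]]$neuron_id <- "dup2"
  s <- nblast_matrix(neurons)
  expect_equal(unname(s["dup", "dup2"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(unclass(s) - t(unclass(s)))), 1e-9)
  expect_equal(unname(diag(s)), rep(1, 6))
  expect_true(all(s >= -1 & s <= 1))
  # self-similarity maximal for equal-density clouds
  expect_true(all(s <= 1 + 1e-9))

  move <- random_rigid_motion()
  s2 <- nblast_matrix(lapply(neurons, move))
  expect_lt(max(abs(unclass(s2) - unclass(s))), 1e-6)
})

test_that("ward_cluster matches manual Lance-Williams agglomeration on 4 items", {
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(0.2, 0.9, 0.85, 0.95, 0.8, 0.1)
  d <- d + t(d) # items 1-2 close (0.2), 3-4 close (0.1), groups far apart
  s <- similarity_matrix(1 - d, sprintf("n%d", 1:4))
  cr <- ward_cluster(s)
  oracle <- manual_ward(d)
  expect_equal(sort(cr$hclust$height), sort(oracle$heights), tolerance = 1e-12)
  expect_false(is.unsorted(cr$hclust$height)) # ultrametric under Ward

  # cut between 2nd and 3rd merge height -> the oracle's 2-cluster partition
  h <- mean(sort(cr$hclust$height)[2:3])
  labels <- cut_clusters(cr, height = h)
  expect_equal(length(unique(labels)), 2)
  grp <- vapply(split(names(labels), labels),
                function(g) paste(sort(g), collapse = ","), "")
  oracle_grp <- vapply(oracle$two_clusters,
                       function(ix) paste(sort(sprintf("n%d", ix)), collapse = ","), "")
  expect_setequal(unname(grp), unname(oracle_grp))
})

test_that("cut_clusters semantics: extremes, strict height rule, k errors", {
  set.seed(61)
  neurons <- lapply(1:5, function(i) random_dotprops(20, sprintf("n%d", i),
                                                     center = rnorm(3, 0, 10)))
  neurons[[6]] <- neurons[[1]]; neurons[[6]]$neuron_id <- "copy"
  cr <- ward_cluster(nblast_matrix(neurons))
  expect_equal(length(unique(cut_clusters(cr, height = max(cr$hclust$height) + 1))), 1)
  # strictly-below-h rule: at 0+ exact duplicates (merged at height 0) stay together
  labels0 <- cut_clusters(cr, height = 1e-12)
  expect_equal(length(unique(labels0)), 5)
  expect_equal(unname(labels0["n1"]), unname(labels0["copy"]))
  expect_error(cut_clusters(cr, k = 99), class = "argument_error")
  expect_error(cut_clusters(cr), class = "argument_error")
  expect_error(cut_clusters(cr, height = 1, k = 2), class = "argument_error")
})

test_that("well-separated identical groups split at any cut between 0 and top", {
  a <- line_dotprops(20, id = "a1")
  neurons <- list(a,
                  local({ d <- a; d$neuron_id <- "a2"; d }),
                  line_dotprops(20, y = 500, id = "b1"),
                  local({ d <- line_dotprops(20, y = 500, id = "b2"); d }))
  cr <- ward_cluster(nblast_matrix(neurons))
  top <- max(cr$hclust$height)
  for (h in c(top * 0.25, top * 0.5, top * 0.9)) {
    labels <- cut_clusters(cr, height = h)
    expect_equal(length(unique(labels)), 2)
    expect_equal(unname(labels["a1"]), unname(labels["a2"]))
    expect_equal(unname(labels["b1"]), unname(labels["b2"]))
  }
})

test_that("write_newick produces a readable ultrametric tree", {
  set.seed(71)
  neurons <- lapply(1:4, function(i) random_dotprops(15, sprintf("n%d", i),
                                                     center = rnorm(3, 0, 10)))
  cr <- ward_cluster(nblast_matrix(neurons))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, sprintf("n%d", 1:4))
})
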