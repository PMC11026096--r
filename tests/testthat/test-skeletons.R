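test_that("read_swc parses a minimal chain and round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 0 0 0 0 1 -1", "2 0 0 5 0 1 1", "3 0 0 10 0 1 2"),
             path)
  sk <- read_swc(path)
  expect_s3_class(sk, "skeleton")
  expect_equal(nrow(sk$nodes), 3)
  expect_equal(sk$nodes$node_id[sk$nodes$parent_id == -1], 1)

  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, out)
  expect_equal(sum(!grepl("^#", readLines(out))), 3)
  sk2 <- read_swc(out)
  expect_equal(sk2$nodes, sk$nodes)
  expect_true(max(abs(sk2$nodes$x - sk$nodes$x),
                  abs(sk2$nodes$z - sk$nodes$z)) < 1e-9)
})

test_that("read_swc reports malformed lines and units_scale rescales", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 0 0 0 0 1 -1", "2 0 0 junk 0 1 1"), path)
  expect_error(read_swc(path), "line 2", class = "swc_parse_error")

  writeLines(c("1 0 1000 2000 3000 500 -1"), path)
  sk <- read_swc(path, units_scale = 1e-3)
  expect_equal(unlist(sk$nodes[1, c("x", "y", "z", "radius")]),
               c(x = 1, y = 2, z = 3, radius = 0.5))
})

test_that("skeleton validation catches dangling parents, cycles, empties", {
  base <- data.frame(node_id = 1:3, x = 0, y = 0, z = 0:2, radius = 0,
                     parent_id = c(-1L, 1L, 2L))
  expect_s3_class(skeleton("ok", base), "skeleton")
  bad <- base; bad$parent_id[2] <- 9L
  expect_error(skeleton("s", bad), "node\\(s\\) 2", class = "skeleton_invalid")
  cyc <- base; cyc$parent_id <- c(3L, 1L, 2L)
  expect_error(skeleton("s", cyc), "cycle", class = "skeleton_invalid")
  expect_error(skeleton("s", base[0, ]), class = "skeleton_invalid")
  dup <- base; dup$node_id[2] <- 1L
  expect_error(skeleton("s", dup), "duplicate", class = "skeleton_invalid")
})

test_that("prune_to_region keeps exactly the in-box nodes (chain example)", {
  sk <- chain_skeleton(10) # z = 0..9
  box <- region_box(c(-1, -1, 0), c(1, 1, 4))
  pr <- prune_to_region(sk, box)
  expect_equal(nrow(pr$nodes), 5) # closed box: z in {0,1,2,3,4}
  expect_setequal(pr$nodes$z, 0:4)

  # identity when fully inside; error when disjoint
  all_in <- prune_to_region(sk, region_box(c(-1, -1, -1), c(1, 1, 100)))
  expect_equal(all_in$nodes, sk$nodes)
  expect_error(prune_to_region(sk, region_box(c(10, 10, 10), c(20, 20, 20))),
               class = "empty_region_error")
})

test_that("prune_to_region matches brute-force membership, is idempotent, re-roots fragments", {
  set.seed(11)
  for (rep in 1:10) {
    nodes <- data.frame(node_id = 1:40, x = runif(40, -5, 5),
                        y = runif(40, -5, 5), z = runif(40, -5, 5),
                        radius = 0, parent_id = c(-1L, sapply(2:40, function(i)
                          sample.int(i - 1, 1))))
    sk <- skeleton(sprintf("r%d", rep), nodes)
    box <- region_box(runif(3, -5, 0), runif(3, 0, 5))
    inside <- with(nodes, x >= box$min[1] & x <= box$max[1] &
                     y >= box$min[2] & y <= box$max[2] &
                     z >= box$min[3] & z <= box$max[3])
    if (!any(inside)) {
      expect_error(prune_to_region(sk, box), class = "empty_region_error")
      next
    }
    pr_all <- prune_to_region(sk, box, keep = "all")
    expect_setequal(pr_all$nodes$node_id, nodes$node_id[inside])
    # each fragment root's original parent is outside (or it was the root)
    roots <- pr_all$nodes[pr_all$nodes$parent_id == -1, "node_id"]
    orig_parent <- nodes$parent_id[match(roots, nodes$node_id)]
    expect_true(all(orig_parent == -1 | !(orig_parent %in% pr_all$nodes$node_id)))
    # idempotence
    pr2 <- prune_to_region(pr_all, box, keep = "all")
    expect_equal(pr2$nodes, pr_all$nodes)
    # keep = largest returns the biggest fragment
    pr_lg <- prune_to_region(sk, box, keep = "largest")
    expect_false(pr_lg$fragmented)
    expect_true(all(pr_lg$nodes$node_id %in% pr_all$nodes$node_id))
  }
})

test_that("resample subdivides a 10 um edge at step 2 into nodes at 0,2,...,10", {
  sk <- skeleton("edge", data.frame(node_id = 1:2, x = 0, y = 0, z = c(0, 10),
                                    radius = 0, parent_id = c(-1L, 1L)))
  rs <- resample_skeleton(sk, 2)
  expect_equal(nrow(rs$nodes), 6)
  expect_equal(sort(rs$nodes$z), seq(0, 10, by = 2))
  expect_error(resample_skeleton(sk, 0), class = "argument_error")
})

test_that("resample preserves fine skeletons, branch points and cable length", {
  fine <- chain_skeleton(10, spacing = 0.5)
  expect_equal(nrow(resample_skeleton(fine, 1)$nodes), 10)

  set.seed(21)
  lay <- generate_layout(flat_roster(3, 2), seed = 21)
  sks <- generate_skeletons(lay, seed = 22)$skeletons
  for (sk in sks) {
    rs <- resample_skeleton(sk, 1.5)
    expect_lt(abs(cable_length(rs) - cable_length(sk)) / cable_length(sk), 1e-6)
    # original nodes survive with identical coordinates
    keep <- match(sk$nodes$node_id, rs$nodes$node_id)
    expect_false(anyNA(keep))
    expect_equal(rs$nodes$x[keep], sk$nodes$x)
    expect_equal(rs$nodes$z[keep], sk$nodes$z)
    # spacing bound holds
    e <- rs$nodes$parent_id != -1
    pm <- match(rs$nodes$parent_id[e], rs$nodes$node_id)
    seg <- sqrt((rs$nodes$x[e] - rs$nodes$x[pm])^2 +
                  (rs$nodes$y[e] - rs$nodes$y[pm])^2 +
                  (rs$nodes$z[e] - rs$nodes$z[pm])^2)
    expect_true(all(seg <= 1.5 + 1e-9))
  }
})
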