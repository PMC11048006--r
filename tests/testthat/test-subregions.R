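test_that("boundary distance matches the all-pairs oracle and hand geometry", {
  # isolated voxel: distance to the adjacent background is one spacing
  g <- array(FALSE, c(5, 5, 5))
  g[3, 3, 3] <- TRUE
  expect_equal(boundary_distance(voxel_mask(g))[3, 3, 3], 1)

  # anisotropic slab, 1 voxel thick in z: in-plane interior voxels see the
  # 3 mm z-step only when it is shorter than the in-plane exit
  slab <- array(FALSE, c(9, 9, 3))
  slab[2:8, 2:8, 2] <- TRUE
  d <- boundary_distance(voxel_mask(slab, c(1, 1, 3)))
  expect_equal(d[5, 5, 2], 3) # centre: z exit (3 mm) beats 4 mm in-plane
  expect_equal(d[2, 5, 2], 1) # edge voxel: 1 mm lateral exit

  # ball and random blob against exhaustive nearest-background search
  for (m in list(mk_ball(6), mk_blob(14, seed = 3),
                 mk_ball(5, spacing = c(1, 1, 2.5)))) {
    expect_equal(boundary_distance(m), oracle_edt(m),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }

  # ball radius 10: deepest point within one voxel of the radius
  b10 <- mk_ball(10)
  expect_lt(abs(max(boundary_distance(b10)) - 10), 1)
  expect_error(boundary_distance(voxel_mask(array(FALSE, c(3, 3, 3)))),
               class = "subgrade_empty_error")
})

test_that("volume-fraction cores match the sort-by-distance oracle", {
  b <- mk_ball(10)
  n <- sum(b)
  for (p in c(0.25, 0.5, 0.75)) {
    core <- extract_core(b, p)
    expect_identical(sum(core), as.integer(round(p * n)))
    expect_equal(array(as.logical(core), dim(core)), oracle_core(b, p),
                 ignore_attr = TRUE)
  }
  # fraction 1 is the identity; centroid voxel is in every core
  expect_identical(extract_core(b, 1), b)
  ctr <- (dim(b) + 1) / 2
  expect_true(extract_core(b, 0.25)[ctr[1], ctr[2], ctr[3]])
  # nesting
  expect_true(all(!(as.logical(extract_core(b, 0.25)) &
                      !as.logical(extract_core(b, 0.5)))))
  # blob (non-convex) agrees with the oracle too
  blob <- mk_blob(16, seed = 9)
  expect_equal(array(as.logical(extract_core(blob, 0.5)), dim(blob)),
               oracle_core(blob, 0.5), ignore_attr = TRUE)
  expect_error(extract_core(voxel_mask(array(c(TRUE, rep(FALSE, 7)),
                                             c(2, 2, 2))), 0.25),
               class = "subgrade_degenerate_error")
})

test_that("peripheries are exact complements of the opposite core", {
  b <- mk_ball(10)
  for (p in c(0.25, 0.5, 0.75)) {
    per <- extract_periphery(b, p)
    core <- extract_core(b, 1 - p)
    expect_identical(sum(per) + sum(core), sum(b))
    expect_false(any(as.logical(per) & as.logical(core)))
    expect_identical(as.logical(per) | as.logical(core),
                     as.logical(b))
  }
  # hollow rim: the centroid is never in the thin periphery
  ctr <- (dim(b) + 1) / 2
  expect_false(extract_periphery(b, 0.25)[ctr[1], ctr[2], ctr[3]])
  # no periphery voxel deeper than the 50% cut distance
  d <- boundary_distance(b)
  per50 <- extract_periphery(b, 0.5)
  core50 <- extract_core(b, 0.5)
  expect_lte(max(d[as.logical(per50)]), min(d[as.logical(core50)]))
})

test_that("the subregion set holds 7 nested regions with exact counts", {
  b <- mk_ball(10)
  set <- build_subregion_set(b)
  masks <- subregion_masks(set)
  expect_named(masks, c("full", "core25", "core50", "core75",
                        "periphery25", "periphery50", "periphery75"))
  n <- sum(b)
  for (p in c(25, 50, 75))
    expect_lte(abs(sum(masks[[paste0("core", p)]]) - p / 100 * n), 1)
  for (p in c(25, 50, 75))
    expect_identical(sum(masks[[paste0("core", p)]]) +
                       sum(masks[[paste0("periphery", 100 - p)]]), n)
  expect_length(set$flags, 0)

  # tiny 2x2x2 mask: degenerate core flagged, not dropped silently
  tiny <- voxel_mask(array(TRUE, c(2, 2, 2)))
  set2 <- build_subregion_set(tiny)
  expect_true(any(grepl("core25", set2$flags)))
})

test_that("volume fractions are accurate within 1% for balls >= 8 voxels", {
  for (r in c(8, 10, 12)) {
    b <- mk_ball(r)
    n <- sum(b)
    for (p in c(0.25, 0.5, 0.75)) {
      frac <- sum(extract_core(b, p)) / n
      expect_lt(abs(frac - p), 0.01)
    }
  }
})

test_that("core extraction is robust to 90-degree rotation", {
  b <- mk_ball(9)
  core <- extract_core(b, 0.5)
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(2, 1, 3)) # 90 deg about z
  core_rot <- extract_core(voxel_mask(rot(array(as.logical(b), dim(b)))), 0.5)
  back <- aperm(core_rot, c(2, 1, 3))[, dim(b)[2]:1, ]
  expect_gte(dice(core, voxel_mask(array(back, dim(b)))), 0.95)
})

test_that("dice follows its closed form and error contract", {
  a <- mk_ball(5)
  expect_equal(dice(a, a), 1)
  empty <- voxel_mask(array(FALSE, dim(a)))
  expect_equal(dice(a, empty), 0)
  expect_equal(dice(empty, empty), 1)
  # constructed overlap |a| = |b| = 100, |intersection| = 93
  g1 <- array(FALSE, c(10, 10, 3))
  g2 <- array(FALSE, c(10, 10, 3))
  g1[seq_len(100)] <- TRUE
  g2[8:107] <- TRUE
  expect_equal(dice(voxel_mask(g1), voxel_mask(g2)), 0.93)
  expect_error(dice(a, mk_ball(6)), class = "subgrade_alignment_error")
})
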