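test_that("reduced morphology arithmetic and structure are correct", {
  # one unbranched dendrite of 4 x 25 um segments
  m <- build_default_morphology(n_primary = 1, segments_per_branch = 4,
                                seg_length = 25, split_after = 4)
  expect_equal(max(m$path_mid_um), 87.5)
  expect_equal(nrow(m) - 1, 1 * 4)
  # parent-to-child path distance monotone non-decreasing
  m2 <- build_default_morphology()
  for (i in 2:nrow(m2)) {
    p <- m2$parent_id[i]
    if (p > 1) expect_gte(m2$path_start_um[i], m2$path_start_um[p])
  }
  # round trip through the delimited table
  f <- tempfile(fileext = ".csv")
  write_morphology(m2, f)
  back <- read_morphology(f)
  expect_equal(back$path_mid_um, m2$path_mid_um)
  unlink(f)
})

test_that("path distances are tree metrics computed along the dendrite", {
  m <- build_default_morphology()
  # same segment
  expect_equal(path_distance(m, 2, 3, 2, 10), 7)
  # ancestor chain: distance equals root-distance difference
  child <- which(m$parent_id == 2)[1]
  d <- path_distance(m, 2, 5, child, 4)
  expect_equal(d, (m$path_start_um[child] + 4) - (m$path_start_um[2] + 5))
  # across the soma: sum of root distances
  prim <- which(m$parent_id == 1)
  d2 <- path_distance(m, prim[1], 2, prim[2], 3)
  expect_equal(d2, 5)
  # symmetry
  expect_equal(path_distance(m, 5, 1, 20, 2),
               path_distance(m, 20, 2, 5, 1))
})

test_that("spine placement respects density, the 25 um exclusion, and rounding", {
  m <- build_default_morphology(n_primary = 1, segments_per_branch = 5,
                                seg_length = 25, split_after = 5)
  expect_equal(nrow(place_spines(m, 0, 25, seed = 1)), 0)
  # eligible length 100 um at 0.1 / um -> exactly 10 spines
  sp <- place_spines(m, 0.1, 25, seed = 2)
  expect_equal(nrow(sp), 10)
  expect_true(all(sp$path_distance_um > 25))
  m2 <- build_default_morphology()
  sp2 <- place_spines(m2, 0.75, 25, seed = 3)
  expect_true(all(sp2$path_distance_um > 25))
  expect_false(any(duplicated(sp2[c("segment_id", "arc_pos_um")])))
})

test_that("cluster assignment is injective and respects the cluster length", {
  m <- tiny_model()
  dm <- spine_distance_matrix(m$morph, m$spines)
  # single-spine clusters: a random matching with zero span
  mp1 <- assign_clusters(m$morph, m$spines, 30, cluster_config(1, 0, seed = 5),
                         dmat = dm)
  expect_equal(attr(mp1, "cluster_span_um"), rep(0, 30))
  expect_false(any(duplicated(mp1$spine_id)))
  # high-density placement: 5-spine clusters within 10 um
  sp <- place_spines(m$morph, 2.0, 25, seed = 6,
                     segments = select_cluster_segments(m$morph, 100))
  dm2 <- spine_distance_matrix(m$morph, sp)
  mp <- assign_clusters(m$morph, sp, 40, cluster_config(5, 10, seed = 7),
                        dmat = dm2)
  expect_false(any(duplicated(mp$spine_id)))
  spans <- attr(mp, "cluster_span_um")
  expect_true(all(spans <= 10 + 1e-6))
  for (cl in unique(mp$cluster_id)) {
    rows <- match(mp$spine_id[mp$cluster_id == cl], sp$spine_id)
    if (length(rows) > 1)
      expect_lte(max(dm2[rows, rows]), 10 + 1e-6)
  }
})

test_that("mapping draws are distinct across configurations and seeds", {
  m <- tiny_model()
  sp <- place_spines(m$morph, 2.0, 25, seed = 6,
                     segments = select_cluster_segments(m$morph, 150))
  dm <- spine_distance_matrix(m$morph, sp)
  grid <- expand.grid(spc = c(1, 2, 5, 10, 20), len = c(10, 20, 40, 60, 80))
  maps <- list()
  for (g in seq_len(nrow(grid))) {
    cc <- cluster_config(grid$spc[g], grid$len[g], n_mappings = 5,
                         seed = 100 * g)
    maps <- c(maps, assign_cluster_mappings(m$morph, sp, 40, cc, dmat = dm))
  }
  expect_equal(length(maps), 125)
  keys <- vapply(maps, function(mm) paste(mm$spine_id, collapse = ","), "")
  expect_equal(length(unique(keys)), 125)
})

test_that("infeasible cluster configurations fail with an explicit constraint error", {
  m <- tiny_model() # low-density spines: 10 spines within 5 um impossible
  expect_error(
    assign_clusters(m$morph, m$spines, 30, cluster_config(10, 5, seed = 1)),
    "cluster_length")
})

test_that("nearest-neighbor order is deterministic with ties broken by spine id", {
  d <- matrix(c(0, 1, 1, 2,
                1, 0, 2, 1,
                1, 2, 0, 1,
                2, 1, 1, 0), 4, 4, byrow = TRUE)
  nn <- nearest_neighbors(d, 3)
  expect_equal(nn[1, ], c(2L, 3L, 4L)) # tie between 2 and 3 -> lower id
  expect_equal(nn[4, ], c(2L, 3L, 1L))
})
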