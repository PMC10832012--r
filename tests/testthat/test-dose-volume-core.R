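test_that("structure volume is voxel count times voxel volume", {
  g <- grid_geometry(spacing = 0.1, dim = c(20, 20, 20))
  occ <- array(FALSE, g$dim); occ[seq_len(1000)] <- TRUE
  expect_equal(structure_volume(structure_mask(occ, g, "S")), 1.0)

  g2 <- grid_geometry(spacing = 0.2, dim = c(10, 10, 10))
  expect_equal(structure_volume(structure_mask(array(TRUE, g2$dim), g2, "all")), 8.0)

  m <- random_mask(g, p = 0.4, seed = 7)
  expect_equal(structure_volume(m), oracle_volume(m))

  empty <- structure_mask(array(FALSE, g$dim), g, "Rectum")
  expect_error(structure_volume(empty), "Rectum")
})

test_that("overlap volume matches brute force and is symmetric", {
  g <- grid_geometry(spacing = 0.25, dim = c(12, 12, 12))
  a <- box_mask(g, c(1, 6), c(1, 12), c(1, 12), "a")
  b <- box_mask(g, c(7, 12), c(1, 12), c(1, 12), "b")
  expect_equal(overlap_volume(a, b), 0)

  inner <- box_mask(g, c(2, 4), c(2, 4), c(2, 4), "inner")
  outer_ <- box_mask(g, c(1, 8), c(1, 8), c(1, 8), "outer")
  expect_equal(overlap_volume(inner, outer_), structure_volume(inner))

  r1 <- random_mask(g, 0.5, seed = 1); r2 <- random_mask(g, 0.5, seed = 2)
  expect_equal(overlap_volume(r1, r2), oracle_overlap(r1, r2))
  expect_equal(overlap_volume(r1, r2), overlap_volume(r2, r1))
  expect_equal(overlap_volume(r1, r1), structure_volume(r1))
  expect_lte(overlap_volume(r1, r2),
             min(structure_volume(r1), structure_volume(r2)))

  g_other <- grid_geometry(spacing = 0.5, dim = c(12, 12, 12))
  expect_error(overlap_volume(r1, random_mask(g_other, 0.5, seed = 3)),
               "same voxel grid")
})

test_that("overlap fraction is the overlap normalized to the OAR volume", {
  g <- grid_geometry(spacing = 1, dim = c(10, 10, 10))  # 1 cc voxels
  ptv <- box_mask(g, c(1, 10), c(1, 10), c(1, 3), "PTV")
  oar_all_in <- box_mask(g, c(1, 5), c(1, 4), c(1, 2), "O1")
  expect_equal(overlap_fraction(oar_all_in, oar_all_in), 100)
  oar_out <- box_mask(g, c(1, 5), c(1, 4), c(5, 9), "O2")
  expect_equal(overlap_fraction(oar_out, ptv), 0)
  # 200 cc OAR with 30 cc inside the target -> 15%
  occ <- array(FALSE, g$dim)
  occ[1:10, 1:3, 3] <- TRUE               # 30 voxels inside the PTV (z 1:3)
  occ[1:10, 1:10, 4] <- TRUE              # 100 voxels outside
  occ[1:10, 1:7, 5] <- TRUE               # 70 voxels outside
  oar <- structure_mask(occ, g, "O3")
  expect_equal(structure_volume(oar), 200)
  expect_equal(overlap_fraction(oar, ptv), 15)
})

test_that("centroids and centroid distances match coordinate averages", {
  g <- grid_geometry(origin = c(0, 0, 0), spacing = 0.5, dim = c(11, 11, 11))
  single <- box_mask(g, c(1, 1), c(1, 1), c(1, 1), "pt")
  expect_equal(centroid(single), c(0, 0, 0), ignore_attr = TRUE)

  cub <- box_mask(g, c(3, 5), c(2, 6), c(1, 11), "cuboid")
  expect_equal(centroid(cub), c(1.5, 1.5, 2.5), ignore_attr = TRUE)

  m <- random_mask(g, 0.3, seed = 11)
  expect_equal(centroid(m), oracle_centroid(m), ignore_attr = TRUE)

  expect_equal(centroid_distance(m, m), 0)
  a <- box_mask(g, c(1, 1), c(1, 1), c(1, 1), "a")       # (0, 0, 0)
  b <- box_mask(g, c(7, 7), c(9, 9), c(1, 1), "b")       # (3, 4, 0)
  expect_equal(centroid_distance(a, b), 5)
  expect_equal(centroid_distance(a, b), centroid_distance(b, a))
  m2 <- random_mask(g, 0.3, seed = 12)
  expect_equal(centroid_distance(m, m2),
               sqrt(sum((oracle_centroid(m) - oracle_centroid(m2))^2)))
})

test_that("cumulative DVH honours its invariants and the voxel oracle", {
  g <- grid_geometry(spacing = 0.25, dim = c(10, 10, 10))
  m <- box_mask(g, c(2, 7), c(2, 7), c(2, 7), "S")

  dvh_u <- cumulative_dvh(uniform_dose(g, 50), m, bin_width = 1)
  expect_equal(dvh_u$cumulative_volume[dvh_u$bin_edges <= 50],
               rep(dvh_u$total_volume, sum(dvh_u$bin_edges <= 50)))
  expect_equal(dvh_u$cumulative_volume[dvh_u$bin_edges > 50],
               rep(0, sum(dvh_u$bin_edges > 50)))

  # two-voxel structure, doses 10 and 30 Gy
  occ <- array(FALSE, g$dim); occ[1:2] <- TRUE
  two <- structure_mask(occ, g, "two")
  d <- array(0, g$dim); d[1] <- 10; d[2] <- 30
  dvh2 <- cumulative_dvh(dose_grid(d, g), two, bin_width = 1)
  expect_equal(dvh2$cumulative_volume[dvh2$bin_edges == 20],
               prod(g$spacing))

  dg <- random_dose(g, seed = 5)
  dvh_r <- cumulative_dvh(dg, m, bin_width = 2)
  for (i in seq_along(dvh_r$bin_edges))
    expect_equal(dvh_r$cumulative_volume[i],
                 oracle_vdose(dg, m, dvh_r$bin_edges[i] - 1e-12, "cc"))
  expect_true(all(diff(dvh_r$cumulative_volume) <= 0))
  expect_equal(dvh_r$cumulative_volume[1], dvh_r$total_volume)
  expect_gte(max(dvh_r$bin_edges), max(dg$dose[m$occupancy]))
  expect_error(cumulative_dvh(dg, m, bin_width = 0), "bin_width")
})

test_that("v_dose counts voxels at or above the threshold", {
  g <- grid_geometry(spacing = 0.2, dim = c(15, 15, 15))
  m <- random_mask(g, 0.5, seed = 3)
  dg <- random_dose(g, seed = 4)
  expect_equal(v_dose(dg, m, 0, "percent"), 100)
  expect_equal(v_dose(dg, m, 0, "cc"), structure_volume(m))
  expect_equal(v_dose(dg, m, max(dg$dose) + 1, "cc"), 0)
  for (thr in c(10, 33.3, 60))
    expect_equal(v_dose(dg, m, thr, "cc"), oracle_vdose(dg, m, thr, "cc"))
  expect_equal(v_dose(dg, m, 40, "percent"), oracle_vdose(dg, m, 40, "percent"))
  # v_dose agrees with the binned DVH at every edge
  dvh <- cumulative_dvh(dg, m, bin_width = 0.5)
  sel <- seq(1, length(dvh$bin_edges), by = 7)
  for (i in sel)
    expect_equal(v_dose(dg, m, dvh$bin_edges[i], "cc"),
                 dvh$cumulative_volume[i], tolerance = 1e-12)
})

test_that("Dq% follows the hottest-q% rank convention", {
  # 100 equal-volume voxels with doses 1..100 Gy
  g <- grid_geometry(spacing = 1, dim = c(100, 1, 1))
  m <- structure_mask(array(TRUE, g$dim), g, "line")
  dg <- dose_grid(array(sample(1:100), g$dim), g)
  expect_equal(d_at_volume_percent(dg, m, 50), oracle_dq(dg, m, 50))
  expect_equal(d_at_volume_percent(dg, m, 50), 51)  # rank 50 of 100..1
  expect_equal(d_at_volume_percent(dg, m, 2), 99)
  expect_equal(d_at_volume_percent(dg, m, 100), 1)  # structure minimum

  gu <- grid_geometry(spacing = 0.3, dim = c(8, 8, 8))
  mu <- random_mask(gu, 0.6, seed = 9)
  for (q in c(2, 50, 95, 98, 100))
    expect_equal(d_at_volume_percent(uniform_dose(gu, 42.5), mu, q), 42.5)

  dgr <- random_dose(gu, seed = 10)
  qs <- c(1, 2, 25, 50, 75, 95, 98, 100)
  vals <- vapply(qs, function(q) d_at_volume_percent(dgr, mu, q), 0)
  expect_equal(vals, vapply(qs, function(q) oracle_dq(dgr, mu, q), 0))
  expect_true(all(diff(vals) <= 0))  # non-increasing in q
  expect_error(d_at_volume_percent(dgr, mu, 0), "q must be")
  expect_error(d_at_volume_percent(dgr, mu, 101), "q must be")
})

test_that("Dq% is the generalized inverse of v_dose", {
  g <- grid_geometry(spacing = 0.3, dim = c(10, 10, 10))
  m <- random_mask(g, 0.5, seed = 21)
  dg <- random_dose(g, seed = 22)
  for (q in c(5, 35, 50, 80, 95))
    expect_gte(v_dose(dg, m, d_at_volume_percent(dg, m, q), "percent"), q)
})

test_that("mean and max dose match brute-force loops", {
  g <- grid_geometry(spacing = 0.4, dim = c(12, 12, 12))
  m <- random_mask(g, 0.4, seed = 31)
  expect_equal(mean_dose(uniform_dose(g, 33), m), 33)
  expect_equal(max_dose(uniform_dose(g, 33), m), 33)

  occ <- array(FALSE, g$dim); occ[5] <- TRUE; occ[9] <- TRUE
  two <- structure_mask(occ, g, "two")
  d <- array(0, g$dim); d[5] <- 10; d[9] <- 30
  dg2 <- dose_grid(d, g)
  expect_equal(mean_dose(dg2, two), 20)
  expect_equal(max_dose(dg2, two), 30)

  dgr <- random_dose(g, seed = 32)
  expect_equal(mean_dose(dgr, m), oracle_mean(dgr, m), tolerance = 1e-12)
  expect_equal(max_dose(dgr, m), oracle_max(dgr, m))
})

test_that("metrics scale with dose and ignore voxel order", {
  g <- grid_geometry(spacing = 0.25, dim = c(10, 10, 10))
  m <- random_mask(g, 0.5, seed = 41)
  dg <- random_dose(g, seed = 42)
  k <- 1.7
  dgk <- dose_grid(dg$dose * k, g, dg$prescription_dose)
  expect_equal(mean_dose(dgk, m), k * mean_dose(dg, m))
  expect_equal(max_dose(dgk, m), k * max_dose(dg, m))
  expect_equal(d_at_volume_percent(dgk, m, 37), k * d_at_volume_percent(dg, m, 37))
  expect_equal(v_dose(dgk, m, k * 20, "cc"), v_dose(dg, m, 20, "cc"))

  perm <- kbpaudit:::with_seed(43, sample(prod(g$dim)))
  dgp <- dose_grid(array(dg$dose[perm], g$dim), g, dg$prescription_dose)
  mp <- structure_mask(array(m$occupancy[perm], g$dim), g, m$name)
  expect_equal(mean_dose(dgp, mp), mean_dose(dg, m))
  expect_equal(max_dose(dgp, mp), max_dose(dg, m))
  expect_equal(v_dose(dgp, mp, 25, "percent"), v_dose(dg, m, 25, "percent"))
  expect_equal(d_at_volume_percent(dgp, mp, 60), d_at_volume_percent(dg, m, 60))
})
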