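# Brute-force oracles: explicit voxel loops and sort-and-count, kept
# deliberately independent of the package's vectorized implementations.

oracle_count_voxels <- function(occ) {
  n <- 0L
  for (i in seq_along(occ)) if (occ[i]) n <- n + 1L
  n
}

oracle_volume <- function(mask) {
  oracle_count_voxels(mask$occupancy) * prod(mask$geometry$spacing)
}

oracle_overlap <- function(a, b) {
  n <- 0L
  oa <- a$occupancy; ob <- b$occupancy
  for (i in seq_along(oa)) if (oa[i] && ob[i]) n <- n + 1L
  n * prod(a$geometry$spacing)
}

oracle_vdose <- function(dose, mask, thr, unit = "cc") {
  d <- dose$dose
  idx <- which(mask$occupancy)
  n_hit <- 0L
  for (i in idx) if (d[i] >= thr) n_hit <- n_hit + 1L
  if (unit == "cc") n_hit * prod(mask$geometry$spacing)
  else 100 * n_hit / length(idx)
}

# dose at rank ceil(q/100 * N) of the descending sort, via ascending sort
oracle_dq <- function(dose, mask, q) {
  ds <- sort(dose$dose[mask$occupancy])
  n <- length(ds)
  ds[n - min(n, max(1L, as.integer(ceiling(q / 100 * n)))) + 1]
}

oracle_mean <- function(dose, mask) {
  d <- dose$dose
  idx <- which(mask$occupancy)
  s <- 0
  for (i in idx) s <- s + d[i]
  s / length(idx)
}

oracle_max <- function(dose, mask) {
  d <- dose$dose
  m <- -Inf
  for (i in which(mask$occupancy)) if (d[i] > m) m <- d[i]
  m
}

oracle_centroid <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  g <- mask$geometry
  pts <- matrix(0, nrow(idx), 3)
  for (r in seq_len(nrow(idx)))
    for (ax in 1:3)
      pts[r, ax] <- g$origin[ax] + (idx[r, ax] - 1) * g$spacing[ax]
  colMeans(pts)
}

# exhaustive two-sided Mann-Whitney p by enumerating all group labelings
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  picks <- utils::combn(na + nb, na)
  u_all <- apply(picks, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# fixtures -------------------------------------------------------------

random_mask <- function(geom, p = 0.3, name = "S", seed = 1) {
  occ <- kbpaudit:::with_seed(seed, array(runif(prod(geom$dim)) < p, geom$dim))
  if (!any(occ)) occ[1] <- TRUE
  structure_mask(occ, geom, name)
}

random_dose <- function(geom, max_gy = 80, seed = 2, prescription = 76) {
  d <- kbpaudit:::with_seed(seed, array(runif(prod(geom$dim), 0, max_gy), geom$dim))
  dose_grid(d, geom, prescription)
}

uniform_dose <- function(geom, gy, prescription = 76) {
  dose_grid(array(gy, geom$dim), geom, prescription)
}

# cuboid mask spanning index ranges (inclusive)
box_mask <- function(geom, xr, yr, zr, name = "box") {
  occ <- array(FALSE, geom$dim)
  occ[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  structure_mask(occ, geom, name)
}
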