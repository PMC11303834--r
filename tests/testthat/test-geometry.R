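test_that("centerline of an axis-aligned annulus is exact", {
  ph <- small_lv_phantom()
  cl <- estimate_centerline(ph$labels, label = 1)
  v <- ph$volume$voxel_size_um
  ctr <- c(47 / 2, 47 / 2) * v
  expect_equal(cl$origin[1:2], ctr, tolerance = 1e-9)
  expect_equal(abs(cl$direction), c(0, 0, 1), tolerance = 1e-12)
})

test_that("centerline recovers a tilted axis to within 0.5 degrees", {
  ax <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  ph <- generate_lv_phantom(lv_phantom_spec(
    shape = c(64, 64, 64), voxel_size_um = 20,
    inner_radius_um = 8 * 20, outer_radius_um = 14 * 20,
    axis = ax, height_um = 700))
  cl <- estimate_centerline(ph$labels, label = 1)
  expect_lt(angle_between(cl$direction, ax), 0.5)
})

test_that("an empty mid-stack slice is skipped without changing the axis", {
  ph <- small_lv_phantom()
  lum <- unclass(ph$labels) == 1L
  cl_full <- estimate_centerline(lum, voxel_size_um = 20)
  lum2 <- lum
  lum2[24, , ] <- FALSE
  cl_skip <- estimate_centerline(lum2, voxel_size_um = 20)
  expect_equal(cl_skip$direction, cl_full$direction, tolerance = 1e-9)
  expect_equal(cl_skip$origin[1:2], cl_full$origin[1:2], tolerance = 1e-9)
  # too few usable slices errors
  lum3 <- lum
  lum3[-(1:2), , ] <- FALSE
  expect_error(estimate_centerline(lum3, voxel_size_um = 20), ">= 3")
})

test_that("the cylindrical frame is right-handed, orthonormal, and excludes the axis", {
  cl <- centerline(c(0, 0, 0), c(0, 0, 1))
  # axis-aligned case: voxel on +x axis
  fr <- local_cylindrical_frame(matrix(c(50, 0, 0), 1), cl, min_radius_um = 20)
  expect_equal(drop(fr$r_hat), c(1, 0, 0))
  expect_equal(drop(fr$c_hat), c(0, 1, 0))
  expect_equal(drop(fr$z_hat), c(0, 0, 1))

  # random voxels: orthonormal right-handed triads
  set.seed(4)
  pts <- matrix(rnorm(3000, sd = 500), ncol = 3)
  fr <- local_cylindrical_frame(pts, cl, min_radius_um = 1)
  ok <- fr$valid
  expect_gt(sum(ok), 990)
  for (m in list(fr$r_hat, fr$c_hat, fr$z_hat))
    expect_lt(max(abs(rowSums(m[ok, ]^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$r_hat[ok, ] * fr$c_hat[ok, ]))), 1e-9)
  expect_lt(max(abs(rowSums(fr$r_hat[ok, ] * fr$z_hat[ok, ]))), 1e-9)
  cross <- cbind(
    fr$r_hat[ok, 2] * fr$c_hat[ok, 3] - fr$r_hat[ok, 3] * fr$c_hat[ok, 2],
    fr$r_hat[ok, 3] * fr$c_hat[ok, 1] - fr$r_hat[ok, 1] * fr$c_hat[ok, 3],
    fr$r_hat[ok, 1] * fr$c_hat[ok, 2] - fr$r_hat[ok, 2] * fr$c_hat[ok, 1])
  expect_lt(max(abs(cross - fr$z_hat[ok, ])), 1e-9)

  # on-axis exclusion: half a voxel off the axis is undefined
  fr0 <- local_cylindrical_frame(matrix(c(10, 0, 100), 1), cl,
                                 min_radius_um = 20)
  expect_false(fr0$valid)
  expect_true(all(is.nan(fr0$r_hat)))
})

test_that("helix angle hits the defining special cases", {
  # hand-built orientation field on a tiny grid with axis +z through origin
  d <- c(8, 8, 8)
  mk_orient <- function(vec_fun) {
    vectors <- array(NaN, c(d, 3))
    valid <- array(FALSE, d)
    for (iz in 1:8) for (iy in 1:8) for (ix in 1:8) {
      p <- c(ix - 1, iy - 1, iz - 1) * 10
      rho <- sqrt(p[1]^2 + p[2]^2)
      if (rho < 15) next
      rhat <- c(p[1], p[2], 0) / rho
      chat <- c(-rhat[2], rhat[1], 0)
      vv <- vec_fun(chat, c(0, 0, 1))
      vectors[iz, iy, ix, ] <- vv
      valid[iz, iy, ix] <- TRUE
    }
    structure(list(vectors = vectors,
                   eigenvalues = list(l1 = array(1, d), l2 = array(0.5, d),
                                      l3 = array(0, d)),
                   valid = valid, voxel_size_um = 10),
              class = "orientation_field")
  }
  cl <- centerline(c(0, 0, 0), c(0, 0, 1))

  circ <- compute_helix_angle_map(mk_orient(function(c_, z_) c_), cl)
  expect_equal(max(abs(circ[!is.nan(circ)])), 0)

  long <- compute_helix_angle_map(mk_orient(function(c_, z_) z_), cl)
  expect_equal(min(abs(long[!is.nan(long)])), 90)

  mid <- compute_helix_angle_map(
    mk_orient(function(c_, z_) (c_ + z_) / sqrt(2)), cl)
  expect_equal(unique(round(mid[!is.nan(mid)], 9)), 45)

  # purely radial fibers are never assigned an angle
  rad <- compute_helix_angle_map(
    mk_orient(function(c_, z_) c(c_[2], -c_[1], 0)), cl)
  expect_true(all(is.nan(rad)))
})

test_that("helix angle is sign-invariant under fiber flips", {
  ph <- small_lv_phantom(noise_sd = 3)
  o <- estimate_orientation(ph$volume)
  cl <- estimate_centerline(ph$labels, label = 1)
  h1 <- compute_helix_angle_map(o, cl, mask = ph$labels == 2L)
  o2 <- o
  o2$vectors <- -o$vectors
  h2 <- compute_helix_angle_map(o2, cl, mask = ph$labels == 2L)
  expect_identical(unclass(h1), unclass(h2))
})

test_that("helix map recovers the prescribed transmural law on the phantom", {
  ph <- small_lv_phantom(noise_sd = 0)
  o <- estimate_orientation(ph$volume)
  cl <- estimate_centerline(ph$labels, label = 1)
  hm <- compute_helix_angle_map(o, cl, mask = ph$labels == 2L)
  err <- abs(unclass(hm) - ph$truth$alpha_deg)
  # thin-wall fixture: sanity bound (see orientation recovery test)
  expect_lt(median(err[!is.nan(err)]), 10)
  dep <- transmural_depth(ph$labels == 2L, ph$labels == 1L, ph$labels == 0L)
  prof <- transmural_profile(hm, dep)
  expect_true(all(prof$n > 0))
  expect_true(all(diff(prof$median_deg) < 0))
})

test_that("constant-law phantoms recover their mean helix angle", {
  # full-radius wall (the tensor-smoothing curvature bias shrinks with
  # radius) with a reduced axial extent to keep the run fast
  for (A in c(-60, 0, 60)) {
    ph <- generate_lv_phantom(lv_phantom_spec(
      shape = c(48, 128, 128), voxel_size_um = 20,
      inner_radius_um = 600, outer_radius_um = 1100,
      alpha_endo_deg = A, alpha_epi_deg = A, noise_sd = 5, seed = 3))
    o <- estimate_orientation(ph$volume)
    cl <- estimate_centerline(ph$labels, label = 1)
    hm <- compute_helix_angle_map(o, cl, mask = ph$labels == 2L)
    expect_lt(abs(mean(hm[!is.nan(hm)]) - A), 2)
  }
})

test_that("helix map is stable under rotation of volume and centerline together", {
  ph <- small_lv_phantom(noise_sd = 0)
  d <- dim(ph$labels)
  rot <- function(a) aperm(a, c(1, 3, 2))[, , rev(seq_len(d[2]))]
  vol2 <- image_volume(rot(ph$volume$data), 20)
  lab2 <- label_map(rot(unclass(ph$labels)), 20)
  h1 <- compute_helix_angle_map(estimate_orientation(ph$volume),
                                estimate_centerline(ph$labels, label = 1),
                                mask = ph$labels == 2L)
  h2 <- compute_helix_angle_map(estimate_orientation(vol2),
                                estimate_centerline(lab2, label = 1),
                                mask = lab2 == 2L)
  # compare per-voxel through the rotation map
  idx <- which(!is.nan(unclass(h1)), arr.ind = TRUE)
  set.seed(6)
  idx <- idx[sample(nrow(idx), 400), , drop = FALSE]
  v1 <- h1[idx]
  idx2 <- cbind(idx[, 1], idx[, 3], d[2] + 1 - idx[, 2])
  v2 <- h2[idx2]
  ok <- !is.nan(v2)
  expect_gt(mean(ok), 0.9)
  expect_lt(median(abs(v1[ok] - v2[ok])), 1)
})

test_that("transmural depth is 0/1 at the surfaces and monotone along rays", {
  ph <- small_lv_phantom()
  wall <- ph$labels == 2L
  dep <- transmural_depth(wall, ph$labels == 1L, ph$labels == 0L)
  expect_true(all(dep[wall] >= 0 & dep[wall] <= 1))
  # monotone along radial rays: follow +x from the inner surface at mid-z
  iz <- 24; iy <- 24
  line <- dep[iz, iy, ]
  inwall <- which(!is.nan(line) & seq_along(line) > 24)
  expect_true(all(diff(line[inwall]) >= 0))
  expect_lt(line[inwall[1]], 0.25)
  expect_gt(line[inwall[length(inwall)]], 0.75)
})
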