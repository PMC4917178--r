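ref <- reference_spacing()

test_that("derivative maps agree with finite-difference oracles to 1e-6", {
  set.seed(11)
  m <- matrix(runif(28 * 26, 0, 255), 28, 26)
  st <- image_stack(m, ref)
  o <- oracle_derivs(m, 1.5)
  expect_lt(max(abs(gauss_gradient_magnitude(st, 1.5)[, , 1] -
                      sqrt(o$ix^2 + o$iy^2))), 1e-6)
  expect_lt(max(abs(laplacian_positive(st, 1.5)[, , 1] -
                      pmax(o$ixx + o$iyy, 0))), 1e-6)
  expect_lt(max(abs(hessian_det_negative_abs(st, 1.5)[, , 1] -
                      abs(pmin(o$ixx * o$iyy - o$ixy^2, 0)))), 1e-6)
})

test_that("derivative maps reproduce closed forms on analytic surfaces", {
  n <- 41L
  xs <- matrix(rep(1:n, each = n), n, n)          # I = 3x (pixel units)
  ys <- matrix(rep(1:n, n), n, n)
  interior <- 8:(n - 8)

  ramp <- image_stack(3 * xs, ref)
  gm <- gauss_gradient_magnitude(ramp, 1.5)[interior, interior, 1]
  expect_true(all(abs(gm - 3) < 0.03))

  const <- image_stack(matrix(9, n, n), ref)
  expect_true(all(gauss_gradient_magnitude(const, 1.5) == 0))

  bowl <- image_stack((xs - 21)^2 + (ys - 21)^2, ref)   # laplacian = 4
  lp <- laplacian_positive(bowl, 1.5)[interior, interior, 1]
  expect_true(all(abs(lp - 4) < 0.04))
  expect_true(all(hessian_det_negative_abs(bowl, 1.5)[interior, interior, 1] < 1e-8))

  dome_vals <- 2 * 21^2 - ((xs - 21)^2 + (ys - 21)^2)   # negative laplacian
  expect_true(all(laplacian_positive(image_stack(dome_vals, ref), 1.5)[interior, interior, 1] < 1e-8))

  saddle_vals <- (xs - 21) * (ys - 21) + 21^2           # det H = -1
  hd <- hessian_det_negative_abs(image_stack(saddle_vals, ref), 1.5)[interior, interior, 1]
  expect_true(all(abs(hd - 1) < 0.02))
})

test_that("the tanh mask has its closed form, monotonicity and steepness", {
  z <- array(0, c(6, 6, 2))
  derivs <- list(gradmag = z, lap_pos = z, hess_negabs = z)
  m0 <- masking_function(derivs, mask_params())
  expect_equal(max(abs(m0 - (1 + tanh(1)) / 2)), 0, tolerance = 1e-12)

  set.seed(12)
  base <- array(runif(72, 0, 5), c(6, 6, 2))
  d1 <- list(gradmag = base, lap_pos = z, hess_negabs = z)
  d2 <- list(gradmag = 2 * base, lap_pos = base, hess_negabs = z)  # S2 >= S1 after norm
  m1 <- masking_function(d1); m2 <- masking_function(d2)
  expect_true(all(m1 >= m2 - 1e-12))
  expect_true(all(m1 > 0 & m1 < 1))

  # doubling gamma with delta = 0 pushes every value further from 1/2
  g1 <- masking_function(d1, mask_params(gamma = 1, delta = 0))
  g2 <- masking_function(d1, mask_params(gamma = 2, delta = 0))
  expect_true(all(abs(g2 - 0.5) >= abs(g1 - 0.5) - 1e-12))
})

test_that("apply_mask is an exact voxelwise product", {
  set.seed(13)
  v <- array(runif(125, 0, 255), c(5, 5, 5))
  st <- image_stack(v, ref)
  expect_equal(apply_mask(st, array(1, dim(v)))$voxels, v)
  expect_equal(apply_mask(st, array(0.5, dim(v)))$voxels, v / 2)
  msk <- array(runif(125), c(5, 5, 5))
  expect_identical(apply_mask(st, msk)$voxels, v * msk)
  expect_error(apply_mask(st, array(1, c(5, 5, 4))), "dimensions")
})

test_that("per-slice Otsu matches the exhaustive variance-maximization oracle", {
  half <- matrix(c(rep(10, 128), rep(200, 128)), 16, 16)
  st <- image_stack(half, ref)
  bin <- otsu_threshold_slices(st)
  expect_identical(bin[, , 1] == 1L, half > 10)

  expect_true(all(otsu_threshold_slices(image_stack(matrix(4, 8, 8), ref)) == 0L))

  set.seed(14)
  for (i in 1:5) {
    sl <- matrix(c(rnorm(150, 40, 12), rnorm(106, 170, 25)), 16, 16)
    sl <- pmax(sl, 0)
    expect_equal(otsu_threshold(sl), oracle_otsu(sl))
  }
})

test_that("3D connected components match a BFS flood-fill oracle", {
  cube <- array(0L, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 1L
  obj <- connected_components_3d(cube, ref)
  expect_length(obj, 1)
  expect_equal(obj[[1]]$volume, 27L)
  expect_equal(obj[[1]]$centroid_um, (c(4, 4, 4) - 0.5) * as.numeric(ref))

  two <- array(0L, c(9, 9, 9))
  two[2:3, 2:3, 2:3] <- 1L; two[7:8, 7:8, 7:8] <- 1L
  expect_length(connected_components_3d(two, ref), 2)

  set.seed(15)
  for (conn in c(26, 6)) {
    bin <- array(as.integer(runif(11 * 10 * 6) < 0.2), c(11, 10, 6))
    objs <- connected_components_3d(bin, ref, conn)
    got <- lapply(objs, function(o)
      sort(unname(o$voxels[, "y"] + 11L * (o$voxels[, "x"] - 1L) +
                    110L * (o$voxels[, "z"] - 1L))))
    want <- oracle_components(bin, conn)
    expect_setequal(got, want)
  }
})

test_that("small-object removal drops only sub-threshold volumes", {
  mk <- function(v) list(object_id = 1L, voxels = matrix(1L, v, 3,
                                                         dimnames = list(NULL, c("x", "y", "z"))),
                         volume = v, centroid_um = c(0, 0, 0))
  objs <- lapply(c(5, 9, 10, 50), mk)
  expect_equal(vapply(remove_small_objects(objs, 10), `[[`, numeric(1), "volume"),
               c(10, 50))
  expect_equal(remove_small_objects(list(), 10), list())
  expect_length(remove_small_objects(objs, 0), 4)
})

test_that("ds_segment finds isolated nuclei near their true centers and is deterministic", {
  sc <- separated_scene(seed = 21, n = 5)
  res <- ds_segment(sc$stack, benchmark_params()$denoise, benchmark_params()$mask)
  expect_length(res$objects, 5)
  cen <- t(vapply(res$objects, `[[`, numeric(3), "centroid_um"))
  m <- match_centroids(sc$truth, cen, 2)
  expect_equal(nrow(m$pairs), 5L)

  res2 <- ds_segment(sc$stack, benchmark_params()$denoise, benchmark_params()$mask)
  expect_identical(res$label_mask, res2$label_mask)

  zero <- image_stack(array(0, c(10, 10, 5)), ref)
  expect_length(ds_segment(zero)$objects, 0)
})

test_that("raising alpha erodes segmented volumes (volume-histogram mode falls)", {
  sc <- separated_scene(seed = 22, n = 5)
  modes <- sapply(c(1, 2), function(a) {
    res <- ds_segment(sc$stack, benchmark_params()$denoise,
                      mask_params(alpha = a, sigma_g = 1.1))
    vols <- vapply(res$objects, `[[`, integer(1), "volume")
    bins <- table(floor(vols / 10))
    (as.integer(names(bins)[which.max(bins)]) + 0.5) * 10
  })
  expect_lt(modes[2], modes[1])
})
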