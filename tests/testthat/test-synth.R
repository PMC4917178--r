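ref <- reference_spacing()

test_that("scene sampling realizes the exact count and stays in bounds", {
  sc <- sample_scene(c(50, 50, 50), 2e-3, seed = 51)
  expect_equal(nrow(sc), 250L)
  expect_true(all(sc$cx >= 0 & sc$cx <= 50 & sc$cy >= 0 & sc$cy <= 50 &
                    sc$cz >= 0 & sc$cz <= 50))
  expect_true(all(abs(sqrt(sc$ux^2 + sc$uy^2 + sc$uz^2) - 1) < 1e-9))
  expect_error(sample_scene(c(5, 5, 5), 1e-6, seed = 1), "no nuclei")
})

test_that("nematic order has its closed forms and Monte-Carlo limits", {
  zhat <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_equal(nematic_order(zhat), 1)
  two <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(nematic_order(two), 0.25)
  set.seed(52)
  g <- matrix(rnorm(3e5), ncol = 3)
  expect_lt(nematic_order(g / sqrt(rowSums(g^2))), 0.01)
  expect_error(nematic_order(matrix(0, 2, 3)), "zero-length")
})

test_that("orientation concentration hits the alignment target", {
  al1 <- sample_scene(c(40, 40, 40), 1.5e-3, alignment_target = 1, seed = 53)
  u <- as.matrix(al1[, c("ux", "uy", "uz")])
  expect_equal(nematic_order(u), 1)
  expect_true(all(abs(abs(u %*% c(1, 0, 0)) - 1) < 1e-9))

  set.seed(54)
  u0 <- dsseg:::.sample_orientations(1e4, 0)
  expect_lt(nematic_order(u0), 0.05)

  for (target in c(0.3, 0.67, 0.9)) {
    set.seed(55)
    ut <- dsseg:::.sample_orientations(2000, target)
    expect_lt(abs(nematic_order(ut) - target), 0.05)
  }
})

test_that("rendered nuclear intensities realize SNR = sqrt(shape)", {
  expect_equal(intensity_model(5)$nucleus_gamma_shape, 25)
  expect_error(intensity_model(5, nucleus_mean = 10, background_mean = 50),
               "exceed")
  big <- data.frame(cx = c(16, 16), cy = c(16, 48), cz = 16,
                    a = 13, b = 13, c = 13, ux = 1, uy = 0, uz = 0)
  attr(big, "size_um") <- c(32, 64, 32)
  sc <- render_scene(big, intensity_model(5), ref, seed = 56)
  # recover nuclear voxels from the known geometry
  d <- dim(sc$stack$voxels); sp <- as.numeric(ref)
  g <- expand.grid(y = 1:d[1], x = 1:d[2], z = 1:d[3])
  px <- (g$x - 0.5) * sp[1]; py <- (g$y - 0.5) * sp[2]; pz <- (g$z - 0.5) * sp[3]
  inside <- ((px - 16)^2 + (py - 16)^2 + (pz - 16)^2 <= 144) |
    ((px - 16)^2 + (py - 48)^2 + (pz - 16)^2 <= 144)   # 1 um inside the surface
  vals <- sc$stack$voxels[cbind(g$y, g$x, g$z)][inside]
  expect_gt(length(vals), 1e4)
  expect_lt(abs(mean(vals) / sd(vals) - 5), 0.2)
})

test_that("ellipsoid voxelization recovers the analytic sphere volume within 10%", {
  one <- data.frame(cx = 10, cy = 10, cz = 10, a = 4, b = 4, c = 4,
                    ux = 0, uy = 0, uz = 1)
  attr(one, "size_um") <- c(20, 20, 20)
  sc <- render_scene(one, intensity_model(5), ref, seed = 57)
  d <- dim(sc$stack$voxels); sp <- as.numeric(ref)
  g <- expand.grid(y = 1:d[1], x = 1:d[2], z = 1:d[3])
  inside <- ((g$x - 0.5) * sp[1] - 10)^2 + ((g$y - 0.5) * sp[2] - 10)^2 +
    ((g$z - 0.5) * sp[3] - 10)^2 <= 16
  analytic <- (4 / 3) * pi * 64 / prod(sp)
  expect_lt(abs(sum(inside) - analytic) / analytic, 0.1)

  none <- one[0, ]; attr(none, "size_um") <- c(20, 20, 20)
  bg <- render_scene(none, intensity_model(5), ref, seed = 57)
  expect_lt(mean(bg$stack$voxels), 40)   # pure background, mean ~25
})

test_that("generation is seed-deterministic and ground truth round trips", {
  s1 <- render_scene(sample_scene(c(30, 30, 30), 1.5e-3, seed = 58),
                     intensity_model(5), ref, seed = 59)
  s2 <- render_scene(sample_scene(c(30, 30, 30), 1.5e-3, seed = 58),
                     intensity_model(5), ref, seed = 59)
  expect_identical(s1$stack$voxels, s2$stack$voxels)

  prefix <- file.path(withr::local_tempdir(), "scene")
  save_ground_truth(s1, prefix)
  truth <- read_ground_truth(paste0(prefix, "_truth.csv"))
  expect_equal(truth$cx, s1$nuclei$cx, tolerance = 1e-12)
  expect_equal(truth$ux, s1$nuclei$ux, tolerance = 1e-12)
  man <- jsonlite::read_json(paste0(prefix, "_manifest.json"))
  expect_equal(man$scene_seed, 58)
  expect_equal(man$render_seed, 59)
  # the manifest suffices to regenerate the identical stack
  s3 <- render_scene(sample_scene(unlist(man$size_um), man$density,
                                  seed = man$scene_seed),
                     intensity_model(5), ref, seed = man$render_seed)
  expect_identical(s3$stack$voxels, s1$stack$voxels)
  back <- read_stack(paste0(prefix, ".tif"), ref)
  expect_identical(back$voxels, s1$stack$voxels)
})
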