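ref <- reference_spacing()

test_that("FOV threshold uses the population standard deviation", {
  vs <- compute_fov_threshold(rep(100, 7), 3)
  expect_equal(vs$fov_threshold, 100)
  vs <- compute_fov_threshold(c(90, 110), 2)
  expect_equal(vs$std_volume, 10)
  expect_equal(vs$fov_threshold, 120)
  expect_error(compute_fov_threshold(numeric(0)), "empty")
})

test_that("axis profiles count voxels per coordinate and conserve volume", {
  cube_vox <- as.matrix(expand.grid(x = 4:6, y = 2:4, z = 7:9))
  obj <- list(object_id = 1L, voxels = cube_vox, volume = 27L)
  profs <- axis_profiles(obj)
  for (ax in c("x", "y", "z")) {
    expect_equal(profs[[ax]]$counts, c(9, 9, 9))
    expect_equal(sum(profs[[ax]]$counts), 27)
  }

  set.seed(31)
  vox <- unique(cbind(x = sample(1:30, 300, TRUE), y = sample(1:30, 300, TRUE),
                      z = sample(1:10, 300, TRUE)))
  robj <- list(object_id = 1L, voxels = vox, volume = nrow(vox))
  expect_true(all(vapply(axis_profiles(robj), function(p) sum(p$counts),
                         numeric(1)) == nrow(vox)))
})

test_that("peak counting follows the prominence/valley rule", {
  expect_equal(count_peaks(c(1, 2, 3, 4, 5)), 1L)     # monotone
  expect_equal(count_peaks(rep(4, 9)), 1L)            # flat
  expect_equal(count_peaks(c(1, 5, 1, 5, 1), 0.2), 2L)
  expect_equal(count_peaks(c(1, 5, 4.9, 5, 1), 0.2), 1L)  # shallow valley
  # sub-prominence bumps are ignored
  expect_equal(count_peaks(c(0.5, 1, 0.2, 100, 0.2, 1, 0.5), 0.2), 1L)
  # a solid sphere's profiles are unimodal on every axis
  ball <- sphere_union_object(matrix(c(8, 8, 8), 1), 4)
  expect_true(all(vapply(axis_profiles(ball), count_peaks, integer(1)) == 1L))
})

test_that("mnp counts fused nuclei along one axis but saturates on 2x2 sheets", {
  single <- sphere_union_object(matrix(c(8, 8, 8), 1), 2.75)
  expect_equal(estimate_mnp(single)$mnp, 1L)

  three_z <- sphere_union_object(
    rbind(c(8, 8, 5), c(8, 8, 10.5), c(8, 8, 16)), 2.75)
  est <- estimate_mnp(three_z, spacing = ref)
  expect_equal(est$peaks[["z"]], 3L)
  expect_equal(est$mnp, 3L)

  sheet <- sphere_union_object(
    rbind(c(8, 8, 8), c(13.5, 8, 8), c(8, 13.5, 8), c(13.5, 13.5, 8)), 2.75)
  expect_equal(estimate_mnp(sheet, spacing = ref)$mnp, 2L)   # known limitation
})

test_that("micron conversion uses voxel centers and the anisotropic spacing", {
  obj <- list(voxels = cbind(x = c(1L, 2L, 1L), y = c(1L, 1L, 1L),
                             z = c(1L, 1L, 2L)))
  pts <- to_micron_points(obj, ref)
  expect_equal(pts[1, ], c(0.3455, 0.3455, 0.875), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pts[2, 1] - pts[1, 1], 0.691, ignore_attr = TRUE)
  expect_equal(pts[3, 3] - pts[1, 3], 1.75, ignore_attr = TRUE)
  expect_equal(nrow(pts), 3L)
})

test_that("K-means splitting is conservative, seeded and leaves singles alone", {
  single <- sphere_union_object(matrix(c(8, 8, 8), 1), 3.5)
  sr <- kmeans_split(single, ref, seed = 1)
  expect_equal(sr$selected_k, 1L)
  expect_equal(sr$children[[1]]$centroid_um, single$centroid_um)

  pair <- sphere_union_object(rbind(c(9, 9, 6), c(9, 9, 14)), 4)
  sr2 <- kmeans_split(pair, ref, seed = 1)
  expect_equal(sr2$selected_k, 2L)
  cen <- t(vapply(sr2$children, `[[`, numeric(3), "centroid_um"))
  m <- match_centroids(rbind(c(9, 9, 6), c(9, 9, 14)), cen, 2)
  expect_equal(nrow(m$pairs), 2L)
  # conservation: children partition the parent voxel multiset
  child_vox <- do.call(rbind, lapply(sr2$children, `[[`, "voxels"))
  expect_setequal(unname(split(unname(child_vox), row(child_vox))),
                  unname(split(unname(pair$voxels), row(pair$voxels))))
  # seeded determinism
  sr3 <- kmeans_split(pair, ref, seed = 1)
  expect_identical(lapply(sr2$children, `[[`, "voxels"),
                   lapply(sr3$children, `[[`, "voxels"))
})

test_that("the GMM log-likelihood and AIC match closed-form hand computations", {
  expect_equal(gmm_aic(-120.5, 2, 3), 2 * 19 - 2 * (-120.5))
  expect_equal(gmm_aic(0, 1, 3), 2 * 9)

  set.seed(32)
  pts <- matrix(rnorm(60 * 3, sd = 2), 60, 3)
  fit <- dsseg:::.gmm_em(pts, 1, seed = 5)
  mu <- colMeans(pts)
  sig <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) + diag(1e-6, 3)
  expect_equal(fit$loglik, sum(mvtnorm::dmvnorm(pts, mu, sig, log = TRUE)),
               tolerance = 1e-8)

  fit2 <- dsseg:::.gmm_em(pts, 2, seed = 5)
  hand <- sum(log(rowSums(vapply(1:2, function(j)
    fit2$pi[j] * mvtnorm::dmvnorm(pts, fit2$mu[j, ], fit2$sigma[[j]]),
    numeric(nrow(pts))))))
  expect_equal(fit2$loglik, hand, tolerance = 1e-6)
})

test_that("GMM+AIC keeps singles whole and splits a fused triple into three", {
  single <- sphere_union_object(matrix(c(8, 8, 8), 1), 3.5)
  sr <- gmm_aic_split(single, ref, seed = 1)
  expect_equal(sr$selected_k, 1L)
  expect_equal(which.min(sr$aic_values), 1L)
  expect_equal(sr$children[[1]]$centroid_um, single$centroid_um)

  centers <- rbind(c(8, 8, 5), c(8, 8, 10.5), c(8, 8, 16))
  triple <- sphere_union_object(centers, 2.75)
  sr3 <- gmm_aic_split(triple, ref, seed = 1)
  expect_equal(length(sr3$children), 3L)
  cen <- t(vapply(sr3$children, `[[`, numeric(3), "centroid_um"))
  expect_equal(nrow(match_centroids(centers, cen, 2)$pairs), 3L)
  child_vox <- do.call(rbind, lapply(sr3$children, `[[`, "voxels"))
  expect_equal(nrow(child_vox), triple$volume)
})

test_that("post-processing conserves voxels, relabels, and respects the FOV gate", {
  sc <- separated_scene(seed = 33, n = 5)
  res <- ds_segment(sc$stack, benchmark_params()$denoise, benchmark_params()$mask)

  # huge n: nothing is post-processed
  un <- postprocess_all(res, n_weight = 1e9, method = "kmeans", seed = 1)
  expect_equal(vapply(un$objects, `[[`, integer(1), "volume"),
               vapply(res$objects, `[[`, integer(1), "volume"))

  for (method in c("kmeans", "gmm", "watershed")) {
    post <- postprocess_all(res, n_weight = 0.5, method = method, seed = 1)
    expect_equal(sum(post$label_mask > 0), sum(res$label_mask > 0))
    expect_equal(sort(unique(as.integer(post$label_mask[post$label_mask > 0]))),
                 seq_along(post$objects))
    # identity on isolated nuclei up to relabelling: centroids unchanged
    cen_pre <- t(vapply(res$objects, `[[`, numeric(3), "centroid_um"))
    cen_post <- t(vapply(post$objects, `[[`, numeric(3), "centroid_um"))
    m <- match_centroids(cen_pre, cen_post, 2)
    expect_equal(nrow(m$pairs), length(res$objects))
    expect_lt(max(m$pairs$distance_um), 0.6)
  }
})

test_that("decreasing n sends a superset of objects for post-processing", {
  set.seed(34)
  vols <- c(rpois(40, 150), rpois(10, 700))
  sent <- lapply(c(2, 1, 0), function(n)
    which(vols > compute_fov_threshold(vols, n)$fov_threshold))
  expect_true(all(sent[[1]] %in% sent[[2]]))
  expect_true(all(sent[[2]] %in% sent[[3]]))
})
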