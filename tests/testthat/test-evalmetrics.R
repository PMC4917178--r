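test_that("centroid matching handles the degenerate and exact cases", {
  pts <- matrix(runif(15, 0, 30), 5, 3)
  m <- match_centroids(pts, pts, 2)
  expect_equal(nrow(m$pairs), 5L)
  expect_lt(max(m$pairs$distance_um), 1e-9)
  expect_length(m$misses, 0)

  far <- pts + 10
  m2 <- match_centroids(pts, far, 2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$misses, 1:5)
  expect_equal(m2$false_detections, 1:5)

  m3 <- match_centroids(pts, matrix(numeric(0), 0, 3), 2)
  expect_equal(m3$misses, 1:5)
})

test_that("Hungarian matching equals the brute-force oracle on small instances", {
  set.seed(61)
  for (i in 1:20) {
    nt <- sample(1:6, 1); nd <- sample(1:6, 1)
    truth <- matrix(runif(nt * 3, 0, 8), nt, 3)
    det <- matrix(runif(nd * 3, 0, 8), nd, 3)
    m <- match_centroids(truth, det, 2)
    want <- oracle_match(truth, det, 2)
    expect_equal(nrow(m$pairs), want$pairs)
    expect_equal(sum(m$pairs$distance_um), want$cost, tolerance = 1e-9)
  }
})

test_that("matching is cost-symmetric and metrics are translation invariant", {
  set.seed(62)
  truth <- matrix(runif(18, 0, 12), 6, 3)
  det <- matrix(runif(15, 0, 12), 5, 3)
  m_fwd <- match_centroids(truth, det, 2)
  m_rev <- match_centroids(det, truth, 2)
  expect_equal(nrow(m_fwd$pairs), nrow(m_rev$pairs))
  expect_equal(sum(m_fwd$pairs$distance_um), sum(m_rev$pairs$distance_um))
  expect_equal(m_fwd$misses, m_rev$false_detections)
  expect_equal(m_fwd$false_detections, m_rev$misses)

  shift <- c(5, -3, 2)
  m_shift <- match_centroids(sweep(truth, 2, -shift), sweep(det, 2, -shift), 2)
  expect_equal(score(m_shift)$sensitivity, score(m_fwd)$sensitivity)
  expect_equal(score(m_shift)$precision, score(m_fwd)$precision)
})

test_that("sensitivity and precision follow their defining ratios", {
  set.seed(63)
  truth <- matrix(runif(30, 0, 20), 10, 3)
  det <- rbind(truth[1:8, ] + matrix(rnorm(24, 0, 0.2), 8, 3),
               matrix(100 + runif(6), 2, 3))
  r <- score(match_centroids(truth, det, 2))
  expect_equal(r$n_correct, 8L)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$n_correct + length(match_centroids(truth, det, 2)$misses),
               r$n_true)

  none <- score(match_centroids(truth, matrix(numeric(0), 0, 3), 2))
  expect_equal(none$sensitivity, 0)
  expect_true(none$degenerate)
  empty <- score(match_centroids(matrix(numeric(0), 0, 3), truth, 2))
  expect_equal(empty$sensitivity, 1)
  expect_true(empty$degenerate)
})

test_that("chimera scoring treats the sparse channel as truth", {
  set.seed(64)
  dense <- matrix(runif(90, 0, 30), 30, 3)
  sparse <- dense[sample(30, 5), ] + matrix(rnorm(15, 0, 0.2), 5, 3)
  r <- chimera_sensitivity(sparse, dense, 2)
  expect_equal(r$sensitivity, 1)
  expect_true(is.na(r$precision))
  r0 <- chimera_sensitivity(matrix(numeric(0), 0, 3), dense, 2)
  expect_true(r0$degenerate)
})

test_that("sweeps are deterministic under a fixed seed", {
  a <- run_density_sweep(1.5e-3, snr = 5, methods = c("ds", "kmeans"),
                         replicates = 1, seed = 9, size_um = c(25, 25, 25))
  b <- run_density_sweep(1.5e-3, snr = 5, methods = c("ds", "kmeans"),
                         replicates = 1, seed = 9, size_um = c(25, 25, 25))
  expect_identical(a, b)
  expect_true(all(c("density", "method", "sensitivity", "precision") %in% names(a)))
  s <- summarize_sweep(a)
  expect_equal(nrow(s), 2L)
})

test_that("the n-weight sweep reduces to DS alone for huge n", {
  tab <- run_n_weight_sweep(c(1e9, 0), density = 2e-3, replicates = 1,
                            seed = 11, size_um = c(25, 25, 25))
  ds <- run_density_sweep(2e-3, methods = "ds", replicates = 1, seed = 11,
                          size_um = c(25, 25, 25))
  expect_equal(tab$sensitivity[tab$n_weight == 1e9], ds$sensitivity)
  expect_equal(tab$n_sent[tab$n_weight == 1e9], 0L)
  expect_gte(tab$n_sent[tab$n_weight == 0], tab$n_sent[tab$n_weight == 1e9])
})

test_that("the mask-weight sweep reports metrics and the volume mode", {
  tab <- run_param_sweep("epsilon", c(0.5, 2), density = 1.5e-3,
                         replicates = 1, seed = 13, size_um = c(25, 25, 25))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("value", "sensitivity", "precision", "volume_mode") %in%
                    names(tab)))
  expect_true(all(tab$sensitivity >= 0 & tab$sensitivity <= 1))
  expect_true(all(tab$volume_mode > 0))
})
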