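## Detection scoring: globally minimum-cost one-to-one centroid matching
## (Hungarian assignment) with pairings beyond the acceptance radius
## excluded from the assignment problem, so the maximum number of admissible
## pairs is matched at minimum total distance. Sensitivity = N_ra / N_r
## (correct detections over true objects), precision = N_ra / N_s (correct
## detections over all detections).

.as_points <- function(p) {
  if (is.null(p) || !length(p)) return(matrix(numeric(0), 0, 3))
  p <- as.matrix(p)
  stopifnot(ncol(p) == 3)
  storage.mode(p) <- "double"
  p
}

#' Match detected centroids to ground truth
#'
#' Solves the assignment problem between truth and detections with the
#' Hungarian algorithm (via `clue::solve_LSAP`), minimizing the summed
#' Euclidean distance of assigned pairs. Pairings farther apart than
#' `radius_um` are forbidden (excluded from the assignment, not filtered
#' afterwards), which simultaneously realizes the cost-minimizing matching
#' and the acceptance radius.
#'
#' @param truth,detected Point matrices (columns x, y, z, microns); either
#'   may be empty.
#' @param radius_um Acceptance radius (default 2 um, half a typical nuclear
#'   radius).
#' @return A `match_result`: `pairs` (data frame `truth_index`,
#'   `detected_index`, `distance_um`), `misses` (unmatched truth indices),
#'   `false_detections` (unmatched detection indices), `radius_um`.
#' @export
match_centroids <- function(truth, detected, radius_um = 2) {
  truth <- .as_points(truth); detected <- .as_points(detected)
  nt <- nrow(truth); nd <- nrow(detected)
  empty_pairs <- data.frame(truth_index = integer(), detected_index = integer(),
                            distance_um = numeric())
  if (nt == 0L || nd == 0L)
    return(structure(list(pairs = empty_pairs, misses = seq_len(nt),
                          false_detections = seq_len(nd),
                          radius_um = radius_um),
                     class = "match_result"))
  d2 <- outer(rowSums(truth^2), rowSums(detected^2), `+`) -
    2 * tcrossprod(truth, detected)
  D <- sqrt(pmax(d2, 0))
  big <- 1e6
  m <- max(nt, nd)
  C <- matrix(big, m, m)
  C[seq_len(nt), seq_len(nd)] <- ifelse(D <= radius_um, D, big)
  sol <- as.integer(clue::solve_LSAP(C))
  ti <- seq_len(nt)
  di <- sol[ti]
  ok <- di <= nd & D[cbind(ti, pmin(di, nd))] <= radius_um
  # recompute matched distances directly (the Gram-matrix form above loses
  # ~1e-7 of precision to cancellation, visible for coincident points)
  exact <- sqrt(rowSums((truth[ti[ok], , drop = FALSE] -
                           detected[di[ok], , drop = FALSE])^2))
  pairs <- data.frame(truth_index = ti[ok], detected_index = di[ok],
                      distance_um = exact)
  pairs <- pairs[order(pairs$truth_index), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 misses = setdiff(seq_len(nt), pairs$truth_index),
                 false_detections = setdiff(seq_len(nd), pairs$detected_index),
                 radius_um = radius_um),
            class = "match_result")
}

#' Sensitivity and precision of a match
#'
#' `sensitivity = N_ra / N_r`, `precision = N_ra / N_s`. Degenerate
#' denominators (no truth / no detections) are reported as 1 with a flag
#' instead of erroring.
#'
#' @param match A `match_result` from [match_centroids()].
#' @return An `eval_report`: `n_true`, `n_detected`, `n_correct`,
#'   `sensitivity`, `precision`, `degenerate` flag.
#' @export
score <- function(match) {
  stopifnot(inherits(match, "match_result"))
  n_correct <- nrow(match$pairs)
  n_true <- n_correct + length(match$misses)
  n_detected <- n_correct + length(match$false_detections)
  degenerate <- n_true == 0L || n_detected == 0L
  structure(list(n_true = n_true, n_detected = n_detected,
                 n_correct = n_correct,
                 sensitivity = if (n_true) n_correct / n_true else 1,
                 precision = if (n_detected) n_correct / n_detected else 1,
                 degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d true, %d detected, %d correct | sensitivity %.3f, precision %.3f%s\n",
              x$n_true, x$n_detected, x$n_correct, x$sensitivity, x$precision,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Two-channel (sparse/dense) chimera sensitivity
#'
#' In a chimeric embryo a sparse, easily segmented second label channel
#' provides in vivo ground truth for the dense channel. The sparse-channel
#' centroids are treated as truth; sensitivity is matches over sparse count.
#' Precision is not meaningful here (the dense channel legitimately contains
#' many unmatched nuclei) and is flagged `NA`.
#'
#' @param sparse_centroids,dense_centroids Point matrices (microns) from the
#'   two co-registered channels.
#' @param radius_um Acceptance radius.
#' @return An `eval_report` with `precision = NA`.
#' @export
chimera_sensitivity <- function(sparse_centroids, dense_centroids,
                                radius_um = 2) {
  m <- match_centroids(sparse_centroids, dense_centroids, radius_um)
  r <- score(m)
  r$precision <- NA_real_
  r$degenerate <- r$n_true == 0L
  r
}

## ---- benchmark sweeps ----

#' Benchmark de-noising/mask defaults for synthetic sweeps
#'
#' The synthetic benchmark uses Gaussian blur (sigma 0.5, window 5) plus a
#' 3x3 median filter for de-noising (no diffusion), and DS weights all 1 at
#' `sigma_g = 1.1`.
#'
#' @return List with `denoise` and `mask` parameter bundles.
#' @export
benchmark_params <- function() {
  list(denoise = denoise_params(gauss_sigma = 0.5, gauss_window = 5,
                                median_window = 3, diff_iterations = 0),
       mask = mask_params(alpha = 1, beta = 1, epsilon = 1, gamma = 1,
                          delta = 1, sigma_g = 1.1))
}

.objects_centroids <- function(objects) {
  if (!length(objects)) return(matrix(numeric(0), 0, 3))
  t(vapply(objects, `[[`, numeric(3), "centroid_um"))
}

#' Segment one synthetic scene with each requested method
#'
#' Runs DS once, then derives each method's centroid set: `"ds"` (no
#' post-processing), `"kmeans"`, `"gmm"`, `"watershed"` (post-processing of
#' above-threshold objects) and `"log"` (standalone LoG detector on the
#' de-noised stack).
#'
#' @param scene A `synthetic_scene`.
#' @param methods Character vector of method names.
#' @param params Benchmark parameters ([benchmark_params()]).
#' @param n_weight FOV weight for the splitters.
#' @param seed Seed for the stochastic splitters.
#' @param logp A [log_params()] for the LoG baseline.
#' @return Named list of detected-centroid matrices.
#' @export
segment_scene_methods <- function(scene, methods = c("ds", "kmeans", "gmm"),
                                  params = benchmark_params(), n_weight = 0.5,
                                  seed = 1, logp = log_params()) {
  res <- ds_segment(scene$stack, params$denoise, params$mask)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(
      m,
      ds = .objects_centroids(res$objects),
      kmeans = ,
      gmm = ,
      watershed = .objects_centroids(
        postprocess_all(res, n_weight, m, seed)$objects),
      log = {
        den <- denoise_stack(scene$stack, params$denoise)
        log_detect(den, logp)
      },
      stop("unknown method: ", m))
  }
  out
}

.sweep_seed <- function(seed, i, j) (seed * 1009L + i * 101L + j) %% 2147483549L

#' Density sweep of the synthetic benchmark
#'
#' For each object density and replicate, generates a scene at the given
#' SNR, segments it with every method, and scores detections against the
#' known centroids within the matching radius. Deterministic per seed.
#'
#' @param densities Object densities in nuclei per cubic micron.
#' @param snr Signal-to-noise ratio of the nuclear gamma law.
#' @param methods Methods understood by [segment_scene_methods()].
#' @param replicates Scenes per density.
#' @param seed Integer master seed.
#' @param size_um Scene extent in microns (default 35 um cube).
#' @param spacing A [voxel_spacing()].
#' @param alignment_target Nematic order of the generated scenes (default
#'   0.67, the alignment of the reference benchmark tissue).
#' @param n_weight,params,logp Passed to [segment_scene_methods()].
#' @param radius_um Matching radius.
#' @return Tidy data frame: one row per density x method x replicate with
#'   `sensitivity`, `precision`, `n_true`, `n_detected`.
#' @export
run_density_sweep <- function(densities, snr = 5,
                              methods = c("ds", "kmeans", "gmm"),
                              replicates = 10, seed = 1,
                              size_um = c(35, 35, 35),
                              spacing = reference_spacing(),
                              alignment_target = 0.67, n_weight = 0.5,
                              params = benchmark_params(),
                              logp = log_params(), radius_um = 2) {
  rows <- list()
  for (i in seq_along(densities)) {
    for (r in seq_len(replicates)) {
      s <- .sweep_seed(seed, i, r)
      scene <- render_scene(
        sample_scene(size_um, densities[i], spacing,
                     alignment_target = alignment_target, seed = s),
        intensity_model(snr = snr), spacing, seed = s + 1)
      dets <- segment_scene_methods(scene, methods, params, n_weight, seed = s)
      for (m in methods) {
        rep_score <- score(match_centroids(scene$truth, dets[[m]], radius_um))
        rows[[length(rows) + 1L]] <-
          data.frame(density = densities[i], snr = snr, method = m,
                     replicate = r, sensitivity = rep_score$sensitivity,
                     precision = rep_score$precision,
                     n_true = rep_score$n_true,
                     n_detected = rep_score$n_detected)
      }
    }
  }
  do.call(rbind, rows)
}

#' SNR sweep of the synthetic benchmark
#'
#' As [run_density_sweep()] but varying SNR at fixed density.
#'
#' @param snrs SNR values.
#' @param density Fixed object density.
#' @inheritParams run_density_sweep
#' @return Tidy data frame as in [run_density_sweep()], with an `snr` column.
#' @export
run_snr_sweep <- function(snrs, density = 2e-3,
                          methods = c("ds", "gmm"), replicates = 10,
                          seed = 1, size_um = c(35, 35, 35),
                          spacing = reference_spacing(), n_weight = 0.5,
                          params = benchmark_params(), logp = log_params(),
                          radius_um = 2) {
  out <- lapply(seq_along(snrs), function(i)
    run_density_sweep(density, snr = snrs[i], methods = methods,
                      replicates = replicates, seed = seed + i,
                      size_um = size_um, spacing = spacing,
                      n_weight = n_weight, params = params, logp = logp,
                      radius_um = radius_um))
  do.call(rbind, out)
}

.volume_hist_mode <- function(volumes, binwidth = 10) {
  if (!length(volumes)) return(NA_real_)
  bins <- floor(volumes / binwidth)
  tab <- table(bins)
  modal <- as.integer(names(tab)[which.max(tab)])
  (modal + 0.5) * binwidth
}

#' DS mask-weight sweep
#'
#' Varies one of the DS weights (`alpha`, `beta`, `epsilon`) with the others
#' fixed at 1, runs DS alone on replicate scenes, and reports sensitivity,
#' precision and the mode of the segmented-volume histogram (10-voxel bins).
#' Raising `alpha` erodes volumes (falling mode); `epsilon` improves
#' separation without erosion; `beta` barely moves volumes.
#'
#' @param param One of `"alpha"`, `"beta"`, `"epsilon"`.
#' @param values Weight values to scan.
#' @param density,snr Scene parameters.
#' @param alignment_target Nematic order of the generated scenes.
#' @inheritParams run_density_sweep
#' @return Data frame: one row per value x replicate with `sensitivity`,
#'   `precision`, `volume_mode`.
#' @export
run_param_sweep <- function(param = c("alpha", "beta", "epsilon"), values,
                            density = 2.5e-3, snr = 5, replicates = 5,
                            seed = 1, size_um = c(35, 35, 35),
                            spacing = reference_spacing(),
                            alignment_target = 0.67,
                            params = benchmark_params(), radius_um = 2) {
  param <- match.arg(param)
  rows <- list()
  for (r in seq_len(replicates)) {
    s <- .sweep_seed(seed, 1L, r)
    scene <- render_scene(
      sample_scene(size_um, density, spacing,
                   alignment_target = alignment_target, seed = s),
      intensity_model(snr = snr), spacing, seed = s + 1)
    for (i in seq_along(values)) {
      mp <- params$mask
      mp[[param]] <- values[i]
      res <- ds_segment(scene$stack, params$denoise, mp)
      sc <- score(match_centroids(scene$truth,
                                  .objects_centroids(res$objects), radius_um))
      vols <- vapply(res$objects, `[[`, integer(1), "volume")
      rows[[length(rows) + 1L]] <-
        data.frame(param = param, value = values[i], replicate = r,
                   sensitivity = sc$sensitivity, precision = sc$precision,
                   volume_mode = .volume_hist_mode(vols))
    }
  }
  do.call(rbind, rows)
}

#' FOV weight (n) sweep
#'
#' Varies the fused-object-volume weight `n` on replicate dense scenes. The
#' DS result per replicate is computed once and re-thresholded for every
#' `n`, so decreasing `n` sends a superset of objects to post-processing.
#' Very large `n` reduces to DS alone.
#'
#' @param n_values FOV weights to scan.
#' @param density,snr Scene parameters (dense by default).
#' @param method Post-processing method.
#' @param alignment_target Nematic order of the generated scenes.
#' @inheritParams run_density_sweep
#' @return Data frame: one row per n x replicate with `sensitivity`,
#'   `precision`, `n_sent` (objects sent for post-processing).
#' @export
run_n_weight_sweep <- function(n_values, density = 3e-3, snr = 5,
                               method = "gmm", replicates = 5, seed = 1,
                               size_um = c(35, 35, 35),
                               spacing = reference_spacing(),
                               alignment_target = 0.67,
                               params = benchmark_params(), radius_um = 2) {
  rows <- list()
  for (r in seq_len(replicates)) {
    s <- .sweep_seed(seed, 1L, r)
    scene <- render_scene(
      sample_scene(size_um, density, spacing,
                   alignment_target = alignment_target, seed = s),
      intensity_model(snr = snr), spacing, seed = s + 1)
    res <- ds_segment(scene$stack, params$denoise, params$mask)
    vols <- vapply(res$objects, `[[`, integer(1), "volume")
    for (n in n_values) {
      post <- postprocess_all(res, n_weight = n, method = method, seed = s)
      sc <- score(match_centroids(scene$truth,
                                  .objects_centroids(post$objects), radius_um))
      fov <- compute_fov_threshold(vols, n)$fov_threshold
      rows[[length(rows) + 1L]] <-
        data.frame(n_weight = n, replicate = r,
                   sensitivity = sc$sensitivity, precision = sc$precision,
                   n_sent = sum(vols > fov))
    }
  }
  do.call(rbind, rows)
}

#' Mean sensitivity/precision per condition of a sweep table
#'
#' @param sweep Output of one of the `run_*_sweep()` functions.
#' @param by Grouping columns (default all non-replicate, non-metric ones).
#' @return Data frame of per-condition means and standard deviations.
#' @export
summarize_sweep <- function(sweep,
                            by = intersect(c("density", "snr", "method",
                                             "param", "value", "n_weight"),
                                           names(sweep))) {
  agg <- stats::aggregate(sweep[c("sensitivity", "precision")],
                          by = sweep[by], FUN = mean)
  sds <- stats::aggregate(sweep[c("sensitivity", "precision")],
                          by = sweep[by], FUN = stats::sd)
  names(sds)[match(c("sensitivity", "precision"), names(sds))] <-
    c("sd_sensitivity", "sd_precision")
  merge(agg, sds, by = by, sort = TRUE)
}
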