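## Post-processing of under-segmented (fused) objects. Objects whose volume
## exceeds an empirical threshold -- mean + n * sd of all segmented volumes
## (the "fused object volume", FOV) -- are candidates for splitting. The
## number of fused nuclei is estimated from the voxel frequency profiles
## along x, y, z (mnp = maximum number of local peaks over the three axes),
## then the voxel list is re-clustered in micron space.

#' Fused-object volume threshold
#'
#' `fov = mean(volumes) + n_weight * sd(volumes)` with the population
#' (divide-by-N) standard deviation. Objects above `fov` are sent for
#' splitting; lower `n_weight` sends more objects (higher sensitivity, more
#' compute), higher `n_weight` fewer.
#'
#' @param volumes Non-empty vector of object volumes in voxels (after the
#'   minimum-volume filter).
#' @param n_weight Dimensionless weight `n`.
#' @return A `volume_stats` list with `mean_volume`, `std_volume`,
#'   `n_weight`, `fov_threshold`.
#' @export
compute_fov_threshold <- function(volumes, n_weight = 1) {
  if (!length(volumes)) stop("empty volume list")
  m <- mean(volumes)
  s <- sqrt(mean((volumes - m)^2))
  structure(list(mean_volume = m, std_volume = s, n_weight = n_weight,
                 fov_threshold = m + n_weight * s),
            class = "volume_stats")
}

.ma3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- (x[1] + x[2]) / 2
  out[n] <- (x[n - 1] + x[n]) / 2
  out
}

#' Voxel frequency profiles of an object along x, y, z
#'
#' Counts of the object's voxels at each integer coordinate along each axis,
#' plus a moving-average smoothed copy used for peak finding. The smoothing
#' window is spacing-aware, covering roughly +/- 0.7 um: window 3 on axes
#' with sub-micron bins (xy at the reference spacing), no smoothing on axes
#' whose bins are already coarser (z, 1.75 um) -- a nucleus only ~3 slices
#' tall would otherwise have its valleys averaged away. Without a spacing
#' the window-3 average is applied to every axis. A correctly segmented
#' single nucleus is unimodal along every axis; fused objects show multiple
#' peaks along the fusion direction.
#'
#' @param obj A segmented object.
#' @param spacing Optional [voxel_spacing()] controlling per-axis smoothing.
#' @return Named list (`x`, `y`, `z`) of `axis_profile` objects, each with
#'   `axis`, `counts`, `smoothed` and the coordinate `support`.
#' @export
axis_profiles <- function(obj, spacing = NULL) {
  sp <- if (is.null(spacing)) c(x = 0, y = 0, z = 0) else
    stats::setNames(as.numeric(spacing), c("x", "y", "z"))
  out <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    coords <- obj$voxels[, ax]
    support <- min(coords):max(coords)
    counts <- tabulate(coords - min(coords) + 1L, length(support))
    smoothed <- if (sp[[ax]] > 1) counts else .ma3(counts)
    structure(list(axis = ax, counts = counts, smoothed = smoothed,
                   support = support),
              class = "axis_profile")
  })
  out
}

#' Count local peaks of a voxel frequency profile
#'
#' A peak is a local maximum strictly inside the profile support (plateaus
#' collapse to their midpoint) whose height exceeds
#' `prominence_frac * max(profile)` and which is separated from every higher
#' accepted peak by a valley dropping below
#' `(1 - prominence_frac) * min(pair heights)`. Monotone or flat profiles
#' count as one peak.
#'
#' @param profile An `axis_profile` (its smoothed counts are used) or a bare
#'   numeric vector (used as given).
#' @param prominence_frac Peak prominence fraction (default 0.2).
#' @return Integer peak count, >= 1.
#' @export
count_peaks <- function(profile, prominence_frac = 0.2) {
  y <- if (inherits(profile, "axis_profile")) profile$smoothed else as.numeric(profile)
  n <- length(y)
  if (n < 3) return(1L)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (i in seq_along(r$values)) {
    if (i == 1L || i == length(r$values)) next        # runs touching the border
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L])
      cand <- c(cand, (starts[i] + ends[i]) %/% 2L)
  }
  if (!length(cand)) return(1L)
  h <- y[cand]
  keep <- h > prominence_frac * max(y)
  cand <- cand[keep]; h <- h[keep]
  if (!length(cand)) return(1L)
  ord <- order(-h, cand)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (a in accepted) {
      rngv <- sort(c(cand[i], a))
      valley <- min(y[rngv[1]:rngv[2]])
      if (valley >= (1 - prominence_frac) * min(h[i], y[a])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, cand[i])
  }
  max(1L, length(accepted))
}

#' Estimate the number of fused nuclei in an object
#'
#' `mnp`: the maximum of the peak counts of the x, y and z voxel frequency
#' profiles. One for a single nucleus; k for k nuclei fused along one axis.
#' Known limitation: arrangements fused along several axes simultaneously
#' (e.g. 4 nuclei in a 2x2 sheet) are under-counted, since no single axis
#' sees more than 2 peaks.
#'
#' @param obj A segmented object.
#' @param prominence_frac Passed to [count_peaks()].
#' @param spacing Optional [voxel_spacing()], passed to [axis_profiles()].
#' @return List with `mnp` (integer >= 1) and the per-axis `peaks`.
#' @export
estimate_mnp <- function(obj, prominence_frac = 0.2, spacing = NULL) {
  profs <- axis_profiles(obj, spacing)
  peaks <- vapply(profs, count_peaks, integer(1),
                  prominence_frac = prominence_frac)
  list(mnp = max(peaks), peaks = peaks)
}

#' Object voxels as micron-space points
#'
#' Maps every voxel index to its physical center `(i - 0.5) * spacing`.
#' All clustering runs on these points so that the anisotropic z step is
#' properly accounted for.
#'
#' @param obj A segmented object.
#' @param spacing A [voxel_spacing()].
#' @return `volume x 3` matrix of (x, y, z) positions in microns.
#' @export
to_micron_points <- function(obj, spacing) {
  sweep(obj$voxels - 0.5, 2, as.numeric(spacing), `*`)
}

.split_result <- function(parent_id, children, method, aic_values = NULL) {
  structure(list(parent_id = parent_id, children = children, method = method,
                 selected_k = length(children), aic_values = aic_values),
            class = "split_result")
}

.child_from_rows <- function(obj, rows, spacing) {
  .segmented_object(obj$object_id,
                    obj$voxels[rows, , drop = FALSE], spacing)
}

#' Split a fused object by recursive K-means
#'
#' If the object's `mnp` is 1 it is returned unchanged. Otherwise K-means
#' (`k = mnp`, 10 restarts, seeded) clusters the micron-space voxel points;
#' every child is re-examined with [estimate_mnp()] and recursively re-split
#' while its `mnp > 1`, up to `max_depth` levels. The children always
#' partition the parent's voxels exactly.
#'
#' @param obj A segmented object.
#' @param spacing A [voxel_spacing()].
#' @param seed Integer seed for the K-means restarts.
#' @param prominence_frac Peak prominence for [count_peaks()].
#' @param max_depth Recursion cap (default 3) against pathological
#'   fragmentation of noisy objects.
#' @return A `split_result` (`method = "kmeans"`).
#' @export
kmeans_split <- function(obj, spacing, seed = 1, prominence_frac = 0.2,
                         max_depth = 3) {
  rec <- function(o, depth) {
    mnp <- estimate_mnp(o, prominence_frac, spacing)$mnp
    if (mnp <= 1L || depth > max_depth) return(list(o))
    pts <- to_micron_points(o, spacing)
    if (nrow(unique(pts)) < mnp) {
      warning("k exceeds number of distinct voxels; object left unsplit")
      return(list(o))
    }
    set.seed(seed + depth)
    km <- tryCatch(suppressWarnings(
      stats::kmeans(pts, centers = mnp, nstart = 10, iter.max = 100,
                    algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) return(list(o))
    kids <- lapply(seq_len(mnp), function(j)
      .child_from_rows(o, which(km$cluster == j), spacing))
    unlist(lapply(kids, rec, depth = depth + 1L), recursive = FALSE)
  }
  .split_result(obj$object_id, rec(obj, 1L), "kmeans")
}

## ---- Gaussian mixture with AIC model selection (no GMM package in the
## dependency environment; EM is implemented here, mvtnorm provides the
## component densities) ----

.gmm_em <- function(pts, k, seed, max_iter = 100, tol = 1e-6, reg = 1e-6) {
  n <- nrow(pts); d <- ncol(pts)
  set.seed(seed)
  if (k == 1L) {
    mu <- matrix(colMeans(pts), 1)
    sig <- list(stats::cov(pts) * (n - 1) / n + diag(reg, d))
    ll <- sum(mvtnorm::dmvnorm(pts, mu[1, ], sig[[1]], log = TRUE))
    return(list(pi = 1, mu = mu, sigma = sig, loglik = ll,
                resp = matrix(1, n, 1)))
  }
  km <- tryCatch(suppressWarnings(
    stats::kmeans(pts, centers = k, nstart = 3, iter.max = 30)),
    error = function(e) NULL)
  if (is.null(km)) return(NULL)
  z <- km$cluster
  pi_k <- tabulate(z, k) / n
  mu <- km$centers
  sig <- lapply(seq_len(k), function(j) {
    xj <- pts[z == j, , drop = FALSE]
    if (nrow(xj) < 2) diag(1, d) else stats::cov(xj) * (nrow(xj) - 1) / nrow(xj) + diag(reg, d)
  })
  ll_old <- -Inf
  logdens <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      dj <- tryCatch(mvtnorm::dmvnorm(pts, mu[j, ], sig[[j]], log = TRUE),
                     error = function(e) NULL)
      if (is.null(dj) || any(!is.finite(dj))) return(NULL)
      logdens[, j] <- log(pi_k[j]) + dj
    }
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)     # emptied component: degenerate fit
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * pts) / nk[j]
      cen <- sweep(pts, 2, mu[j, ])
      sig[[j]] <- crossprod(cen * resp[, j], cen) / nk[j] + diag(reg, d)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  # final E-step so that loglik and resp correspond to the returned params
  for (j in seq_len(k)) {
    dj <- tryCatch(mvtnorm::dmvnorm(pts, mu[j, ], sig[[j]], log = TRUE),
                   error = function(e) NULL)
    if (is.null(dj) || any(!is.finite(dj))) return(NULL)
    logdens[, j] <- log(pi_k[j]) + dj
  }
  m <- apply(logdens, 1, max)
  lse <- m + log(rowSums(exp(logdens - m)))
  list(pi = pi_k, mu = mu, sigma = sig, loglik = sum(lse),
       resp = exp(logdens - lse))
}

#' AIC of a fitted Gaussian mixture
#'
#' `AIC = 2p - 2 logL` with `p = (k - 1) + k d + k d (d + 1) / 2` free
#' parameters (mixing weights, means, full covariances) in `d` dimensions.
#'
#' @param loglik Fitted log-likelihood.
#' @param k Number of components.
#' @param d Data dimension (3 for voxel points).
#' @return The AIC value.
#' @export
gmm_aic <- function(loglik, k, d = 3) {
  p <- (k - 1) + k * d + k * d * (d + 1) / 2
  2 * p - 2 * loglik
}

#' Split a fused object by a Gaussian mixture with AIC selection
#'
#' Full-covariance Gaussian mixtures with `k = 1 ... mnp + 1` components are
#' fitted by EM (5 seeded restarts each, regularized covariances) to the
#' micron-space voxel points; the deliberately over-estimated upper end of
#' the range lets AIC reject a superfluous component rather than trust `mnp`.
#' The `k` minimizing AIC wins; voxels go to the component of maximum
#' responsibility, and children below 10 voxels are merged into their
#' nearest sibling. Degenerate fits (singular or emptied components) are
#' skipped.
#'
#' Because `mnp` under-counts compact multi-nucleus aggregates (overlapping
#' axis projections hide peaks), every child with `mnp > 1` is re-split
#' recursively, up to `max_depth` levels -- the same re-iteration the
#' K-means splitter uses. AIC still guards each level against over-splitting
#' (a child that is a single nucleus selects `k = 1`).
#'
#' @inheritParams kmeans_split
#' @param restarts EM restarts per candidate `k`.
#' @param max_depth Recursion cap.
#' @return A `split_result` (`method = "gmm"`) with the top-level candidate
#'   `aic_values`.
#' @export
gmm_aic_split <- function(obj, spacing, seed = 1, prominence_frac = 0.2,
                          restarts = 5, max_depth = 3) {
  top_aic <- NULL
  rec <- function(o, depth) {
    fit <- .gmm_fit_select(o, spacing, seed, prominence_frac, restarts)
    if (depth == 1L) top_aic <<- fit$aic
    kids <- fit$children
    if (depth >= max_depth || length(kids) == 1L) return(kids)
    out <- list()
    for (ch in kids) {
      if (length(kids) > 1L && estimate_mnp(ch, prominence_frac, spacing)$mnp > 1L) {
        out <- c(out, rec(ch, depth + 1L))
      } else {
        out <- c(out, list(ch))
      }
    }
    out
  }
  .split_result(obj$object_id, rec(obj, 1L), "gmm", top_aic)
}

# one level of GMM fitting + AIC selection + sub-threshold merging; for very
# large objects EM runs on a seeded subsample (all voxels are still assigned
# by responsibility under the fitted model)
.gmm_fit_select <- function(obj, spacing, seed, prominence_frac, restarts,
                            max_fit_points = 2000L) {
  mnp <- estimate_mnp(obj, prominence_frac, spacing)$mnp
  pts <- to_micron_points(obj, spacing)
  fit_pts <- pts
  if (nrow(pts) > max_fit_points) {
    set.seed(seed)
    fit_pts <- pts[sample.int(nrow(pts), max_fit_points), , drop = FALSE]
  }
  ks <- seq_len(min(mnp + 1L, nrow(fit_pts)))
  fits <- vector("list", length(ks))
  aic <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      f <- .gmm_em(fit_pts, ks[i], seed = seed + 1000L * ks[i] + r)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
      if (ks[i] == 1L) break
    }
    if (is.null(best)) next
    fits[[i]] <- best
    aic[i] <- gmm_aic(best$loglik, ks[i], ncol(fit_pts))
  }
  if (all(is.na(aic)))
    return(list(children = list(obj), aic = aic))
  sel <- which.min(aic)
  fit <- fits[[sel]]
  k_sel <- length(fit$pi)
  logdens <- vapply(seq_len(k_sel), function(j)
    log(fit$pi[j]) + mvtnorm::dmvnorm(pts, fit$mu[j, ], fit$sigma[[j]],
                                      log = TRUE),
    numeric(nrow(pts)))
  if (is.null(dim(logdens))) logdens <- matrix(logdens, nrow = nrow(pts))
  assign <- max.col(logdens, ties.method = "first")
  groups <- split(seq_len(nrow(pts)), assign)
  kids <- lapply(groups, function(rows) .child_from_rows(obj, rows, spacing))
  # merge sub-threshold children into the nearest surviving sibling
  repeat {
    vols <- vapply(kids, `[[`, integer(1), "volume")
    if (length(kids) <= 1 || all(vols >= 10)) break
    i <- which.min(vols)
    cen <- t(vapply(kids, `[[`, numeric(3), "centroid_um"))
    dists <- sqrt(rowSums(sweep(cen, 2, cen[i, ])^2))
    dists[i] <- Inf
    j <- which.min(dists)
    merged_vox <- rbind(kids[[j]]$voxels, kids[[i]]$voxels)
    kids[[j]] <- .segmented_object(obj$object_id, merged_vox, spacing)
    kids[[i]] <- NULL
  }
  list(children = kids, aic = aic)
}

#' Post-process a segmentation result
#'
#' Computes the FOV threshold from the object volumes, splits every object
#' strictly above it with the chosen method, and passes all others through
#' untouched. Voxels are conserved exactly; new consecutive ids are
#' assigned; on a stack of isolated single nuclei the operation is the
#' identity up to relabelling.
#'
#' @param result A `segmentation_result` from [ds_segment()].
#' @param n_weight FOV weight `n` (see [compute_fov_threshold()]). The
#'   default 0.5 matches the reference stack's printed threshold (237
#'   voxels, with roughly a third of all objects above it).
#' @param method `"kmeans"`, `"gmm"` or `"watershed"`.
#' @param seed Integer seed for the stochastic splitters.
#' @param prominence_frac Peak prominence for [count_peaks()].
#' @return A new `segmentation_result`; `$postprocess` records the volume
#'   stats, method, seed and a per-parent audit table (`parent_id`,
#'   `child_id`, `method`, `selected_k`).
#' @export
postprocess_all <- function(result, n_weight = 0.5,
                            method = c("kmeans", "gmm", "watershed"),
                            seed = 1, prominence_frac = 0.2) {
  method <- match.arg(method)
  stopifnot(inherits(result, "segmentation_result"))
  objects <- result$objects
  if (!length(objects)) return(result)
  vols <- vapply(objects, `[[`, integer(1), "volume")
  vs <- compute_fov_threshold(vols, n_weight)
  out <- list()
  audit <- list()
  for (o in objects) {
    if (o$volume > vs$fov_threshold) {
      sr <- switch(method,
                   kmeans = kmeans_split(o, result$spacing, seed, prominence_frac),
                   gmm = gmm_aic_split(o, result$spacing, seed, prominence_frac),
                   watershed = watershed_split(o, result$spacing))
      for (ch in sr$children) out[[length(out) + 1L]] <- ch
      audit[[length(audit) + 1L]] <-
        data.frame(parent_id = o$object_id,
                   n_children = sr$selected_k, method = method)
    } else {
      out[[length(out) + 1L]] <- o
    }
  }
  for (i in seq_along(out)) out[[i]]$object_id <- i
  structure(list(objects = out,
                 label_mask = label_mask(out, result$dims),
                 spacing = result$spacing,
                 dims = result$dims,
                 params = result$params,
                 postprocess = list(volume_stats = vs, method = method,
                                    seed = seed,
                                    audit = do.call(rbind, audit))),
            class = "segmentation_result")
}
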