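## The Derivatives Sum (DS) segmentation core. Three per-slice derivative
## maps of the de-noised image -- gradient magnitude (broad maxima at nuclear
## edges), positive Laplacian (enclosing nuclear boundaries) and the absolute
## negative Hessian determinant (saddle points where two nuclei touch) -- are
## combined into a tanh mask that darkens contact zones before thresholding.

#' DS mask parameters
#'
#' Tuning weights of the Derivatives Sum mask. `alpha`, `beta`, `epsilon`
#' weight the gradient-magnitude, positive-Laplacian and negative-Hessian
#' contributions; `gamma` sets the steepness and `delta` the offset of the
#' tanh transition; `sigma_g` is the Gaussian scale (pixels) at which the
#' derivatives are taken. The default preset is all weights 1 with
#' `sigma_g = 1.5`; the synthetic benchmark of the evaluation module uses
#' `sigma_g = 1.1`.
#'
#' Raising `alpha` erodes object volumes (useful in dense tissue); `epsilon`
#' improves separation of touching nuclei without eroding volume; `beta` has
#' only a weak effect on volumes.
#'
#' @param alpha,beta,epsilon Non-negative derivative weights.
#' @param gamma,delta Mask steepness and offset.
#' @param sigma_g Derivative scale in pixels (> 0).
#' @return A `mask_params` list.
#' @export
mask_params <- function(alpha = 1, beta = 1, epsilon = 1,
                        gamma = 1, delta = 1, sigma_g = 1.5) {
  if (any(c(alpha, beta, epsilon, gamma) < 0)) stop("weights must be >= 0")
  if (sigma_g <= 0) stop("sigma_g must be > 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 gamma = gamma, delta = delta, sigma_g = sigma_g),
            class = "mask_params")
}

.smooth_sigma_g <- function(voxels, sigma_g) {
  win <- max(3L, 2L * ceiling(3 * sigma_g) + 1L)
  k <- gaussian_kernel_1d(sigma_g, win)
  cpp_conv_sep2d(voxels, k, k)
}

# Central-difference first derivative and [1,-2,1] second derivative of the
# sigma_g-smoothed slices. Derivatives are finite differences on the smoothed
# image (a standard scale-space discretization).
.d1 <- c(-0.5, 0, 0.5)
.d2 <- c(1, -2, 1)
.id <- 1

#' Gauss gradient magnitude
#'
#' Per-slice `sqrt(Ix^2 + Iy^2)` where `Ix`, `Iy` are central differences of
#' the Gaussian-smoothed slice at scale `sigma_g`. Nuclear edges appear as
#' broad ridges of this map.
#'
#' @param stack A de-noised [image_stack()].
#' @param sigma_g Derivative scale in pixels.
#' @return 3D array of non-negative responses, same dimensions as the stack.
#' @export
gauss_gradient_magnitude <- function(stack, sigma_g = 1.5) {
  .check_stack(stack)
  s <- .smooth_sigma_g(stack$voxels, sigma_g)
  ix <- cpp_conv_sep2d(s, .id, .d1)
  iy <- cpp_conv_sep2d(s, .d1, .id)
  out <- sqrt(ix^2 + iy^2)
  dim(out) <- dim(stack$voxels)
  out
}

#' Positive part of the Laplacian
#'
#' Per-slice `max(Ixx + Iyy, 0)` of the Gaussian-smoothed slice; positive
#' values enclose nuclear boundaries (intensity valleys between nuclei).
#'
#' @inheritParams gauss_gradient_magnitude
#' @return 3D array of non-negative responses.
#' @export
laplacian_positive <- function(stack, sigma_g = 1.5) {
  .check_stack(stack)
  s <- .smooth_sigma_g(stack$voxels, sigma_g)
  lap <- cpp_conv_sep2d(s, .id, .d2) + cpp_conv_sep2d(s, .d2, .id)
  pmax(lap, 0)
}

#' Absolute negative Hessian determinant
#'
#' Per-slice `|min(Ixx * Iyy - Ixy^2, 0)|` of the Gaussian-smoothed slice.
#' Negative determinants flag saddle points -- exactly the configurations
#' where two nuclear edges touch -- so this map is the key ingredient for
#' separating fused nuclei.
#'
#' @inheritParams gauss_gradient_magnitude
#' @return 3D array of non-negative responses.
#' @export
hessian_det_negative_abs <- function(stack, sigma_g = 1.5) {
  .check_stack(stack)
  s <- .smooth_sigma_g(stack$voxels, sigma_g)
  ixx <- cpp_conv_sep2d(s, .id, .d2)
  iyy <- cpp_conv_sep2d(s, .d2, .id)
  ixy <- cpp_conv_sep2d(s, .d1, .d1)
  det <- ixx * iyy - ixy^2
  abs(pmin(det, 0))
}

#' Compute the three DS derivative maps
#' @inheritParams gauss_gradient_magnitude
#' @return List with `gradmag`, `lap_pos`, `hess_negabs` arrays.
#' @export
derivative_maps <- function(stack, sigma_g = 1.5) {
  list(gradmag = gauss_gradient_magnitude(stack, sigma_g),
       lap_pos = laplacian_positive(stack, sigma_g),
       hess_negabs = hessian_det_negative_abs(stack, sigma_g))
}

.norm_by_slice_max <- function(map) {
  d <- dim(map)
  for (z in seq_len(d[3])) {
    m <- max(map[, , z])
    if (m > 0) map[, , z] <- map[, , z] / m
  }
  map
}

#' Hyperbolic-tangent masking function
#'
#' Each derivative map is rescaled to `[0, 1]` by its per-slice maximum
#' (per-slice so that the weights stay comparable across depth despite signal
#' attenuation; an all-zero map stays zero). The weighted derivatives sum
#' `S = alpha * G + beta * L + epsilon * H` then drives the mask
#' `m = (1 + tanh(delta - gamma * S)) / 2`, which is strictly decreasing in
#' `S` and lies in (0, 1): bright where the image is flat (nuclear
#' interiors), dark on the edge/saddle "crown" around each nucleus.
#'
#' @param derivs Output of [derivative_maps()].
#' @param params A [mask_params()].
#' @return 3D mask array with values in (0, 1).
#' @export
masking_function <- function(derivs, params = mask_params()) {
  stopifnot(all(c("gradmag", "lap_pos", "hess_negabs") %in% names(derivs)))
  g <- .norm_by_slice_max(derivs$gradmag)
  l <- .norm_by_slice_max(derivs$lap_pos)
  h <- .norm_by_slice_max(derivs$hess_negabs)
  s <- params$alpha * g + params$beta * l + params$epsilon * h
  (1 + tanh(params$delta - params$gamma * s)) / 2
}

#' Apply a mask to a de-noised stack
#'
#' Voxelwise product; with mask values below 1 this only ever suppresses
#' intensity, darkening nuclear contacts so the subsequent threshold separates
#' touching nuclei.
#'
#' @param denoised A de-noised [image_stack()].
#' @param mask Mask array from [masking_function()], same dimensions.
#' @return The masked [image_stack()].
#' @export
apply_mask <- function(denoised, mask) {
  .check_stack(denoised)
  if (!identical(dim(denoised$voxels), dim(mask))) stop("mask dimensions differ")
  .as_stack_like(denoised, denoised$voxels * mask)
}

#' Otsu threshold of a single slice (256-bin histogram)
#'
#' Exhaustive maximization of between-class variance over 256 bins spanning
#' the slice's intensity range. Returns the threshold value; a constant slice
#' returns `Inf` so that everything classifies as background.
#'
#' @param slice Numeric matrix.
#' @return Threshold; foreground is `slice > threshold`.
#' @export
otsu_threshold <- function(slice) {
  rng <- range(slice)
  if (diff(rng) == 0) return(Inf)
  nb <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- as.numeric(tabulate(pmin(findInterval(slice, breaks, all.inside = TRUE), nb), nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  tot <- w[nb]; mtot <- mu[nb]
  w1 <- w[-nb]; m1 <- mu[-nb]
  w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  sb <- rep(-Inf, nb - 1L)
  sb[valid] <- (mtot * w1[valid] / tot - m1[valid])^2 / (w1[valid] * w2[valid])
  t_idx <- which.max(sb)
  breaks[t_idx + 1L]
}

#' Per-slice Otsu thresholding of a masked stack
#'
#' One Otsu threshold is computed independently for every z-slice (the
#' masked-image statistics vary with depth); foreground is strictly above the
#' threshold. All-constant slices yield all-background.
#'
#' Otsu's criterion always splits a histogram, even a unimodal one: on a
#' slice containing only background it would bisect the noise and flood half
#' the slice with spurious foreground that then bridges real objects in 3D.
#' With `floor_global = TRUE` (default) each slice threshold is therefore
#' floored at the whole-stack Otsu threshold, which leaves nuclei-bearing
#' slices essentially untouched but classifies background-only slices as
#' background. Single-slice stacks are unaffected (the global threshold is
#' the slice threshold).
#'
#' @param masked A masked [image_stack()].
#' @param floor_global Floor slice thresholds at the global Otsu threshold.
#' @return Integer 3D array of 0/1 foreground flags.
#' @export
otsu_threshold_slices <- function(masked, floor_global = TRUE) {
  .check_stack(masked)
  v <- masked$voxels
  gthr <- if (floor_global) otsu_threshold(v) else -Inf
  out <- array(0L, dim(v))
  for (z in seq_len(dim(v)[3])) {
    thr <- max(otsu_threshold(v[, , z]), gthr)
    out[, , z] <- (v[, , z] > thr) * 1L
  }
  out
}

.segmented_object <- function(id, vox_xyz, spacing) {
  # vox_xyz: integer matrix, columns x, y, z (1-based voxel indices)
  centroid <- (colMeans(vox_xyz) - 0.5) * as.numeric(spacing)
  list(object_id = as.integer(id),
       voxels = vox_xyz,
       volume = nrow(vox_xyz),
       centroid_um = unname(centroid))
}

#' 3D connected components of a binary stack
#'
#' Maximal 26-connected (default) foreground components; foreground pixels in
#' neighbouring slices join into 3D objects. Labels are assigned
#' deterministically in raster order of each component's first voxel.
#' Centroids are voxel-center means converted to microns via the spacing.
#'
#' @param binary Integer/logical 3D array (non-zero = foreground).
#' @param spacing A [voxel_spacing()].
#' @param connectivity 26 (default) or 6.
#' @return List of segmented objects, each a list with `object_id`, `voxels`
#'   (n x 3 integer matrix of 1-based x, y, z indices), `volume` (voxel
#'   count) and `centroid_um` (x, y, z in microns).
#' @export
connected_components_3d <- function(binary, spacing = reference_spacing(),
                                    connectivity = 26) {
  b <- binary
  storage.mode(b) <- "integer"
  lab <- cpp_label3d(b, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  ai <- arrayInd(idx, dim(lab))           # columns: y, x, z
  labs <- lab[idx]
  ord <- order(labs)
  ai <- ai[ord, , drop = FALSE]
  labs <- labs[ord]
  splits <- split(seq_len(nrow(ai)), labs)
  lapply(seq_along(splits), function(i) {
    rows <- splits[[i]]
    vox <- cbind(x = ai[rows, 2L], y = ai[rows, 1L], z = ai[rows, 3L])
    .segmented_object(i, vox, spacing)
  })
}

#' Drop objects below a minimum volume
#'
#' Components smaller than `min_volume` voxels (default 10) are treated as
#' noise and discarded; survivors keep their voxel lists but are renumbered
#' consecutively.
#'
#' @param objects List of segmented objects.
#' @param min_volume Minimum volume in voxels.
#' @return Filtered, renumbered object list.
#' @export
remove_small_objects <- function(objects, min_volume = 10) {
  keep <- Filter(function(o) o$volume >= min_volume, objects)
  for (i in seq_along(keep)) keep[[i]]$object_id <- i
  keep
}

#' Rebuild an integer label mask from an object list
#' @param objects List of segmented objects.
#' @param dims Stack dimensions `(ny, nx, nz)`.
#' @return Integer 3D array; 0 = background.
#' @export
label_mask <- function(objects, dims) {
  lab <- array(0L, dims)
  for (o in objects) {
    lin <- o$voxels[, "y"] + dims[1] * (o$voxels[, "x"] - 1L) +
      dims[1] * dims[2] * (o$voxels[, "z"] - 1L)
    lab[lin] <- o$object_id
  }
  lab
}

#' Derivatives Sum 3D segmentation
#'
#' The full DS path: de-noise, per-slice derivative maps at `sigma_g`, tanh
#' masking, voxelwise mask product, per-slice Otsu thresholding, 3D connected
#' components, small-object removal. Deterministic: identical input and
#' parameters give a bit-identical label mask.
#'
#' @param stack Raw [image_stack()].
#' @param denoise A [denoise_params()].
#' @param mask A [mask_params()].
#' @param min_volume Minimum object volume in voxels (default 10).
#' @param connectivity 3D connectivity for components. The pipeline default
#'   is 6 (face adjacency): with the z step 2.5x coarser than xy, the
#'   diagonal inter-slice adjacencies of 26-connectivity bridge nuclei that
#'   the per-slice mask has already separated.
#' @return A `segmentation_result`: list with `objects`, `label_mask`,
#'   `spacing`, `dims` and the parameter bundles in `params`.
#' @examples
#' scene <- render_scene(sample_scene(c(25, 25, 25), 1e-3, seed = 7), seed = 7)
#' res <- ds_segment(scene$stack, denoise_params(median_window = 3,
#'                                               diff_iterations = 0),
#'                   mask_params(sigma_g = 1.1))
#' length(res$objects)
#' @export
ds_segment <- function(stack, denoise = denoise_params(),
                       mask = mask_params(), min_volume = 10,
                       connectivity = 6) {
  .check_stack(stack)
  den <- denoise_stack(stack, denoise)
  derivs <- derivative_maps(den, mask$sigma_g)
  m <- masking_function(derivs, mask)
  masked <- apply_mask(den, m)
  binary <- otsu_threshold_slices(masked)
  objects <- connected_components_3d(binary, stack$spacing, connectivity)
  objects <- remove_small_objects(objects, min_volume)
  structure(list(objects = objects,
                 label_mask = label_mask(objects, dim(stack$voxels)),
                 spacing = stack$spacing,
                 dims = dim(stack$voxels),
                 params = list(denoise = denoise, mask = mask,
                               min_volume = min_volume,
                               connectivity = connectivity)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  vols <- vapply(x$objects, `[[`, integer(1), "volume")
  cat(sprintf("segmentation_result: %d objects", length(x$objects)))
  if (length(vols))
    cat(sprintf(" (volumes %d-%d voxels, median %g)", min(vols), max(vols),
                stats::median(vols)))
  cat("\n")
  invisible(x)
}
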