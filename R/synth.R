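## Synthetic 3D stacks of ellipsoidal nuclei with known ground truth. The
## stated world: nuclei are ellipsoids (default semi-axes 4 x 2.75 x 2.75 um
## with 15% uniform jitter; the long semi-axis is the typical nuclear radius
## of 4 um, and the resulting ~126 um^3 volume is what makes the reference
## density range of up to 4e-3 nuclei per um^3 geometrically possible),
## voxel intensities inside a nucleus follow a gamma law whose mean/sd ratio
## is the SNR (SNR = sqrt(shape)), the background follows a dimmer gamma law
## (mean one quarter of the nuclear mean, shape 4), and long-axis
## orientations can be tuned from isotropic to perfectly aligned via the
## nematic order parameter.

#' Gamma intensity model for synthetic nuclei
#'
#' The nuclear gamma shape is `snr^2` (for a gamma law mean/sd =
#' sqrt(shape)), the scale is set from the requested mean. The background is
#' an independent, dimmer gamma.
#'
#' @param snr Signal-to-noise ratio (mean over sd within a nucleus).
#' @param nucleus_mean Mean nuclear intensity (default 100 on a 16-bit scale).
#' @param background_mean Mean background intensity (default `nucleus_mean/4`).
#' @param background_shape Background gamma shape (default 4).
#' @return An `intensity_model` list with the gamma shapes/scales and `snr`.
#' @export
intensity_model <- function(snr = 5, nucleus_mean = 100,
                            background_mean = nucleus_mean / 4,
                            background_shape = 4) {
  if (snr <= 0) stop("snr must be > 0")
  if (nucleus_mean <= background_mean)
    stop("nucleus mean must exceed background mean")
  shape <- snr^2
  structure(list(nucleus_gamma_shape = shape,
                 nucleus_gamma_scale = nucleus_mean / shape,
                 background_gamma_shape = background_shape,
                 background_gamma_scale = background_mean / background_shape,
                 snr = snr),
            class = "intensity_model")
}

#' Nematic order parameter of a set of orientations
#'
#' Largest eigenvalue of the nematic tensor
#' `Q = (3 / (2N)) * sum_i u_i u_i^T - I/2` built from unit long-axis
#' vectors: 1 for perfect alignment, 0.25 for two orthogonal axes, ~0 for
#' isotropic orientations (lower bound -0.5).
#'
#' @param orientations `N x 3` matrix of unit vectors (sign irrelevant).
#' @return The largest eigenvalue of `Q`.
#' @export
nematic_order <- function(orientations) {
  u <- as.matrix(orientations)
  if (!nrow(u)) stop("empty orientation list")
  nrm <- sqrt(rowSums(u^2))
  if (any(nrm < 1e-12)) stop("zero-length orientation vector")
  u <- u / nrm
  q <- (3 / (2 * nrow(u))) * crossprod(u) - diag(3) / 2
  max(eigen(q, symmetric = TRUE, only.values = TRUE)$values)
}

.unit <- function(v) v / sqrt(sum(v^2))

# Orientations with tunable alignment: u_i = normalize(kappa * director + g_i),
# g_i ~ N(0, I3); kappa found by bisection on the realized nematic order of
# the actual sample (deterministic given the RNG state on entry).
.sample_orientations <- function(n, target, director = c(1, 0, 0)) {
  g <- matrix(stats::rnorm(3 * n), n, 3)
  mix <- function(kappa) {
    u <- sweep(g, 2, kappa * director, `+`)
    u / sqrt(rowSums(u^2))
  }
  if (target >= 0.999) return(matrix(director, n, 3, byrow = TRUE))
  base <- nematic_order(mix(0))
  if (target <= base) return(mix(0))
  lo <- 0; hi <- 1
  while (nematic_order(mix(hi)) < target && hi < 1e4) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (nematic_order(mix(mid)) < target) lo <- mid else hi <- mid
  }
  mix((lo + hi) / 2)
}

#' Sample a synthetic scene specification
#'
#' Places `N = round(density * X * Y * Z)` ellipsoids in the box, jitters the
#' semi-axes uniformly by `axes_jitter`, and draws long-axis orientations so
#' that the realized nematic order matches `alignment_target` (within 0.05
#' for attainable targets; at small `N` an isotropic sample has residual
#' order of order `1/sqrt(N)`, which is the attainability floor).
#'
#' Placement emulates tissue packing: centers are sampled uniformly subject
#' to a hard minimum center gap, and additionally rejected while the new
#' ellipsoid would interpenetrate an existing one (directional-radius test
#' along the center-to-center line). When the density makes non-overlapping
#' placement infeasible -- as it does at the upper end of the reference
#' density range, where nuclei pack space almost completely -- the placement
#' with the least interpenetration among the bounded attempts is accepted, so
#' low-density scenes contain touching-but-distinct nuclei (whose contact
#' necks the DS mask can cut) while high-density scenes contain genuinely
#' fused silhouettes (which only post-processing can resolve). Deterministic
#' for a fixed seed.
#'
#' @param size_um Scene extent `(X, Y, Z)` in microns.
#' @param density Nuclei per cubic micron (reference tissue: 1e-3 to 4e-3).
#' @param spacing A [voxel_spacing()] (used only to carry through to
#'   rendering defaults).
#' @param axes_um Mean semi-axes `(a, b, c)` in microns, long axis first.
#' @param axes_jitter Uniform relative jitter of each semi-axis.
#' @param alignment_target Desired nematic order in `[0, 1]`.
#' @param min_center_gap_um Hard minimum distance between centers.
#' @param max_attempts Placement attempts per nucleus before the
#'   least-overlapping candidate is accepted.
#' @param seed Integer seed.
#' @return A data frame of nucleus specs (`cx, cy, cz, a, b, c, ux, uy, uz`)
#'   with the scene parameters in attributes.
#' @export
sample_scene <- function(size_um, density, spacing = reference_spacing(),
                         axes_um = c(4, 2.75, 2.75), axes_jitter = 0.15,
                         alignment_target = 0, min_center_gap_um = 4,
                         max_attempts = 600, seed = 1) {
  size_um <- as.numeric(size_um)
  stopifnot(length(size_um) == 3, all(size_um > 0), density > 0)
  n <- round(density * prod(size_um))
  if (n < 1) stop("density * volume < 1: no nuclei to place")
  set.seed(seed)
  jit <- matrix(stats::runif(3 * n, 1 - axes_jitter, 1 + axes_jitter), n, 3)
  axes <- sweep(jit, 2, axes_um, `*`)
  u <- .sample_orientations(n, alignment_target)
  # per-nucleus quadratic form M = R diag(a^2,b^2,c^2) R^T; the ellipsoid's
  # radius along unit direction d through its center is sqrt(d^T M d)
  M6 <- matrix(NA_real_, n, 6)  # xx, yy, zz, xy, xz, yz
  for (i in seq_len(n)) {
    R <- .frame_from_axis(u[i, ])
    M <- R %*% diag(axes[i, ]^2) %*% t(R)
    M6[i, ] <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  }
  dir_radius <- function(rows, dx, dy, dz) {
    sqrt(M6[rows, 1] * dx^2 + M6[rows, 2] * dy^2 + M6[rows, 3] * dz^2 +
           2 * (M6[rows, 4] * dx * dy + M6[rows, 5] * dx * dz +
                  M6[rows, 6] * dy * dz))
  }
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    best <- NULL; best_margin <- -Inf
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(3) * size_um
      if (i == 1L) { best <- p; best_margin <- Inf; break }
      prev <- seq_len(i - 1L)
      dx <- p[1] - centers[prev, 1]; dy <- p[2] - centers[prev, 2]
      dz <- p[3] - centers[prev, 3]
      dd <- sqrt(dx^2 + dy^2 + dz^2)
      if (min(dd) < min_center_gap_um) next
      ux <- dx / dd; uy <- dy / dd; uz <- dz / dd
      margin <- min(dd - dir_radius(prev, ux, uy, uz) -
                      dir_radius(rep(i, i - 1L), ux, uy, uz))
      if (margin > best_margin) { best_margin <- margin; best <- p }
      if (margin >= 0) break
    }
    if (is.null(best))
      stop("center rejection sampling failed: density infeasible for min gap")
    centers[i, ] <- best
  }
  out <- data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                    a = axes[, 1], b = axes[, 2], c = axes[, 3],
                    ux = u[, 1], uy = u[, 2], uz = u[, 3])
  attr(out, "size_um") <- size_um
  attr(out, "density") <- density
  attr(out, "spacing") <- spacing
  attr(out, "alignment") <- nematic_order(u)
  attr(out, "seed") <- seed
  out
}

# Orthonormal frame with first axis u; complement chosen deterministically.
.frame_from_axis <- function(u) {
  u <- .unit(u)
  e <- diag(3)[, which.min(abs(u))]
  v <- .unit(pracma_cross(u, e))
  w <- pracma_cross(u, v)
  cbind(u, v, w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Render a synthetic scene to an image stack
#'
#' Every voxel whose center lies inside at least one ellipsoid draws its
#' intensity from the nuclear gamma law; where nuclei overlap, the maximum of
#' independent draws is taken (mimicking fluorescence saturation at touching
#' nuclei without seams). All other voxels draw from the background gamma.
#' Intensities are rounded and clipped to the bit depth. Deterministic for a
#' fixed seed.
#'
#' @param nuclei Scene specification from [sample_scene()].
#' @param model An [intensity_model()].
#' @param spacing A [voxel_spacing()].
#' @param seed Integer seed.
#' @param bit_depth 8 or 16.
#' @return A `synthetic_scene`: list with `stack` ([image_stack()]),
#'   `nuclei`, `truth` (centroid matrix in microns), realized `alignment`,
#'   `density` and `seed`.
#' @export
render_scene <- function(nuclei, model = intensity_model(),
                         spacing = attr(nuclei, "spacing"), seed = 1,
                         bit_depth = 16L) {
  size_um <- attr(nuclei, "size_um")
  if (is.null(spacing)) spacing <- reference_spacing()
  sp <- as.numeric(spacing)
  nx <- max(1L, round(size_um[1] / sp[1]))
  ny <- max(1L, round(size_um[2] / sp[2]))
  nz <- max(1L, round(size_um[3] / sp[3]))
  set.seed(seed)
  nvox <- ny * nx * nz
  vox <- array(stats::rgamma(nvox, shape = model$background_gamma_shape,
                             scale = model$background_gamma_scale),
               c(ny, nx, nz))
  nuc_val <- array(0, c(ny, nx, nz))
  inside_any <- array(FALSE, c(ny, nx, nz))
  xc <- (seq_len(nx) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  zc <- (seq_len(nz) - 0.5) * sp[3]
  for (i in seq_len(nrow(nuclei))) {
    cen <- c(nuclei$cx[i], nuclei$cy[i], nuclei$cz[i])
    ax <- c(nuclei$a[i], nuclei$b[i], nuclei$c[i])
    R <- .frame_from_axis(c(nuclei$ux[i], nuclei$uy[i], nuclei$uz[i]))
    rmax <- max(ax)
    xi <- which(xc >= cen[1] - rmax & xc <= cen[1] + rmax)
    yi <- which(yc >= cen[2] - rmax & yc <= cen[2] + rmax)
    zi <- which(zc >= cen[3] - rmax & zc <= cen[3] + rmax)
    if (!length(xi) || !length(yi) || !length(zi)) next
    g <- expand.grid(y = yi, x = xi, z = zi)
    p <- cbind(xc[g$x] - cen[1], yc[g$y] - cen[2], zc[g$z] - cen[3])
    loc <- p %*% R            # coordinates in the ellipsoid frame
    ins <- (loc[, 1] / ax[1])^2 + (loc[, 2] / ax[2])^2 + (loc[, 3] / ax[3])^2 <= 1
    if (!any(ins)) next
    lin <- g$y[ins] + ny * (g$x[ins] - 1L) + ny * nx * (g$z[ins] - 1L)
    draws <- stats::rgamma(length(lin), shape = model$nucleus_gamma_shape,
                           scale = model$nucleus_gamma_scale)
    nuc_val[lin] <- pmax(nuc_val[lin], draws)
    inside_any[lin] <- TRUE
  }
  vox[inside_any] <- nuc_val[inside_any]
  vox <- pmin(pmax(round(vox), 0), 2^bit_depth - 1)
  dim(vox) <- c(ny, nx, nz)
  truth <- cbind(x = nuclei$cx, y = nuclei$cy, z = nuclei$cz)
  structure(list(stack = image_stack(vox, spacing, bit_depth),
                 nuclei = nuclei, truth = truth,
                 alignment = attr(nuclei, "alignment"),
                 density = attr(nuclei, "density"),
                 seed = seed),
            class = "synthetic_scene")
}

#' Save a synthetic scene with its ground truth
#'
#' Writes the stack as a multi-page TIFF, the nucleus specs as CSV
#' (`<prefix>_truth.csv`) and all generation parameters plus seeds as a JSON
#' manifest (`<prefix>_manifest.json`). The CSV/JSON round trip is lossless;
#' regenerating from the manifest's seed reproduces the identical stack.
#'
#' @param scene A `synthetic_scene` from [render_scene()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
save_ground_truth <- function(scene, prefix) {
  stopifnot(inherits(scene, "synthetic_scene"))
  tif <- paste0(prefix, ".tif")
  csv <- paste0(prefix, "_truth.csv")
  man <- paste0(prefix, "_manifest.json")
  write_stack(scene$stack, tif)
  utils::write.csv(scene$nuclei, csv, row.names = FALSE)
  sp <- as.numeric(scene$stack$spacing)
  jsonlite::write_json(list(
    size_um = attr(scene$nuclei, "size_um"),
    density = scene$density,
    alignment = scene$alignment,
    spacing = sp,
    bit_depth = scene$stack$bit_depth,
    scene_seed = attr(scene$nuclei, "seed"),
    render_seed = scene$seed,
    n_nuclei = nrow(scene$nuclei)
  ), man, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, csv, man))
}

#' Read back a ground-truth CSV written by [save_ground_truth()]
#' @param path CSV path.
#' @return Data frame of nucleus specs.
#' @export
read_ground_truth <- function(path) utils::read.csv(path)
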