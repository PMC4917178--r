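# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive R, sharing no code path with the package internals.

# dense 2D correlation with edge replication
oracle_conv2d <- function(mat, kernel) {
  ry <- (nrow(kernel) - 1) / 2
  rx <- (ncol(kernel) - 1) / 2
  ny <- nrow(mat); nx <- ncol(mat)
  out <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    acc <- 0
    for (ky in 1:nrow(kernel)) for (kx in 1:ncol(kernel)) {
      yy <- min(max(y + ky - ry - 1, 1), ny)
      xx <- min(max(x + kx - rx - 1, 1), nx)
      acc <- acc + kernel[ky, kx] * mat[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

oracle_median2d <- function(mat, win) {
  r <- (win - 1) / 2
  ny <- nrow(mat); nx <- ncol(mat)
  out <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r)
      vals <- c(vals, mat[min(max(y + dy, 1), ny), min(max(x + dx, 1), nx)])
    out[y, x] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# one explicit Perona-Malik step, 4-neighbour, zero-flux borders
oracle_pm_step <- function(mat, kappa, lam) {
  ny <- nrow(mat); nx <- ncol(mat)
  out <- mat
  for (y in 1:ny) for (x in 1:nx) {
    c0 <- mat[y, x]
    acc <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      yy <- min(max(y + d[1], 1), ny); xx <- min(max(x + d[2], 1), nx)
      df <- mat[yy, xx] - c0
      acc <- acc + exp(-(df / kappa)^2) * df
    }
    out[y, x] <- c0 + lam * acc
  }
  out
}

oracle_gauss_kernel2d <- function(sigma, win) {
  r <- (win - 1) / 2
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# finite differences of the smoothed slice (replicated edges)
oracle_derivs <- function(mat, sigma_g) {
  win <- max(3, 2 * ceiling(3 * sigma_g) + 1)
  s <- oracle_conv2d(mat, oracle_gauss_kernel2d(sigma_g, win))
  ny <- nrow(s); nx <- ncol(s)
  at <- function(y, x) s[min(max(y, 1), ny), min(max(x, 1), nx)]
  ix <- iy <- ixx <- iyy <- ixy <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    ix[y, x] <- (at(y, x + 1) - at(y, x - 1)) / 2
    iy[y, x] <- (at(y + 1, x) - at(y - 1, x)) / 2
    ixx[y, x] <- at(y, x + 1) - 2 * at(y, x) + at(y, x - 1)
    iyy[y, x] <- at(y + 1, x) - 2 * at(y, x) + at(y - 1, x)
    ixy[y, x] <- (at(y + 1, x + 1) - at(y + 1, x - 1) -
                    at(y - 1, x + 1) + at(y - 1, x - 1)) / 4
  }
  list(ix = ix, iy = iy, ixx = ixx, iyy = iyy, ixy = ixy)
}

# exhaustive between-class variance maximization on the same 256-bin grid
oracle_otsu <- function(slice) {
  rng <- range(slice)
  if (diff(rng) == 0) return(Inf)
  nb <- 256
  breaks <- seq(rng[1], rng[2], length.out = nb + 1)
  bin <- pmin(findInterval(slice, breaks, all.inside = TRUE), nb)
  best <- -Inf; best_t <- 1
  for (t in 1:(nb - 1)) {
    lo <- bin <= t; n1 <- sum(lo); n2 <- length(bin) - n1
    if (n1 == 0 || n2 == 0) next
    sb <- n1 * n2 * (mean(bin[lo]) - mean(bin[!lo]))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  breaks[best_t + 1]
}

# BFS flood fill labelling; returns partition as a list of sorted index sets
oracle_components <- function(bin, connectivity = 26) {
  d <- dim(bin)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  for (i in which(bin != 0)) {
    if (lab[i]) next
    nxt <- nxt + 1L
    queue <- i; lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ai <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        y <- ai[1] + offs$dy[k]; x <- ai[2] + offs$dx[k]; z <- ai[3] + offs$dz[k]
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
        j <- y + d[1] * (x - 1) + d[1] * d[2] * (z - 1)
        if (bin[j] != 0 && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
      }
    }
  }
  unname(lapply(split(which(lab > 0), lab[lab > 0]), sort))
}

# brute-force max-cardinality min-cost matching with a forbidden radius
oracle_match <- function(truth, det, radius) {
  nt <- nrow(truth); nd <- nrow(det)
  if (nt == 0 || nd == 0) return(list(pairs = 0L, cost = 0))
  D <- as.matrix(stats::dist(rbind(truth, det)))[1:nt, nt + (1:nd), drop = FALSE]
  best <- list(pairs = -1L, cost = Inf)
  rec <- function(i, used, pairs, cost) {
    if (i > nt) {
      if (pairs > best$pairs || (pairs == best$pairs && cost < best$cost))
        best <<- list(pairs = pairs, cost = cost)
      return(invisible())
    }
    rec(i + 1, used, pairs, cost)            # leave truth i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && D[i, j] <= radius) {
        used[j] <- TRUE
        rec(i + 1, used, pairs + 1L, cost + D[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nd), 0L, 0)
  best
}

# binary-mask object from a union of spheres; returns a segmented-object list
sphere_union_object <- function(centers_um, radius_um, spacing = reference_spacing(),
                                pad_um = 3) {
  sp <- as.numeric(spacing)
  hi <- apply(centers_um, 2, max) + radius_um + pad_um
  nx <- ceiling(hi[1] / sp[1]); ny <- ceiling(hi[2] / sp[2]); nz <- ceiling(hi[3] / sp[3])
  g <- expand.grid(x = 1:nx, y = 1:ny, z = 1:nz)
  px <- (g$x - 0.5) * sp[1]; py <- (g$y - 0.5) * sp[2]; pz <- (g$z - 0.5) * sp[3]
  inside <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(centers_um)))
    inside <- inside | ((px - centers_um[i, 1])^2 + (py - centers_um[i, 2])^2 +
                          (pz - centers_um[i, 3])^2 <= radius_um^2)
  vox <- cbind(x = g$x[inside], y = g$y[inside], z = g$z[inside])
  list(object_id = 1L, voxels = vox, volume = nrow(vox),
       centroid_um = unname((colMeans(vox) - 0.5) * sp))
}

# a few well-separated spherical nuclei rendered as an intensity scene
separated_scene <- function(seed = 1, n = 5, r_um = 2.75, box = c(34, 34, 30)) {
  centers <- rbind(c(7, 7, 7), c(27, 7, 7), c(7, 27, 7), c(27, 27, 22),
                   c(17, 17, 15), c(7, 27, 22), c(27, 7, 22))[seq_len(n), , drop = FALSE]
  nuc <- data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                    a = r_um, b = r_um, c = r_um, ux = 1, uy = 0, uz = 0)
  attr(nuc, "size_um") <- box
  attr(nuc, "density") <- n / prod(box)
  attr(nuc, "seed") <- seed
  render_scene(nuc, intensity_model(5), reference_spacing(), seed = seed)
}

# minimal uncompressed RGB TIFF (2 x 2), for rejection tests
write_rgb_tiff <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeBin(charToRaw("II"), con); w(42, 2); w(8, 4)
  entry <- function(tag, type, count, value) {
    w(tag, 2); w(type, 2); w(count, 4)
    if (type == 3) { w(value, 2); w(0, 2) } else w(value, 4)
  }
  # IFD with 8 entries at offset 8; pixel data after IFD
  n <- 8
  w(n, 2)
  data_off <- 8 + 2 + n * 12 + 4
  entry(256, 4, 1, 2); entry(257, 4, 1, 2)
  entry(258, 3, 1, 8)                      # bits per sample (abbreviated)
  entry(259, 3, 1, 1); entry(262, 3, 1, 2) # photometric RGB
  entry(273, 4, 1, data_off)
  entry(277, 3, 1, 3)                      # samples per pixel 3
  entry(279, 4, 1, 12)
  w(0, 4)
  writeBin(as.integer(rep(c(255, 0, 0), 4)), con, size = 1)
  invisible(path)
}
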