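#' Voxel geometry of an image stack
#'
#' Physical size of one voxel in micrometres. The default matches the
#' high-content acquisition grid used throughout the package:
#' 0.217 x 0.217 um laterally and 0.500 um between z-planes, i.e. an
#' anisotropic grid with z-pitch roughly 2.3x the lateral pitch.
#'
#' @param dx,dy lateral voxel pitch in um (x and y).
#' @param dz axial pitch (plane spacing) in um.
#' @return An object of class `voxel_spec`.
#' @examples
#' voxel_spec()
#' voxel_spec(0.1, 0.1, 0.3)
#' @export
voxel_spec <- function(dx = 0.217, dy = 0.217, dz = 0.500) {
  dx <- as.numeric(dx); dy <- as.numeric(dy); dz <- as.numeric(dz)
  if (length(dx) != 1L || length(dy) != 1L || length(dz) != 1L ||
      !all(is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("voxel pitches must be single positive finite numbers")
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spec")
}

#' @export
print.voxel_spec <- function(x, ...) {
  cat(sprintf("voxel: %.4g x %.4g x %.4g um (x, y, z)\n", x$dx, x$dy, x$dz))
  invisible(x)
}

as_voxel_spec <- function(x) {
  if (inherits(x, "voxel_spec")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(voxel_spec(x[1], x[2], x[3]))
  stop("cannot interpret 'voxel' as a voxel_spec")
}

voxel_volume <- function(voxel) voxel$dx * voxel$dy * voxel$dz

#' Label connected components in a 3D mask
#'
#' Flood-fill connected-component labelling of a binary volume. An "object"
#' is a connected group of voxels; 26-connectivity (faces, edges and corners)
#' is the default neighbourhood.
#'
#' @param mask logical or numeric 3D array; non-zero / TRUE is foreground.
#' @param connectivity 26 (default) or 6.
#' @return Integer 3D array of labels, 0 = background, objects numbered from 1
#'   in raster order of first occurrence.
#' @examples
#' m <- array(FALSE, c(4, 4, 2)); m[1, 1, 1] <- TRUE; m[4, 4, 2] <- TRUE
#' table(label_components(m))
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) == 2L) {
    d <- c(d, 1L)
    dim(mask) <- d
  }
  if (length(d) != 3L) stop("mask must be a 2D or 3D array")
  .cc3d_label(as.logical(mask != 0), as.integer(d), as.integer(connectivity))
}

# --- small numeric kernels shared across modules ------------------------------

# Separable Gaussian smoothing of a 3D array; sigma given per axis in voxels.
# Zero-padded convolution (values near the border are attenuated, which is the
# desired behaviour for indicator functions of compact objects).
gauss_smooth3 <- function(x, sigma) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be 3D")
  sigma <- rep_len(sigma, 3L)
  conv_axis <- function(a, s, axis) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    dd <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dd[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[i] * m[src[ok], ]
    }
    ap <- array(out, dim(ap))
    aperm(ap, order(perm))
  }
  x <- conv_axis(x, sigma[1], 1L)
  x <- conv_axis(x, sigma[2], 2L)
  conv_axis(x, sigma[3], 3L)
}

# Squared Euclidean distance transform of a 1D sampled function
# (Felzenszwalb & Huttenlocher lower envelope of parabolas).
edt1d_sq <- function(f, step = 1) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); zl <- numeric(n + 1L)
  d <- numeric(n)
  k <- 1L
  v[1L] <- 1L
  zl[1L] <- -Inf; zl[2L] <- Inf
  s2 <- step * step
  for (q in 2L:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (s <= zl[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    zl[k] <- s
    zl[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (zl[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

# Euclidean distance transform of a 2D logical mask: for every TRUE pixel the
# physical distance (um) to the nearest FALSE pixel (or to the array border,
# treated as background when border_is_background).
edt2d <- function(mask, dx = 1, dy = 1, border_is_background = TRUE) {
  m <- mask
  if (border_is_background) {
    m2 <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
    m2[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
    m <- m2
  }
  big <- (sum(dim(m))^2) * (dx^2 + dy^2)
  f <- ifelse(m, big, 0)
  # pass along rows (x), then columns (y)
  f <- apply(f, 2L, edt1d_sq, step = dx)
  f <- t(apply(f, 1L, edt1d_sq, step = dy))
  d <- sqrt(pmin(f, big))
  if (border_is_background)
    d <- d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
  d
}

# Anisotropic 3D EDT (distance of foreground voxels to nearest background).
edt3d <- function(mask, voxel = voxel_spec()) {
  voxel <- as_voxel_spec(voxel)
  d <- dim(mask)
  big <- (sum(d)^2) * (voxel$dx^2 + voxel$dy^2 + voxel$dz^2)
  f <- array(ifelse(mask, big, 0), d)
  along <- function(a, axis, step) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    m <- apply(m, 2L, edt1d_sq, step = step)
    aperm(array(m, dim(ap)), order(perm))
  }
  f <- along(f, 1L, voxel$dx)
  f <- along(f, 2L, voxel$dy)
  f <- along(f, 3L, voxel$dz)
  sqrt(pmin(f, big))
}

# voxel centre coordinates (um) along each axis of a volume
axis_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

# bounding box of a 3D mask as index ranges; NULL if empty
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  apply(w, 2L, range)
}
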