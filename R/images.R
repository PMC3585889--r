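#' Image and grid utilities
#'
#' Images throughout the package are plain numeric matrices with values in
#' \[0, 1\]; rows index the vertical (y) axis, columns the horizontal (x)
#' axis, matching the convention of [png::readPNG()].
#'
#' @name image-utils
#' @keywords internal
NULL

#' Validate a grayscale image matrix
#'
#' Checks that `img` is a finite numeric matrix with values in \[0, 1\].
#'
#' @param img numeric matrix.
#' @param min_dim minimum allowed side length (default 1).
#' @param what name used in error messages.
#' @return the validated matrix, invisibly usable downstream.
#' @export
validate_image <- function(img, min_dim = 1L, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(img)))
    stop(what, " contains non-finite pixels", call. = FALSE)
  if (min(img) < -1e-12 || max(img) > 1 + 1e-12)
    stop(what, " must be normalized to [0, 1]", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(what, sprintf(" must be at least %dx%d", min_dim, min_dim),
         call. = FALSE)
  img
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8- or 16-bit images are normalized to \[0, 1\] (the readers already divide
#' by the dtype maximum). RGB input is converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning; an alpha channel is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      warning("RGB input converted to luminance", call. = FALSE)
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  pmin(pmax(x, 0), 1)
}

#' Write a grayscale image or binary mask as 8-bit PNG
#'
#' Masks are written with object = 255 and background = 0.
#'
#' @param img numeric matrix in \[0, 1\], or a logical/0-1 mask.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img * 1.0, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

# Mirror (reflective, edge not duplicated) index into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # period of the reflected sequence is 2n - 2
  j <- (i - 1L) %% (2L * n - 2L)
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

# Pad a matrix by r pixels on each side with mirror reflection.
mirror_pad <- function(m, r) {
  if (r == 0L) return(m)
  ri <- reflect_index(seq(1L - r, nrow(m) + r), nrow(m))
  ci <- reflect_index(seq(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dy, dx): out[y, x] = m[y + dy, x + dx] where the source
# index is valid, `fill` elsewhere.
shift_mat <- function(m, dy, dx, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1L, 1L - dy):min(H, H - dy)
  xs <- max(1L, 1L - dx):min(W, W - dx)
  if (length(ys) > 0L && length(xs) > 0L)
    out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# Sampled, sum-normalized 1-D Gaussian kernel.
gauss_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  z <- seq(-radius, radius)
  k <- exp(-z^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with mirror padding (used for Gaussian smoothing).
conv_sep_mirror <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(img * k)
  p <- mirror_pad(img, r)
  H <- nrow(img); W <- ncol(img)
  # rows direction
  acc <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k))
    acc <- acc + k[i] * p[(i - 1L) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k))
    out <- out + k[i] * acc[, (i - 1L) + seq_len(W), drop = FALSE]
  out
}

# Gaussian smoothing with mirror boundary.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep_mirror(img, gauss_kernel1d(sigma))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
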