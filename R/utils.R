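#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate a function with a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that seeded operations inside the package never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

#' Bilinear interpolation of a grayscale image at real-valued coordinates
#'
#' Coordinates are 0-based: (x, y) = (0, 0) is the center of the top-left
#' pixel, x runs along columns and y along rows. Samples outside the image
#' are clamped to the border.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of equal length.
#' @return numeric vector of sampled values.
#' @noRd
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1)
  y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Separable Gaussian blur of a matrix (reflective borders)
#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(2.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) clamp(c((r:1), seq_len(n), n - (0:(r - 1))), 1L, n)
  # rows
  m <- img[pad_idx(nrow(img)), , drop = FALSE]
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- m[(r + 1):(r + nrow(img)), , drop = FALSE]
  # cols
  m2 <- m[, pad_idx(ncol(img)), drop = FALSE]
  m2 <- t(apply(m2, 1, function(row) stats::filter(row, k, sides = 2)))
  m2[, (r + 1):(r + ncol(img)), drop = FALSE]
}

#' Bounding box of a set of points
#' @param pts n x 2 matrix of (x, y); NA rows ignored.
#' @return list(xmin, xmax, ymin, ymax) or NULL if no finite points.
#' @noRd
points_bbox <- function(pts) {
  ok <- stats::complete.cases(pts)
  if (!any(ok)) return(NULL)
  p <- pts[ok, , drop = FALSE]
  list(xmin = min(p[, 1]), xmax = max(p[, 1]),
       ymin = min(p[, 2]), ymax = max(p[, 2]))
}
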