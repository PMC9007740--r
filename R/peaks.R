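#' Peak tables
#'
#' Peak-finding functions return a data.frame with one row per detected
#' peak and columns:
#' \describe{
#'   \item{channel}{node (channel) index, 1-based}
#'   \item{gx, gy}{integer grid coordinates of the peak pixel (0-based)}
#'   \item{x, y}{image coordinates; equal to `gx * s_o`, `gy * s_o` until
#'     [refine_peaks()] updates them}
#'   \item{value}{confidence value at the peak pixel}
#' }
#' @name peak-table
#' @keywords internal
NULL

empty_peaks <- function() {
  data.frame(channel = integer(), gx = integer(), gy = integer(),
             x = numeric(), y = numeric(), value = numeric())
}

#' Find the global peak of each confidence-map channel
#'
#' For single-instance maps: per channel, the pixel with the highest value,
#' provided it reaches the confidence threshold. Ties are broken toward the
#' lowest (row, column) in raster order so results are deterministic.
#'
#' @param cms a [encode_confidence_maps()] result (or compatible object).
#' @param threshold minimum confidence to report a peak (default 0.2, which
#'   retains low-confidence predictions while dropping parts predicted as
#'   not visible).
#' @return a [peak-table] with at most one row per channel.
#' @export
find_global_peaks <- function(cms, threshold = 0.2) {
  stopifnot(inherits(cms, "confidence_maps"))
  tensor <- cms$tensor
  stride <- cms$grid$stride
  out <- empty_peaks()
  for (ch in seq_len(dim(tensor)[3])) {
    m <- tensor[, , ch]
    top <- max(m)
    if (!is.finite(top) || top < threshold) next
    hits <- which(m == top, arr.ind = TRUE)
    best <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
    gx <- unname(best[2]) - 1L; gy <- unname(best[1]) - 1L
    out <- rbind(out, data.frame(channel = ch, gx = gx, gy = gy,
                                 x = gx * stride, y = gy * stride,
                                 value = top))
  }
  out
}

# Maximum over the 8-neighborhood of every pixel, computed by shifting the
# matrix in each direction with -Inf padding (grayscale dilation with a 3x3
# kernel whose center is excluded).
neighborhood_max <- function(m) {
  h <- nrow(m); w <- ncol(m)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nb <- shift(-1, -1)
  for (d in list(c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))) {
    nb <- pmax(nb, shift(d[1], d[2]))
  }
  nb
}

#' Find all local peaks in multi-instance confidence maps
#'
#' A pixel is a local peak when it is strictly greater than each of its
#' eight neighbors (non-maximum suppression via grayscale dilation with the
#' center pixel excluded) and reaches the confidence threshold. Borders are
#' handled by implicit -Inf padding; plateaus yield no peak.
#'
#' @inheritParams find_global_peaks
#' @return a [peak-table], ordered by (channel, gy, gx).
#' @export
find_local_peaks <- function(cms, threshold = 0.2) {
  stopifnot(inherits(cms, "confidence_maps"))
  tensor <- cms$tensor
  stride <- cms$grid$stride
  out_list <- list()
  for (ch in seq_len(dim(tensor)[3])) {
    m <- tensor[, , ch]
    is_peak <- (m > neighborhood_max(m)) & (m >= threshold)
    if (!any(is_peak)) next
    hits <- which(is_peak, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    gx <- hits[, 2] - 1L; gy <- hits[, 1] - 1L
    out_list[[length(out_list) + 1L]] <- data.frame(
      channel = ch, gx = gx, gy = gy,
      x = gx * stride, y = gy * stride,
      value = m[hits])
  }
  if (!length(out_list)) return(empty_peaks())
  out <- do.call(rbind, out_list)
  rownames(out) <- NULL
  out
}

#' Subpixel refinement by integral regression
#'
#' Updates the image coordinates of grid-aligned peaks with the
#' confidence-weighted mean offset of the local `patch_size` x `patch_size`
#' patch around each peak (integral regression). Patches are clipped at map
#' borders; an all-zero patch leaves the peak unmoved. The refined
#' coordinate is `(grid + offset) * s_o`.
#'
#' @param cms the confidence maps the peaks came from.
#' @param peaks a [peak-table] from [find_global_peaks()] or
#'   [find_local_peaks()].
#' @param patch_size odd patch side length (default 5).
#' @return the peak table with updated `x`, `y`.
#' @export
refine_peaks <- function(cms, peaks, patch_size = 5L) {
  stopifnot(inherits(cms, "confidence_maps"),
            is_count(patch_size), patch_size >= 1, patch_size %% 2 == 1)
  if (nrow(peaks) == 0L) return(peaks)
  tensor <- cms$tensor
  stride <- cms$grid$stride
  half <- (patch_size - 1L) %/% 2L
  h <- dim(tensor)[1]; w <- dim(tensor)[2]
  for (k in seq_len(nrow(peaks))) {
    r0 <- peaks$gy[k] + 1L; c0 <- peaks$gx[k] + 1L
    rs <- max(1L, r0 - half):min(h, r0 + half)
    cs <- max(1L, c0 - half):min(w, c0 + half)
    patch <- tensor[rs, cs, peaks$channel[k], drop = TRUE]
    patch <- matrix(patch, length(rs), length(cs))
    tot <- sum(patch)
    if (tot > 0) {
      dx <- sum(patch %*% (cs - c0)) / tot
      dy <- sum((rs - r0) %*% patch) / tot
    } else {
      dx <- 0; dy <- 0
    }
    peaks$x[k] <- (peaks$gx[k] + dx) * stride
    peaks$y[k] <- (peaks$gy[k] + dy) * stride
  }
  peaks
}
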