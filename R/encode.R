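#' Define the target grid for encoded tensors
#'
#' Encoded tensors (confidence maps, part affinity fields, class maps) live
#' on a grid downsampled from the image by the output stride `s_o`. Grid
#' pixel `(gx, gy)` corresponds to image coordinate `(gx * s_o, gy * s_o)`
#' (no half-pixel offset), so a stride-1 grid is identical to image
#' coordinates. The effective Gaussian spread is `sigma_base * s_o`, keeping
#' a fixed scale relative to image resolution.
#'
#' @param height,width image size in pixels.
#' @param output_stride one of 1, 2, 4, 8.
#' @param sigma_base confidence-map spread in grid units (default 1.0; values
#'   of 1.5-3.0 give smoother maps at the cost of subpixel-refinement bias).
#' @return object of class `grid_spec` with derived fields `grid_height`,
#'   `grid_width` and `sigma` (the effective image-space spread).
#' @export
grid_spec <- function(height, width, output_stride = 1L, sigma_base = 1.0) {
  stopifnot(is_count(height), height > 0, is_count(width), width > 0)
  if (!output_stride %in% c(1L, 2L, 4L, 8L)) {
    stop("`output_stride` must be one of 1, 2, 4, 8")
  }
  stopifnot(is.numeric(sigma_base), sigma_base > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 stride = as.integer(output_stride),
                 sigma_base = as.numeric(sigma_base),
                 grid_height = as.integer(ceiling(height / output_stride)),
                 grid_width = as.integer(ceiling(width / output_stride)),
                 sigma = as.numeric(sigma_base * output_stride)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: image %dx%d, stride %d, grid %dx%d, sigma %.2f px>\n",
              x$height, x$width, x$stride, x$grid_height, x$grid_width, x$sigma))
  invisible(x)
}

# x coordinates (image px) of grid columns / y of grid rows
grid_xs <- function(grid) (seq_len(grid$grid_width) - 1) * grid$stride
grid_ys <- function(grid) (seq_len(grid$grid_height) - 1) * grid$stride

#' Encode instances as part confidence maps
#'
#' For each body part i the map value at grid pixel p is the unnormalized
#' Gaussian `exp(-||x_i - x_p||^2 / (2 sigma^2)) * delta_i`, where `delta_i`
#' is the visibility flag. Maps from multiple instances are combined by the
#' per-pixel maximum, which keeps closely spaced peaks separable. Invisible
#' parts contribute an all-zero map. For tractability each Gaussian is only
#' evaluated within `ceiling(8 sigma)` px of its center; omitted tail values
#' are below 1.6e-14.
#'
#' @param instances list of [pose_instance()] (may be empty).
#' @param grid a [grid_spec()].
#' @return object of class `confidence_maps` holding `tensor`
#'   (grid_height x grid_width x n_nodes), `grid` and `node_names`.
#' @export
encode_confidence_maps <- function(instances, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  skel <- if (length(instances)) instances[[1]]$skeleton else NULL
  nn <- if (is.null(skel)) 0L else n_nodes(skel)
  tensor <- array(0, dim = c(grid$grid_height, grid$grid_width, max(nn, 1L)))
  if (nn == 0L) {
    return(structure(list(tensor = tensor, grid = grid, node_names = character()),
                     class = "confidence_maps"))
  }
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  s2 <- 2 * grid$sigma^2
  win <- ceiling(8 * grid$sigma)
  for (inst in instances) {
    for (i in which(inst$visible)) {
      cx <- inst$points[i, 1]; cy <- inst$points[i, 2]
      ci <- which(xs >= cx - win & xs <= cx + win)
      ri <- which(ys >= cy - win & ys <= cy + win)
      if (!length(ci) || !length(ri)) next
      g <- outer(exp(-(ys[ri] - cy)^2 / s2), exp(-(xs[ci] - cx)^2 / s2))
      tensor[ri, ci, i] <- pmax(tensor[ri, ci, i], g)
    }
  }
  structure(list(tensor = tensor, grid = grid, node_names = skel$nodes),
            class = "confidence_maps")
}

#' @export
print.confidence_maps <- function(x, ...) {
  cat(sprintf("<confidence_maps: %d x %d x %d channels, stride %d>\n",
              dim(x$tensor)[1], dim(x$tensor)[2], dim(x$tensor)[3],
              x$grid$stride))
  invisible(x)
}

#' Encode instances as part affinity fields
#'
#' For every skeleton edge e = (s, d) the field at grid pixel p is the unit
#' vector `u_e` from source to destination, weighted by a Gaussian in the
#' distance `M(p)` between p and its clamped projection onto the segment
#' (`exp(-M^2 / (2 sigma^2))`), and gated by both endpoint visibilities.
#' Fields from multiple instances are combined by summation. Zero-length
#' edges produce an all-zero field for that instance (direction undefined)
#' with a message.
#'
#' @param instances list of [pose_instance()].
#' @param skeleton the shared skeleton (validated tree/forest).
#' @param grid a [grid_spec()].
#' @param paf_sigma spatial spread of the field in image pixels (default 5).
#' @return object of class `part_affinity_fields` with `tensor`
#'   (grid_height x grid_width x 2|E|; x/y components interleaved per edge),
#'   `grid` and `edges`.
#' @export
encode_pafs <- function(instances, skeleton, grid, paf_sigma = 5) {
  stopifnot(inherits(skeleton, "pose_skeleton"), inherits(grid, "grid_spec"))
  viol <- validate_skeleton(skeleton)
  if (length(viol)) stop("invalid skeleton: ", viol[1])
  ne <- nrow(skeleton$edges)
  tensor <- array(0, dim = c(grid$grid_height, grid$grid_width, max(2L * ne, 1L)))
  if (ne == 0L) {
    return(structure(list(tensor = tensor, grid = grid, edges = skeleton$edges,
                          paf_sigma = paf_sigma),
                     class = "part_affinity_fields"))
  }
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  px <- matrix(xs, grid$grid_height, grid$grid_width, byrow = TRUE)
  py <- matrix(ys, grid$grid_height, grid$grid_width)
  s2 <- 2 * paf_sigma^2
  for (inst in instances) {
    for (e in seq_len(ne)) {
      s <- skeleton$edges[e, 1]; d <- skeleton$edges[e, 2]
      if (!inst$visible[s] || !inst$visible[d]) next
      xsrc <- inst$points[s, ]; xdst <- inst$points[d, ]
      v <- xdst - xsrc
      len2 <- sum(v^2)
      if (len2 == 0) {
        message(sprintf("zero-length edge %d (%s -> %s): field left zero",
                        e, skeleton$nodes[s], skeleton$nodes[d]))
        next
      }
      ue <- v / sqrt(len2)
      r <- clamp(((px - xsrc[1]) * v[1] + (py - xsrc[2]) * v[2]) / len2, 0, 1)
      projx <- xsrc[1] + r * v[1]
      projy <- xsrc[2] + r * v[2]
      m2 <- (px - projx)^2 + (py - projy)^2
      w <- exp(-m2 / s2)
      tensor[, , 2L * e - 1L] <- tensor[, , 2L * e - 1L] + w * ue[1]
      tensor[, , 2L * e] <- tensor[, , 2L * e] + w * ue[2]
    }
  }
  structure(list(tensor = tensor, grid = grid, edges = skeleton$edges,
                 paf_sigma = paf_sigma),
            class = "part_affinity_fields")
}

#' @export
print.part_affinity_fields <- function(x, ...) {
  cat(sprintf("<part_affinity_fields: %d x %d, %d edges, stride %d>\n",
              dim(x$tensor)[1], dim(x$tensor)[2], nrow(x$edges),
              x$grid$stride))
  invisible(x)
}

#' Encode instances as class maps for appearance-based identification
#'
#' Marks a binary disk of fixed radius around each visible body part, with
#' all of an instance's disks collapsed into the channel of its class.
#' Pixels claimed by two or more distinct classes are ambiguous and zeroed
#' in every channel, so the assignment signal never contradicts itself.
#'
#' @param instances list of [pose_instance()], each carrying `class_id` in
#'   `[1, n_classes]`.
#' @param n_classes number of identity classes (channels).
#' @param radius disk radius in image pixels.
#' @param grid a [grid_spec()].
#' @return object of class `class_maps` with `tensor`
#'   (grid_height x grid_width x n_classes) in \{0, 1\}, `grid`, `radius`.
#' @export
encode_class_maps <- function(instances, n_classes, radius, grid) {
  stopifnot(inherits(grid, "grid_spec"), is_count(n_classes), n_classes >= 1,
            is.numeric(radius), radius > 0)
  lacking <- which(vapply(instances, function(i) is.null(i$class_id), logical(1)))
  if (length(lacking)) {
    stop("instance(s) lacking class_id: ", paste(lacking, collapse = ", "))
  }
  bad <- which(vapply(instances, function(i)
    i$class_id < 1L || i$class_id > n_classes, logical(1)))
  if (length(bad)) {
    stop("instance class_id out of range [1, ", n_classes, "]: ",
         paste(bad, collapse = ", "))
  }
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  px <- matrix(xs, grid$grid_height, grid$grid_width, byrow = TRUE)
  py <- matrix(ys, grid$grid_height, grid$grid_width)
  tensor <- array(0, dim = c(grid$grid_height, grid$grid_width, n_classes))
  r2 <- radius^2
  for (inst in instances) {
    ch <- inst$class_id
    for (i in which(inst$visible)) {
      hit <- (px - inst$points[i, 1])^2 + (py - inst$points[i, 2])^2 <= r2
      tensor[, , ch][hit] <- 1
    }
  }
  if (n_classes > 1L) {
    claimed <- apply(tensor, c(1, 2), sum)
    amb <- claimed > 1
    if (any(amb)) for (ch in seq_len(n_classes)) tensor[, , ch][amb] <- 0
  }
  structure(list(tensor = tensor, grid = grid, radius = radius),
            class = "class_maps")
}

#' Automatic crop size for top-down decoding
#'
#' The smallest even integer that is a multiple of `multiple` and at least
#' the largest instance bounding-box side plus margins on both sides, so a
#' single fixed crop size fits every labeled animal.
#'
#' @param dataset a non-empty [labels_dataset()].
#' @param margin_px margin added on each side (default 16).
#' @param multiple round up to a multiple of this (default 32, matching
#'   typical network stride constraints); bumped to the next even multiple
#'   if odd.
#' @return even integer crop size in pixels.
#' @export
compute_crop_size <- function(dataset, margin_px = 16, multiple = 32L) {
  stopifnot(inherits(dataset, "labels_dataset"))
  insts <- unlist(lapply(dataset$frames, `[[`, "instances"), recursive = FALSE)
  if (!length(insts)) stop("dataset has no instances")
  side <- max(vapply(insts, function(inst) {
    bb <- instance_bbox(inst)
    max(bb$xmax - bb$xmin, bb$ymax - bb$ymin)
  }, numeric(1)))
  need <- side + 2 * margin_px
  step <- as.integer(multiple)
  if (step %% 2L == 1L) step <- 2L * step
  size <- step * ceiling(need / step)
  if (size < step) size <- step
  as.integer(size)
}

#' Select the anchor point of an instance
#'
#' The anchor centers top-down crops: the designated anchor node when
#' visible, otherwise the centroid of the bounding box of the remaining
#' visible parts.
#'
#' @param inst a [pose_instance()] with at least one visible node.
#' @param anchor_node node name or index of the preferred anchor part.
#' @return numeric (x, y) in full-frame pixels.
#' @export
select_anchor <- function(inst, anchor_node) {
  stopifnot(inherits(inst, "pose_instance"))
  if (is.character(anchor_node)) {
    anchor_node <- match(anchor_node, inst$skeleton$nodes)
    if (is.na(anchor_node)) stop("unknown anchor node name")
  }
  if (!any(inst$visible)) stop("instance has no visible nodes")
  if (inst$visible[anchor_node]) {
    return(inst$points[anchor_node, ])
  }
  bb <- instance_bbox(inst)
  c((bb$xmin + bb$xmax) / 2, (bb$ymin + bb$ymax) / 2)
}

#' Extract centered square crops around anchor points
#'
#' Each crop is a `crop_size` x `crop_size` patch of the image whose center
#' pixel (`crop_size/2`, 0-based) lies on the rounded anchor; regions
#' falling outside the frame are zero-padded. The full-precision anchor and
#' the crop's top-left offset are recorded so decoded coordinates can be
#' mapped back to the full frame.
#'
#' @param image numeric grayscale matrix (rows = y).
#' @param anchors n x 2 matrix of anchor (x, y) coordinates.
#' @param crop_size even integer.
#' @return object of class `crop_set`: list with `crops` (list of matrices),
#'   `anchors`, `offsets` (n x 2 full-frame coordinates of each crop's
#'   (0, 0) pixel) and `crop_size`.
#' @export
make_anchor_crops <- function(image, anchors, crop_size) {
  stopifnot(is.matrix(image), is_count(crop_size), crop_size > 0)
  if (crop_size %% 2L != 0L) stop("`crop_size` must be even")
  anchors <- matrix(as.numeric(anchors), ncol = 2L)
  h <- nrow(image); w <- ncol(image)
  half <- crop_size / 2
  crops <- vector("list", nrow(anchors))
  offsets <- matrix(0, nrow(anchors), 2L)
  for (k in seq_len(nrow(anchors))) {
    ox <- round(anchors[k, 1]) - half  # full-frame x of crop pixel x=0
    oy <- round(anchors[k, 2]) - half
    crop <- matrix(0, crop_size, crop_size)
    src_x <- (ox:(ox + crop_size - 1))
    src_y <- (oy:(oy + crop_size - 1))
    in_x <- which(src_x >= 0 & src_x <= w - 1)
    in_y <- which(src_y >= 0 & src_y <= h - 1)
    if (length(in_x) && length(in_y)) {
      crop[in_y, in_x] <- image[src_y[in_y] + 1, src_x[in_x] + 1]
    }
    crops[[k]] <- crop
    offsets[k, ] <- c(ox, oy)
  }
  structure(list(crops = crops, anchors = anchors, offsets = offsets,
                 crop_size = as.integer(crop_size)),
            class = "crop_set")
}
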