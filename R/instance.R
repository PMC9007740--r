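#' Construct a pose instance (one animal in one frame)
#'
#' An instance is a set of landmark coordinates for one animal, aligned with
#' a skeleton's node order. Invisible landmarks are coded as `NA` rows with
#' `visible = FALSE`; the `NA` never propagates into metrics, which mask on
#' the visibility flags.
#'
#' @param points n_nodes x 2 numeric matrix of (x, y) image coordinates
#'   (0-based pixels, pixel centers at integer coordinates).
#' @param skeleton the shared [skeleton()].
#' @param visible logical vector; defaults to rows of `points` being finite.
#' @param track_id,class_id optional integer labels.
#' @param point_scores optional per-node confidences in \[0, 1\], `NA` where
#'   invisible.
#' @param instance_score optional scalar instance score.
#' @return object of class `pose_instance`.
#' @export
pose_instance <- function(points, skeleton, visible = NULL,
                          track_id = NULL, class_id = NULL,
                          point_scores = NULL, instance_score = NULL) {
  stopifnot(inherits(skeleton, "pose_skeleton"))
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) != n_nodes(skeleton)) {
    stop(sprintf("`points` must be a %d x 2 matrix matching the skeleton",
                 n_nodes(skeleton)))
  }
  storage.mode(points) <- "double"
  finite <- is.finite(points[, 1]) & is.finite(points[, 2])
  if (is.null(visible)) visible <- finite
  visible <- as.logical(visible)
  if (length(visible) != nrow(points)) {
    stop("`visible` must have one flag per node")
  }
  if (any(visible & !finite)) {
    stop("visible nodes must have finite coordinates")
  }
  if (!any(visible)) stop("an instance needs at least one visible node")
  points[!visible, ] <- NA_real_
  if (!is.null(point_scores)) {
    point_scores <- as.numeric(point_scores)
    if (length(point_scores) != nrow(points)) {
      stop("`point_scores` must align with nodes")
    }
    if (any(visible & is.na(point_scores))) {
      stop("visible nodes must carry a point score when scores are supplied")
    }
    point_scores[!visible] <- NA_real_
  }
  structure(list(points = points, visible = visible, skeleton = skeleton,
                 track_id = if (!is.null(track_id)) as.integer(track_id),
                 class_id = if (!is.null(class_id)) as.integer(class_id),
                 point_scores = point_scores,
                 instance_score = if (!is.null(instance_score))
                   as.numeric(instance_score)),
            class = "pose_instance")
}

#' @export
print.pose_instance <- function(x, ...) {
  cat(sprintf("<pose_instance: %d/%d nodes visible%s%s>\n",
              sum(x$visible), length(x$visible),
              if (!is.null(x$track_id)) paste0(", track ", x$track_id) else "",
              if (!is.null(x$class_id)) paste0(", class ", x$class_id) else ""))
  invisible(x)
}

#' Axis-aligned bounding box of an instance's visible nodes
#'
#' @param inst a [pose_instance()].
#' @return list with `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
instance_bbox <- function(inst) {
  points_bbox(inst$points)
}

#' Construct a labeled frame
#'
#' @param video_id identifier of the source video/session.
#' @param frame_index nonnegative integer frame number.
#' @param instances list of [pose_instance()] sharing one skeleton.
#' @export
labeled_frame <- function(video_id, frame_index, instances = list()) {
  stopifnot(is_count(frame_index), frame_index >= 0)
  if (!all(vapply(instances, inherits, logical(1), "pose_instance"))) {
    stop("`instances` must be a list of pose_instance objects")
  }
  structure(list(video_id = as.character(video_id)[1],
                 frame_index = as.integer(frame_index),
                 instances = instances),
            class = "labeled_frame")
}

#' Construct a labels dataset
#'
#' The central container for multi-animal pose data: one skeleton, a list of
#' labeled frames (ground truth or predictions), optional track and class
#' registries, and the image size.
#'
#' @param skeleton shared [skeleton()].
#' @param frames list of [labeled_frame()].
#' @param tracks data.frame with columns `track_id` (unique integers) and
#'   `name`, or NULL.
#' @param class_names optional ordered character vector of class labels.
#' @param image_size integer (H, W) in pixels.
#' @param provenance free-text metadata.
#' @export
labels_dataset <- function(skeleton, frames = list(), tracks = NULL,
                           class_names = NULL, image_size = c(512L, 512L),
                           provenance = "") {
  stopifnot(inherits(skeleton, "pose_skeleton"))
  if (!all(vapply(frames, inherits, logical(1), "labeled_frame"))) {
    stop("`frames` must be a list of labeled_frame objects")
  }
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size <= 0L)) {
    stop("`image_size` must be positive (H, W)")
  }
  if (is.null(tracks)) {
    tracks <- data.frame(track_id = integer(), name = character(),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("track_id", "name") %in% names(tracks))) {
    stop("`tracks` must have columns track_id and name")
  }
  if (anyDuplicated(tracks$track_id)) stop("track ids must be unique")
  # frame_index unique per video
  if (length(frames)) {
    vids <- vapply(frames, `[[`, character(1), "video_id")
    fidx <- vapply(frames, `[[`, integer(1), "frame_index")
    if (anyDuplicated(paste(vids, fidx))) {
      stop("frame_index must be unique within each video")
    }
    for (fr in frames) {
      for (inst in fr$instances) {
        if (!is.null(inst$track_id) && !(inst$track_id %in% tracks$track_id)) {
          stop(sprintf("instance in frame %d references unknown track %d",
                       fr$frame_index, inst$track_id))
        }
        if (!is.null(inst$class_id) &&
            (is.null(class_names) || inst$class_id > length(class_names) ||
             inst$class_id < 1L)) {
          stop(sprintf("instance in frame %d references unknown class %s",
                       fr$frame_index, inst$class_id))
        }
      }
    }
  }
  structure(list(skeleton = skeleton, frames = frames, tracks = tracks,
                 class_names = class_names, image_size = image_size,
                 provenance = as.character(provenance)[1]),
            class = "labels_dataset")
}

#' @export
print.labels_dataset <- function(x, ...) {
  n_inst <- sum(vapply(x$frames, function(f) length(f$instances), integer(1)))
  cat(sprintf(paste0("<labels_dataset: %d frames, %d instances, skeleton ",
                     "'%s' (%d nodes), %d tracks, image %dx%d>\n"),
              length(x$frames), n_inst, x$skeleton$name,
              n_nodes(x$skeleton), nrow(x$tracks),
              x$image_size[1], x$image_size[2]))
  invisible(x)
}
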