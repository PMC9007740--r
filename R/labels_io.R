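#' Save a labels dataset to a portable HDF5 container
#'
#' Writes the whole dataset (skeleton, frames, instances, tracks, metadata)
#' into a single self-contained `.poses.h5` file. Coordinates are stored as
#' IEEE doubles, so `load_labels(save_labels(d))` is bit-identical and
#' preserves ordering. Invisible nodes are stored as NaN with a false
#' visibility flag. Node indices in the stored skeleton are 0-based for
#' portability across languages.
#'
#' Layout: `/meta` (image size, provenance, class names, format version),
#' `/skeleton` (JSON text), `/tracks` (id + name columns), `/frames`
#' (per-frame video id, index, instance counts) and `/instances` (flat
#' instance table with a points tensor).
#'
#' @param dataset a [labels_dataset()].
#' @param path output file path (conventionally ending in `.poses.h5`).
#' @return `path`, invisibly.
#' @export
save_labels <- function(dataset, path) {
  stopifnot(inherits(dataset, "labels_dataset"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  skel <- dataset$skeleton
  skel_json <- jsonlite::toJSON(
    list(nodes = skel$nodes,
         edges = if (nrow(skel$edges)) unname(skel$edges - 1L)
                 else matrix(integer(), ncol = 2),
         name = skel$name),
    auto_unbox = TRUE, digits = NA)
  rhdf5::h5write(as.character(skel_json), path, "skeleton")

  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write("multipose-1", path, "meta/format_version")
  rhdf5::h5write(dataset$image_size, path, "meta/image_size")
  rhdf5::h5write(dataset$provenance, path, "meta/provenance")
  rhdf5::h5write(dataset$class_names %||% character(), path, "meta/class_names")

  rhdf5::h5createGroup(path, "tracks")
  rhdf5::h5write(as.integer(dataset$tracks$track_id), path, "tracks/track_id")
  rhdf5::h5write(as.character(dataset$tracks$name), path, "tracks/name")

  frames <- dataset$frames
  rhdf5::h5createGroup(path, "frames")
  rhdf5::h5write(vapply(frames, `[[`, character(1), "video_id") %||% character(),
                 path, "frames/video_id")
  rhdf5::h5write(vapply(frames, `[[`, integer(1), "frame_index") %||% integer(),
                 path, "frames/frame_index")
  counts <- vapply(frames, function(f) length(f$instances), integer(1))
  rhdf5::h5write(counts %||% integer(), path, "frames/n_instances")

  insts <- unlist(lapply(frames, `[[`, "instances"), recursive = FALSE)
  n_inst <- length(insts)
  nn <- n_nodes(skel)
  rhdf5::h5createGroup(path, "instances")
  if (n_inst > 0L) {
    pts <- array(NA_real_, dim = c(n_inst, nn, 2L))
    vis <- matrix(0L, n_inst, nn)
    scores <- matrix(NA_real_, n_inst, nn)
    for (k in seq_len(n_inst)) {
      pts[k, , ] <- insts[[k]]$points
      vis[k, ] <- as.integer(insts[[k]]$visible)
      if (!is.null(insts[[k]]$point_scores)) {
        scores[k, ] <- insts[[k]]$point_scores
      }
    }
    rhdf5::h5write(rep(seq_along(frames), counts), path, "instances/frame_row")
    rhdf5::h5write(vapply(insts, function(i) i$track_id %||% -1L, integer(1)),
                   path, "instances/track_id")
    rhdf5::h5write(vapply(insts, function(i) i$class_id %||% -1L, integer(1)),
                   path, "instances/class_id")
    rhdf5::h5write(vapply(insts, function(i) i$instance_score %||% NA_real_,
                          numeric(1)),
                   path, "instances/instance_score")
    rhdf5::h5write(vapply(insts, function(i) !is.null(i$point_scores),
                          logical(1)),
                   path, "instances/has_point_scores")
    rhdf5::h5write(pts, path, "instances/points")
    rhdf5::h5write(vis, path, "instances/visible")
    rhdf5::h5write(scores, path, "instances/point_scores")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load a labels dataset from its HDF5 container
#'
#' Inverse of [save_labels()]. Fails with a descriptive error naming the
#' missing group when the container is incomplete.
#'
#' @param path path to a `.poses.h5` file.
#' @return a [labels_dataset()].
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  present <- file.path(contents$group, contents$name)
  present <- sub("^//", "/", present)
  for (grp in c("/skeleton", "/meta", "/frames", "/tracks", "/instances")) {
    if (!any(present == grp)) {
      stop("container is missing required group '", grp, "': ", path)
    }
  }

  skel_json <- jsonlite::fromJSON(rhdf5::h5read(path, "skeleton"))
  edges <- skel_json$edges
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2) + 1L
  }
  skel <- skeleton(skel_json$nodes, edges, name = skel_json$name %||% "skeleton")

  image_size <- as.integer(rhdf5::h5read(path, "meta/image_size"))
  provenance <- as.character(rhdf5::h5read(path, "meta/provenance"))
  class_names <- as.character(rhdf5::h5read(path, "meta/class_names"))
  if (length(class_names) == 0L) class_names <- NULL

  tracks <- data.frame(
    track_id = as.integer(rhdf5::h5read(path, "tracks/track_id")),
    name = as.character(rhdf5::h5read(path, "tracks/name")),
    stringsAsFactors = FALSE)

  video_id <- as.character(rhdf5::h5read(path, "frames/video_id"))
  frame_index <- as.integer(rhdf5::h5read(path, "frames/frame_index"))
  counts <- as.integer(rhdf5::h5read(path, "frames/n_instances"))

  n_inst <- sum(counts)
  insts <- list()
  if (n_inst > 0L) {
    pts <- rhdf5::h5read(path, "instances/points")
    vis <- rhdf5::h5read(path, "instances/visible")
    scores <- rhdf5::h5read(path, "instances/point_scores")
    has_scores <- as.logical(rhdf5::h5read(path, "instances/has_point_scores"))
    track_id <- as.integer(rhdf5::h5read(path, "instances/track_id"))
    class_id <- as.integer(rhdf5::h5read(path, "instances/class_id"))
    inst_score <- as.numeric(rhdf5::h5read(path, "instances/instance_score"))
    insts <- lapply(seq_len(n_inst), function(k) {
      pose_instance(
        points = matrix(pts[k, , ], ncol = 2L),
        skeleton = skel,
        visible = as.logical(vis[k, ]),
        track_id = if (track_id[k] >= 0L) track_id[k],
        class_id = if (class_id[k] >= 0L) class_id[k],
        point_scores = if (has_scores[k]) scores[k, ],
        instance_score = if (!is.na(inst_score[k])) inst_score[k])
    })
  }
  offsets <- cumsum(c(0L, counts))
  frames <- lapply(seq_along(counts), function(i) {
    idx <- if (counts[i] > 0L) (offsets[i] + 1L):offsets[i + 1L] else integer()
    labeled_frame(video_id[i], frame_index[i], insts[idx])
  })
  labels_dataset(skel, frames, tracks = tracks, class_names = class_names,
                 image_size = image_size, provenance = provenance)
}

#' Split frames into train/validation/test sets
#'
#' Randomly partitions frame positions into disjoint, exhaustive subsets with
#' sizes matching the requested ratios (largest-remainder rounding), fully
#' determined by the seed. The workflow default is a 0.9/0.1 train/validation
#' split; evaluation work uses 0.8/0.1/0.1.
#'
#' @param dataset a [labels_dataset()] with at least 3 frames.
#' @param ratios numeric vector of 2 (train, val) or 3 (train, val, test)
#'   strictly positive ratios summing to 1 (tolerance 1e-9).
#' @param seed integer seed controlling the shuffle.
#' @return list with integer frame positions `train`, `val`, `test` (the
#'   latter empty for two-way splits).
#' @examples
#' # 1,000 frames at the evaluation ratios give 800/100/100
#' @export
make_splits <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(inherits(dataset, "labels_dataset"))
  n <- length(dataset$frames)
  if (n < 3L) stop("need at least 3 frames to split, got ", n)
  if (!length(ratios) %in% c(2L, 3L)) {
    stop("`ratios` must have 2 or 3 entries")
  }
  if (any(ratios <= 0)) stop("all split ratios must be strictly positive")
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")

  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac <- n * ratios - sizes
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  out <- list(
    train = sort(perm[seq_len(sizes[1])]),
    val = sort(perm[(ends[1] + 1L):ends[2]]),
    test = if (length(sizes) == 3L && sizes[3] > 0L) {
      sort(perm[(ends[2] + 1L):ends[3]])
    } else integer())
  out
}

#' Export a tracked dataset as dense point arrays
#'
#' Converts a fully tracked dataset into a dense numeric array of shape
#' (frames x tracks x nodes x 2) plus an occupancy mask, the standard shape
#' for downstream kinematic analysis. Cells with no instance (or invisible
#' nodes) are `NA`; the mask is `TRUE` exactly where a visible point exists.
#'
#' @param dataset a [labels_dataset()] whose instances all carry `track_id`.
#' @return list with `points` (array, dimnames frame/track/node/coord) and
#'   `mask` (logical array frames x tracks x nodes).
#' @export
to_point_arrays <- function(dataset) {
  stopifnot(inherits(dataset, "labels_dataset"))
  missing_tid <- vapply(dataset$frames, function(f) {
    any(vapply(f$instances, function(i) is.null(i$track_id), logical(1)))
  }, logical(1))
  if (any(missing_tid)) {
    stop("instances lacking track_id in frame(s): ",
         paste(vapply(dataset$frames[missing_tid], `[[`, integer(1),
                      "frame_index"), collapse = ", "))
  }
  track_ids <- dataset$tracks$track_id
  nn <- n_nodes(dataset$skeleton)
  nf <- length(dataset$frames)
  nt <- length(track_ids)
  pts <- array(NA_real_, dim = c(nf, nt, nn, 2L),
               dimnames = list(NULL, as.character(track_ids),
                               dataset$skeleton$nodes, c("x", "y")))
  mask <- array(FALSE, dim = c(nf, nt, nn))
  for (fi in seq_len(nf)) {
    for (inst in dataset$frames[[fi]]$instances) {
      ti <- match(inst$track_id, track_ids)
      pts[fi, ti, , ] <- inst$points
      mask[fi, ti, ] <- inst$visible
    }
  }
  list(points = pts, mask = mask)
}

#' Export tracked points as a long-format CSV table
#'
#' One row per (frame, track, node) with visible coordinates; the companion
#' flat export to [to_point_arrays()].
#'
#' @param dataset a fully tracked [labels_dataset()].
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_points_csv <- function(dataset, path) {
  rows <- list()
  for (fr in dataset$frames) {
    for (inst in fr$instances) {
      vis <- which(inst$visible)
      if (!length(vis)) next
      rows[[length(rows) + 1L]] <- data.frame(
        video = fr$video_id, frame = fr$frame_index,
        track = inst$track_id %||% NA_integer_,
        node = dataset$skeleton$nodes[vis],
        x = inst$points[vis, 1], y = inst$points[vis, 2],
        score = if (!is.null(inst$point_scores)) inst$point_scores[vis]
                else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(video = character(), frame = integer(), track = integer(),
               node = character(), x = numeric(), y = numeric(),
               score = numeric())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
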