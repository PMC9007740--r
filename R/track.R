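#' Tracker parameters
#'
#' @param window_size number of recent tracked frames kept as candidate
#'   sources (default 5).
#' @param cost_threshold maximum matching cost in pixels; `NULL` (default)
#'   derives half the median instance bounding-box diagonal from the first
#'   frame.
#' @param flow_levels pyramid levels for sparse optical flow.
#' @param flow_window odd patch side for the flow estimator (px).
#' @param flow_iterations iterative refinement steps per level.
#' @return object of class `tracker_params`.
#' @export
tracker_params <- function(window_size = 5L, cost_threshold = NULL,
                           flow_levels = 3L, flow_window = 15L,
                           flow_iterations = 10L) {
  stopifnot(is_count(window_size), window_size >= 1,
            is_count(flow_levels), flow_levels >= 1,
            is_count(flow_window), flow_window >= 3, flow_window %% 2 == 1,
            is_count(flow_iterations), flow_iterations >= 1)
  if (!is.null(cost_threshold)) {
    stopifnot(is.numeric(cost_threshold), cost_threshold > 0)
  }
  structure(list(window_size = as.integer(window_size),
                 cost_threshold = cost_threshold,
                 flow_levels = as.integer(flow_levels),
                 flow_window = as.integer(flow_window),
                 flow_iterations = as.integer(flow_iterations)),
            class = "tracker_params")
}

# 2x downsample with a small blur; image stays a plain matrix
pyr_down <- function(img) {
  img <- gaussian_blur(img, 1)
  h <- nrow(img) %/% 2L; w <- ncol(img) %/% 2L
  img[2 * seq_len(h) - 1L, 2 * seq_len(w) - 1L, drop = FALSE]
}

# Sparse iterative Lucas-Kanade at one pyramid level. pts are 0-based (x, y)
# coordinates in this level's frame; guess is the current flow estimate.
# Returns list(flow = n x 2, ok = logical).
lk_level <- function(prev, cur, pts, guess, win, iters) {
  half <- (win - 1) / 2
  n <- nrow(pts)
  flow <- guess
  ok <- rep(TRUE, n)
  offs <- as.matrix(expand.grid(dx = -half:half, dy = -half:half))
  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    if (px < 1 || py < 1 || px > ncol(prev) - 2 || py > nrow(prev) - 2) {
      ok[i] <- FALSE
      next
    }
    xs <- px + offs[, "dx"]; ys <- py + offs[, "dy"]
    ix <- (bilinear_sample(prev, xs + 1, ys) -
             bilinear_sample(prev, xs - 1, ys)) / 2
    iy <- (bilinear_sample(prev, xs, ys + 1) -
             bilinear_sample(prev, xs, ys - 1)) / 2
    g11 <- sum(ix * ix); g12 <- sum(ix * iy); g22 <- sum(iy * iy)
    det <- g11 * g22 - g12 * g12
    tr <- g11 + g22
    min_eig <- (tr - sqrt(max(tr * tr - 4 * det, 0))) / 2
    if (!is.finite(det) || min_eig < 1e-4 * win * win) {
      ok[i] <- FALSE
      next
    }
    tmpl <- bilinear_sample(prev, xs, ys)
    v <- flow[i, ]
    for (it in seq_len(iters)) {
      di <- tmpl - bilinear_sample(cur, xs + v[1], ys + v[2])
      b1 <- sum(di * ix); b2 <- sum(di * iy)
      dv <- c(g22 * b1 - g12 * b2, -g12 * b1 + g11 * b2) / det
      v <- v + dv
      if (sum(dv^2) < 1e-6) break
    }
    flow[i, ] <- v
  }
  list(flow = flow, ok = ok)
}

#' Sparse pyramidal optical flow at query points
#'
#' Estimates per-point displacement from `img_prev` to `img_cur` with an
#' iterative Lucas-Kanade solver over an image pyramid. Points where the
#' local structure tensor is degenerate (featureless patches) are flagged
#' untrackable.
#'
#' @param img_prev,img_cur grayscale matrices of identical shape.
#' @param pts n x 2 matrix of (x, y) query points, 0-based px.
#' @param params a [tracker_params()] (flow settings are used).
#' @return list with `flow` (n x 2 displacements) and `ok` (logical; FALSE
#'   rows have zero flow).
#' @export
sparse_flow <- function(img_prev, img_cur, pts, params = tracker_params()) {
  stopifnot(is.matrix(img_prev), all(dim(img_prev) == dim(img_cur)))
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(pts)
  if (n == 0L) return(list(flow = pts, ok = logical()))
  levels <- params$flow_levels
  pyr_prev <- list(img_prev); pyr_cur <- list(img_cur)
  while (length(pyr_prev) < levels &&
         min(dim(pyr_prev[[length(pyr_prev)]])) >= 2 * params$flow_window) {
    pyr_prev[[length(pyr_prev) + 1L]] <- pyr_down(pyr_prev[[length(pyr_prev)]])
    pyr_cur[[length(pyr_cur) + 1L]] <- pyr_down(pyr_cur[[length(pyr_cur)]])
  }
  L <- length(pyr_prev)
  flow <- matrix(0, n, 2L)
  ok <- rep(TRUE, n)
  for (lev in L:1) {
    scale <- 2^(lev - 1)
    res <- lk_level(pyr_prev[[lev]], pyr_cur[[lev]], pts / scale,
                    flow / scale, params$flow_window, params$flow_iterations)
    flow <- res$flow * scale
    if (lev == 1L) ok <- res$ok
  }
  flow[!ok, ] <- 0
  list(flow = flow, ok = ok)
}

#' Advect instances by optical flow
#'
#' Shifts each visible point of the previous frame's instances by the sparse
#' optical flow estimated at that point, producing the candidates used for
#' cost-based track matching. Untrackable points keep their previous
#' coordinates and are flagged in the `trackable` attribute.
#'
#' @param img_prev,img_cur consecutive grayscale frames.
#' @param instances_prev list of [pose_instance()] detected in `img_prev`.
#' @param params a [tracker_params()].
#' @return list of shifted instances (with `trackable` logical attribute).
#' @export
flow_shift <- function(img_prev, img_cur, instances_prev,
                       params = tracker_params()) {
  if (!length(instances_prev)) return(instances_prev)
  all_pts <- do.call(rbind, lapply(instances_prev, function(i)
    i$points[i$visible, , drop = FALSE]))
  res <- sparse_flow(img_prev, img_cur, all_pts, params)
  out <- instances_prev
  at <- 0L
  for (k in seq_along(out)) {
    vis <- which(out[[k]]$visible)
    idx <- at + seq_along(vis)
    at <- at + length(vis)
    pts <- out[[k]]$points
    pts[vis, ] <- pts[vis, , drop = FALSE] + res$flow[idx, , drop = FALSE]
    trackable <- rep(FALSE, length(out[[k]]$visible))
    trackable[vis] <- res$ok[idx]
    out[[k]]$points <- pts
    attr(out[[k]], "trackable") <- trackable
  }
  out
}

#' Matching cost between candidate and new instances
#'
#' Cost is the mean Euclidean distance over jointly visible nodes; pairs
#' with no shared visible node get infinite cost (never matched).
#'
#' @param candidates list of flow-shifted instances from tracked frames.
#' @param new_instances list of untracked instances in the current frame.
#' @return numeric matrix (length(candidates) x length(new_instances)).
#' @export
tracking_cost <- function(candidates, new_instances) {
  m <- matrix(Inf, length(candidates), length(new_instances))
  for (i in seq_along(candidates)) {
    for (j in seq_along(new_instances)) {
      shared <- candidates[[i]]$visible & new_instances[[j]]$visible
      if (!any(shared)) next
      d <- candidates[[i]]$points[shared, , drop = FALSE] -
        new_instances[[j]]$points[shared, , drop = FALSE]
      m[i, j] <- mean(sqrt(rowSums(d^2)))
    }
  }
  m
}

#' Initialize tracker state
#'
#' @param params a [tracker_params()].
#' @return object of class `tracker_state` holding the sliding window of
#'   tracked frames, the track registry and the id counter.
#' @export
tracker_state <- function(params = tracker_params()) {
  structure(list(register = list(), prev_img = NULL, n_seen = 0L,
                 tracks = data.frame(track_id = integer(),
                                     name = character(),
                                     stringsAsFactors = FALSE),
                 next_track_id = 1L, params = params),
            class = "tracker_state")
}

#' Track one frame
#'
#' Core step of flow-shift tracking: build candidates from the most recent
#' occurrence of each track within the window (advected frame-to-frame by
#' optical flow), compute the matching cost against the new detections,
#' solve the minimum-cost one-to-one assignment, reject pairs above the cost
#' threshold, spawn new tracks for unmatched detections, and advance the
#' window.
#'
#' @param state a [tracker_state()].
#' @param new_instances untracked instances detected in `img`.
#' @param img the current grayscale frame.
#' @return updated state; `state$last_assigned` holds the instances with
#'   track ids for this frame.
#' @export
track_frame <- function(state, new_instances, img) {
  stopifnot(inherits(state, "tracker_state"))
  params <- state$params

  if (is.null(params$cost_threshold) && length(new_instances)) {
    diags <- vapply(new_instances, function(inst) {
      bb <- instance_bbox(inst)
      sqrt((bb$xmax - bb$xmin)^2 + (bb$ymax - bb$ymin)^2)
    }, numeric(1))
    params$cost_threshold <- max(stats::median(diags) / 2, 1e-6)
    state$params <- params
  }

  # Candidates: one carried instance per active track — its latest detection,
  # advected frame-to-frame up to the previous frame. Shift once more to the
  # current frame before costing.
  cand <- state$register
  if (length(cand)) {
    cand <- flow_shift(state$prev_img, img, cand, params)
  }
  cand_tracks <- vapply(cand, `[[`, integer(1), "track_id")

  assigned <- new_instances
  matched_new <- rep(FALSE, length(new_instances))
  matched_cand <- rep(FALSE, length(cand))
  if (length(cand) && length(new_instances)) {
    costm <- tracking_cost(cand, new_instances)
    pairs <- solve_assignment(costm)
    pairs <- pairs[is.finite(pairs$cost) &
                     pairs$cost <= params$cost_threshold, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      assigned[[pairs$col[k]]]$track_id <- cand_tracks[pairs$row[k]]
      matched_new[pairs$col[k]] <- TRUE
      matched_cand[pairs$row[k]] <- TRUE
    }
  }
  for (j in which(!matched_new)) {
    tid <- state$next_track_id
    assigned[[j]]$track_id <- tid
    state$tracks <- rbind(state$tracks,
                          data.frame(track_id = tid,
                                     name = sprintf("track_%d", tid),
                                     stringsAsFactors = FALSE))
    state$next_track_id <- tid + 1L
  }

  # New register: fresh detections at age 0; unmatched (dormant) tracks keep
  # their advected estimate and age until they fall out of the window.
  register <- lapply(assigned, function(inst) {
    attr(inst, "age") <- 0L
    inst
  })
  for (i in which(!matched_cand)) {
    inst <- cand[[i]]
    age <- (attr(inst, "age") %||% 0L) + 1L
    if (age < params$window_size) {
      attr(inst, "age") <- age
      register[[length(register) + 1L]] <- inst
    }
  }
  state$register <- register
  state$prev_img <- img
  state$n_seen <- state$n_seen + 1L
  state$last_assigned <- assigned
  state
}

#' Run the flow-shift tracker over a session
#'
#' Applies [track_frame()] to an ordered sequence of frames, producing a
#' fully tracked dataset. Deterministic given inputs and parameters.
#'
#' @param frames list of [labeled_frame()] with untracked instances, ordered
#'   by increasing `frame_index`.
#' @param images list of grayscale matrices aligned with `frames`.
#' @param skeleton the shared skeleton.
#' @param image_size (H, W) of the session frames.
#' @param params a [tracker_params()].
#' @return list with `dataset` (tracked [labels_dataset()]) and `summary`
#'   (n_tracks, per-frame assignment table).
#' @export
run_tracker <- function(frames, images, skeleton,
                        image_size = dim(images[[1]]),
                        params = tracker_params()) {
  if (!length(frames)) stop("empty session")
  stopifnot(length(frames) == length(images))
  fidx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (is.unsorted(fidx, strictly = TRUE)) {
    stop("frames must be ordered by strictly increasing frame_index")
  }
  state <- tracker_state(params)
  out_frames <- vector("list", length(frames))
  assign_rows <- list()
  for (t in seq_along(frames)) {
    state <- track_frame(state, frames[[t]]$instances, images[[t]])
    out_frames[[t]] <- labeled_frame(frames[[t]]$video_id,
                                     frames[[t]]$frame_index,
                                     state$last_assigned)
    if (length(state$last_assigned)) {
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        frame = frames[[t]]$frame_index,
        instance = seq_along(state$last_assigned),
        track_id = vapply(state$last_assigned, `[[`, integer(1), "track_id"))
    }
  }
  dataset <- labels_dataset(skeleton, out_frames, tracks = state$tracks,
                            image_size = image_size,
                            provenance = "run_tracker")
  list(dataset = dataset,
       summary = list(n_tracks = nrow(state$tracks),
                      assignments = if (length(assign_rows))
                        do.call(rbind, assign_rows)
                      else data.frame(frame = integer(), instance = integer(),
                                      track_id = integer())))
}
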