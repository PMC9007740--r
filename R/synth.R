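#' Specify a synthetic multi-animal scene
#'
#' The generator stands in for a camera plus a perfectly trained network: it
#' draws ground-truth poses (which the encode module can turn into "ideal"
#' network output tensors) and, optionally, renders textured blob images so
#' optical flow has something to latch onto. Defaults emulate the regimes
#' the pipeline targets: a few animals (2-8) with body extents tens of
#' pixels across, well separated relative to body size, in frames large
#' enough that borders rarely interfere.
#'
#' @param image_size integer (H, W), default 512 x 512.
#' @param skeleton a [skeleton()]; default the 5-node mouse-like skeleton.
#' @param n_instances number of animals (>= 1).
#' @param min_separation minimum centroid-to-centroid distance, px.
#' @param pose_scale approximate body extent, px (node offsets are drawn
#'   within `pose_scale / 2` of the root).
#' @param noise_sigma per-node Gaussian jitter applied to the rendered
#'   landmark positions (ground truth stays exact), px.
#' @param occlusion_rate probability that a non-root node is invisible.
#' @param classes give each instance a distinct class id.
#' @param seed RNG seed; scenes are deterministic given the spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       skeleton = example_skeletons()$mouse5,
                       n_instances = 2L, min_separation = 64,
                       pose_scale = 32, noise_sigma = 0,
                       occlusion_rate = 0, classes = FALSE, seed = 1L) {
  stopifnot(is_count(n_instances), n_instances >= 1, min_separation >= 0,
            pose_scale > 0, noise_sigma >= 0,
            occlusion_rate >= 0, occlusion_rate < 1,
            inherits(skeleton, "pose_skeleton"))
  structure(list(image_size = as.integer(image_size), skeleton = skeleton,
                 n_instances = as.integer(n_instances),
                 min_separation = min_separation, pose_scale = pose_scale,
                 noise_sigma = noise_sigma, occlusion_rate = occlusion_rate,
                 classes = isTRUE(classes), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Specify a synthetic session (scene + smooth trajectories)
#'
#' Instances move with constant velocity plus optional Gaussian jitter,
#' reflecting off frame borders; identities are consistent by construction,
#' providing ground truth for tracker tests.
#'
#' @param scene a [scene_spec()].
#' @param n_frames number of frames (>= 2).
#' @param max_step maximum centroid displacement per frame, px. Keep below
#'   `min_separation / 2` for switch-free tracking guarantees.
#' @param jitter_sigma per-frame Gaussian velocity jitter, px.
#' @return object of class `session_spec`.
#' @export
session_spec <- function(scene = scene_spec(), n_frames = 100L, max_step = 2,
                         jitter_sigma = 0) {
  stopifnot(inherits(scene, "scene_spec"), is_count(n_frames), n_frames >= 2,
            max_step >= 0, jitter_sigma >= 0)
  structure(list(scene = scene, n_frames = as.integer(n_frames),
                 max_step = max_step, jitter_sigma = jitter_sigma),
            class = "session_spec")
}

# rejection-sample n centroids at pairwise distance >= sep, margin from border
sample_centroids <- function(n, h, w, sep, margin, max_attempts = 10000L) {
  centroids <- matrix(NA_real_, n, 2L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d instances at separation %.1f in %d x %d (%d attempts)",
        n, sep, h, w, max_attempts))
    }
    cand <- c(stats::runif(1, margin, w - 1 - margin),
              stats::runif(1, margin, h - 1 - margin))
    if (placed > 0L) {
      d <- sqrt(rowSums((centroids[seq_len(placed), , drop = FALSE] -
                           matrix(cand, placed, 2, byrow = TRUE))^2))
      if (any(d < sep)) next
    }
    placed <- placed + 1L
    centroids[placed, ] <- cand
  }
  centroids
}

# draw one pose: root at centroid, each node at a deterministic depth-scaled
# offset in a random common orientation, so bodies look rigid-ish
sample_pose <- function(skel, centroid, pose_scale) {
  nn <- n_nodes(skel)
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, nn, 2L)
  indeg <- tabulate(skel$edges[, 2], nbins = nn)
  roots <- if (nrow(skel$edges)) which(indeg == 0L) else 1L
  root <- roots[1]
  pts[root, ] <- centroid
  for (r in setdiff(roots, root)) {
    ang <- theta + stats::runif(1, -pi, pi)
    pts[r, ] <- centroid + stats::runif(1, 0.1, 0.5) * pose_scale *
      c(cos(ang), sin(ang))
  }
  if (nrow(skel$edges)) {
    for (e in edge_topological_order(skel)) {
      s <- skel$edges[e, 1]; d <- skel$edges[e, 2]
      ang <- theta + stats::runif(1, -pi, pi)
      len <- stats::runif(1, 0.15, 0.5) * pose_scale
      pts[d, ] <- pts[s, ] + len * c(cos(ang), sin(ang))
    }
  }
  pts
}

#' Generate one synthetic scene
#'
#' Deterministic given the spec's seed. Ground-truth instances respect the
#' minimum centroid separation; when `render = TRUE` an image is produced
#' with one Gaussian blob per visible node (amplitudes vary per node so
#' patches are textured).
#'
#' @param spec a [scene_spec()].
#' @param render also rasterize an image.
#' @return list with `instances` (ground truth, with track/class ids),
#'   `centroids` and (optionally) `image`.
#' @export
generate_scene <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec, render))
}

generate_scene_impl <- function(spec, render) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  margin <- spec$pose_scale
  centroids <- sample_centroids(spec$n_instances, h, w,
                                spec$min_separation, margin)
  skel <- spec$skeleton
  instances <- lapply(seq_len(spec$n_instances), function(k) {
    pts <- sample_pose(skel, centroids[k, ], spec$pose_scale)
    if (spec$noise_sigma > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$noise_sigma),
                          ncol = 2)
    }
    pts[, 1] <- clamp(pts[, 1], 0, w - 1)
    pts[, 2] <- clamp(pts[, 2], 0, h - 1)
    vis <- rep(TRUE, n_nodes(skel))
    if (spec$occlusion_rate > 0 && n_nodes(skel) > 1L) {
      occ <- stats::runif(n_nodes(skel)) < spec$occlusion_rate
      occ[1] <- FALSE  # keep the root so instances stay anchored
      vis[occ] <- FALSE
      pts[occ, ] <- NA_real_
    }
    pose_instance(pts, skel, visible = vis, track_id = k,
                  class_id = if (spec$classes) k)
  })
  out <- list(instances = instances, centroids = centroids)
  if (render) out$image <- render_scene(instances, h, w)
  out
}

#' Rasterize instances as a blob image
#'
#' One Gaussian blob (sd 1.5 px) per visible node; amplitudes cycle over
#' \{1.0, 0.8, 0.6\} so neighborhoods carry gradient structure for optical
#' flow.
#'
#' @param instances list of [pose_instance()].
#' @param h,w image size.
#' @return numeric matrix in \[0, ~1\].
#' @export
render_scene <- function(instances, h, w) {
  img <- matrix(0, h, w)
  amps <- c(1.0, 0.8, 0.6)
  sd <- 1.5
  win <- 6L
  for (inst in instances) {
    for (i in which(inst$visible)) {
      cx <- inst$points[i, 1]; cy <- inst$points[i, 2]
      xs <- max(0, floor(cx) - win):min(w - 1, ceiling(cx) + win)
      ys <- max(0, floor(cy) - win):min(h - 1, ceiling(cy) + win)
      if (!length(xs) || !length(ys)) next
      blob <- outer(exp(-(ys - cy)^2 / (2 * sd^2)),
                    exp(-(xs - cx)^2 / (2 * sd^2))) *
        amps[(i - 1L) %% length(amps) + 1L]
      img[ys + 1, xs + 1] <- pmax(img[ys + 1, xs + 1], blob)
    }
  }
  img
}

#' Generate a synthetic session with ground-truth tracks
#'
#' Starts from [generate_scene()] and moves each instance rigidly with a
#' constant random velocity (magnitude at most `max_step`), Gaussian
#' velocity jitter, and reflection at frame borders; per-frame centroid
#' displacement never exceeds `max_step`. Identity labels are correct by
#' construction.
#'
#' @param spec a [session_spec()].
#' @param render also rasterize every frame.
#' @return list with `dataset` (tracked [labels_dataset()]) and `images`
#'   (list of matrices, or NULL).
#' @export
generate_session <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "session_spec"))
  with_seed(spec$scene$seed, generate_session_impl(spec, render))
}

generate_session_impl <- function(spec, render) {
  sc <- spec$scene
  h <- sc$image_size[1]; w <- sc$image_size[2]
  scene <- generate_scene_impl(sc, render = FALSE)
  skel <- sc$skeleton
  n <- sc$n_instances
  speed <- stats::runif(n, 0.5, 1) * spec$max_step
  ang <- stats::runif(n, 0, 2 * pi)
  vel <- cbind(speed * cos(ang), speed * sin(ang))
  margin <- sc$pose_scale / 2

  offsets <- lapply(scene$instances, function(inst) {
    sweep(inst$points, 2, colMeans(inst$points[inst$visible, , drop = FALSE]))
  })
  centroids <- t(vapply(scene$instances, function(inst)
    colMeans(inst$points[inst$visible, , drop = FALSE]), numeric(2)))

  frames <- vector("list", spec$n_frames)
  images <- if (render) vector("list", spec$n_frames) else NULL
  for (t in seq_len(spec$n_frames)) {
    insts <- lapply(seq_len(n), function(k) {
      pts <- sweep(offsets[[k]], 2, centroids[k, ], `+`)
      pose_instance(pts, skel,
                    visible = scene$instances[[k]]$visible,
                    track_id = k,
                    class_id = scene$instances[[k]]$class_id)
    })
    frames[[t]] <- labeled_frame("synthetic", t - 1L, insts)
    if (render) images[[t]] <- render_scene(insts, h, w)
    if (t < spec$n_frames) {
      step <- vel
      if (spec$jitter_sigma > 0) {
        step <- step + matrix(stats::rnorm(2 * n, 0, spec$jitter_sigma),
                              ncol = 2)
        # cap so the switch-free displacement guarantee holds by construction
        mag <- sqrt(rowSums(step^2))
        too_fast <- mag > spec$max_step & mag > 0
        step[too_fast, ] <- step[too_fast, , drop = FALSE] *
          (spec$max_step / mag[too_fast])
      }
      for (k in seq_len(n)) {
        nxt <- centroids[k, ] + step[k, ]
        # reflect at borders (with margin so bodies stay in frame)
        for (d in 1:2) {
          lim <- if (d == 1) w - 1 - margin else h - 1 - margin
          if (nxt[d] < margin) {
            nxt[d] <- 2 * margin - nxt[d]
            vel[k, d] <- -vel[k, d]
          } else if (nxt[d] > lim) {
            nxt[d] <- 2 * lim - nxt[d]
            vel[k, d] <- -vel[k, d]
          }
        }
        centroids[k, ] <- nxt
      }
    }
  }
  tracks <- data.frame(track_id = seq_len(n),
                       name = sprintf("animal_%d", seq_len(n)),
                       stringsAsFactors = FALSE)
  dataset <- labels_dataset(skel, frames, tracks = tracks,
                            class_names = if (sc$classes)
                              sprintf("class_%d", seq_len(n)),
                            image_size = c(h, w),
                            provenance = "generate_session")
  list(dataset = dataset, images = images)
}
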