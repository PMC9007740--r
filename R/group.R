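#' Score a candidate connection along a part affinity field
#'
#' Line-integral score of a putative source-to-destination connection: the
#' mean, over `n_samples` evenly spaced points from source to destination
#' (inclusive of both endpoints), of the dot product between the PAF sampled
#' at the point and the unit vector from source to destination. Sampling
#' uses the nearest grid pixel (bilinear optional). Perfectly aligned
#' fields of unit magnitude score 1; orthogonal fields score 0. A
#' zero-length candidate scores 0.
#'
#' @param pafs an [encode_pafs()] result (or network-predicted fields).
#' @param edge skeleton edge index the candidate belongs to.
#' @param src_xy,dst_xy numeric (x, y) of the candidate endpoints, image px.
#' @param n_samples number of sample points (default 10).
#' @param bilinear sample the field bilinearly instead of nearest-pixel.
#' @return scalar score, in \[-1, 1\] for unit-magnitude fields.
#' @export
score_connection <- function(pafs, edge, src_xy, dst_xy, n_samples = 10L,
                             bilinear = FALSE) {
  stopifnot(inherits(pafs, "part_affinity_fields"), is_count(edge),
            edge >= 1, edge <= nrow(pafs$edges))
  v <- dst_xy - src_xy
  len <- sqrt(sum(v^2))
  if (len == 0) return(0)
  u <- v / len
  t <- seq(0, 1, length.out = n_samples)
  sx <- src_xy[1] + t * v[1]
  sy <- src_xy[2] + t * v[2]
  stride <- pafs$grid$stride
  fx_map <- pafs$tensor[, , 2L * edge - 1L]
  fy_map <- pafs$tensor[, , 2L * edge]
  if (bilinear) {
    fx <- bilinear_sample(fx_map, sx / stride, sy / stride)
    fy <- bilinear_sample(fy_map, sx / stride, sy / stride)
  } else {
    gc <- clamp(round(sx / stride), 0, ncol(fx_map) - 1) + 1
    gr <- clamp(round(sy / stride), 0, nrow(fx_map) - 1) + 1
    idx <- cbind(gr, gc)
    fx <- fx_map[idx]
    fy <- fy_map[idx]
  }
  mean(fx * u[1] + fy * u[2])
}

#' Match source to destination candidates for one skeleton edge
#'
#' One-to-one assignment of source peaks to destination peaks maximizing the
#' total connection score (Hungarian matching), followed by dropping pairs
#' whose score falls below `min_score`.
#'
#' @param candidates data.frame with columns `src` and `dst` (peak row ids),
#'   and `score`; all candidates must belong to a single edge.
#' @param min_score minimum connection score to accept (default 0.05).
#' @return subset of `candidates` rows that were accepted, ordered by
#'   decreasing score.
#' @export
match_edge <- function(candidates, min_score = 0.05) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(data.frame(src = integer(), dst = integer(), score = numeric()))
  }
  srcs <- sort(unique(candidates$src))
  dsts <- sort(unique(candidates$dst))
  m <- matrix(-Inf, length(srcs), length(dsts))
  m[cbind(match(candidates$src, srcs), match(candidates$dst, dsts))] <-
    candidates$score
  pairs <- solve_assignment(m, maximize = TRUE)
  pairs <- pairs[is.finite(pairs$cost) & pairs$cost >= min_score, , drop = FALSE]
  out <- data.frame(src = srcs[pairs$row], dst = dsts[pairs$col],
                    score = pairs$cost)
  out[order(-out$score), , drop = FALSE]
}

#' Assemble peaks and matched connections into instances
#'
#' Greedy bottom-up assembly: edges are processed in skeleton topological
#' order (roots first); each accepted connection extends the partial
#' instance containing its source peak, merges two disjoint partial
#' instances, or seeds a new one. When a merge would assign the same node
#' twice, the connection with the higher score wins and the other is
#' discarded. Peaks left unconnected become single-node instances only when
#' `allow_singletons` is set. Output can be capped at `max_instances` by
#' descending summed connection score.
#'
#' @param peaks a [peak-table] (refined or not); row order defines peak ids.
#' @param connections data.frame with columns `edge`, `src`, `dst`, `score`
#'   (peak row ids into `peaks`), e.g. from [match_edge()] per edge.
#' @param skeleton validated [skeleton()] (tree/forest).
#' @param max_instances optional cap on the number of returned instances.
#' @param allow_singletons keep unconnected peaks as one-node instances.
#' @return list of [pose_instance()], each with `point_scores` from peak
#'   values, `instance_score` = summed connection scores, and an attribute
#'   `peak_ids` giving the source peak row per node.
#' @export
assemble_instances <- function(peaks, connections, skeleton,
                               max_instances = NULL, allow_singletons = FALSE) {
  viol <- validate_skeleton(skeleton)
  if (length(viol)) stop("invalid skeleton: ", viol[1])
  nn <- n_nodes(skeleton)

  # assignment state: instance id per peak; node slots per instance
  inst_of_peak <- rep(NA_integer_, nrow(peaks))
  slots <- list()   # per instance: integer vector of peak id per node (NA empty)
  scores <- numeric()

  new_instance <- function() {
    slots[[length(slots) + 1L]] <<- rep(NA_integer_, nn)
    scores[length(slots)] <<- 0
    length(slots)
  }

  if (nrow(connections) > 0L) {
    eorder <- edge_topological_order(skeleton)
    rank <- match(connections$edge, eorder)
    conns <- connections[order(rank, -connections$score), , drop = FALSE]
    for (k in seq_len(nrow(conns))) {
      e <- conns$edge[k]
      s_node <- skeleton$edges[e, 1]; d_node <- skeleton$edges[e, 2]
      ps <- conns$src[k]; pd <- conns$dst[k]
      is_ <- inst_of_peak[ps]; id_ <- inst_of_peak[pd]
      if (is.na(is_) && is.na(id_)) {
        ii <- new_instance()
        slots[[ii]][s_node] <- ps
        slots[[ii]][d_node] <- pd
        inst_of_peak[c(ps, pd)] <- ii
        scores[ii] <- scores[ii] + conns$score[k]
      } else if (!is.na(is_) && is.na(id_)) {
        if (is.na(slots[[is_]][d_node])) {
          slots[[is_]][d_node] <- pd
          inst_of_peak[pd] <- is_
          scores[is_] <- scores[is_] + conns$score[k]
        }  # else: node already filled, lower-ranked connection discarded
      } else if (is.na(is_) && !is.na(id_)) {
        if (is.na(slots[[id_]][s_node])) {
          slots[[id_]][s_node] <- ps
          inst_of_peak[ps] <- id_
          scores[id_] <- scores[id_] + conns$score[k]
        }
      } else if (is_ != id_) {
        # merge when node slots are disjoint; otherwise discard (the
        # connections already in place were ranked higher)
        if (!any(!is.na(slots[[is_]]) & !is.na(slots[[id_]]))) {
          merged <- ifelse(is.na(slots[[is_]]), slots[[id_]], slots[[is_]])
          slots[[is_]] <- merged
          inst_of_peak[stats::na.omit(merged)] <- is_
          scores[is_] <- scores[is_] + scores[id_] + conns$score[k]
          slots[[id_]] <- rep(NA_integer_, nn)
          scores[id_] <- 0
        }
      } else {
        scores[is_] <- scores[is_] + conns$score[k]
      }
    }
  }

  if (allow_singletons) {
    for (p in which(is.na(inst_of_peak))) {
      ii <- new_instance()
      slots[[ii]][peaks$channel[p]] <- p
      inst_of_peak[p] <- ii
    }
  }

  keep <- which(vapply(slots, function(s) any(!is.na(s)), logical(1)))
  keep <- keep[order(-scores[keep])]
  if (!is.null(max_instances) && length(keep) > max_instances) {
    keep <- keep[seq_len(max_instances)]
  }

  lapply(keep, function(ii) {
    s <- slots[[ii]]
    pts <- matrix(NA_real_, nn, 2L)
    pscore <- rep(NA_real_, nn)
    filled <- which(!is.na(s))
    pts[filled, 1] <- peaks$x[s[filled]]
    pts[filled, 2] <- peaks$y[s[filled]]
    pscore[filled] <- peaks$value[s[filled]]
    inst <- pose_instance(pts, skeleton, visible = !is.na(s),
                          point_scores = pscore, instance_score = scores[ii])
    attr(inst, "peak_ids") <- s
    inst
  })
}

#' Full bottom-up decoding of one frame
#'
#' Convenience pipeline: local peak finding + refinement on the confidence
#' maps, line-integral scoring of every source x destination peak pair per
#' edge, per-edge Hungarian matching, and greedy assembly.
#'
#' @param cms multi-instance confidence maps.
#' @param pafs matching part affinity fields.
#' @param skeleton the skeleton whose edges index the PAF channels.
#' @param peak_threshold confidence threshold for peak finding.
#' @param min_connection_score minimum accepted line-integral score.
#' @param n_line_samples sample count for [score_connection()].
#' @param refine apply [refine_peaks()] before grouping.
#' @inheritParams assemble_instances
#' @return list of [pose_instance()].
#' @export
bottomup_decode <- function(cms, pafs, skeleton, peak_threshold = 0.2,
                            min_connection_score = 0.05, n_line_samples = 10L,
                            refine = TRUE, max_instances = NULL,
                            allow_singletons = FALSE) {
  peaks <- find_local_peaks(cms, threshold = peak_threshold)
  if (refine) peaks <- refine_peaks(cms, peaks)
  conns_list <- list()
  for (e in seq_len(nrow(skeleton$edges))) {
    s_node <- skeleton$edges[e, 1]; d_node <- skeleton$edges[e, 2]
    src_ids <- which(peaks$channel == s_node)
    dst_ids <- which(peaks$channel == d_node)
    if (!length(src_ids) || !length(dst_ids)) next
    cand <- expand.grid(src = src_ids, dst = dst_ids)
    cand$score <- vapply(seq_len(nrow(cand)), function(k) {
      score_connection(pafs, e,
                       c(peaks$x[cand$src[k]], peaks$y[cand$src[k]]),
                       c(peaks$x[cand$dst[k]], peaks$y[cand$dst[k]]),
                       n_samples = n_line_samples)
    }, numeric(1))
    acc <- match_edge(cand, min_score = min_connection_score)
    if (nrow(acc)) {
      acc$edge <- e
      conns_list[[length(conns_list) + 1L]] <- acc
    }
  }
  conns <- if (length(conns_list)) do.call(rbind, conns_list) else {
    data.frame(edge = integer(), src = integer(), dst = integer(),
               score = numeric())
  }
  assemble_instances(peaks, conns, skeleton, max_instances = max_instances,
                     allow_singletons = allow_singletons)
}

#' Decode top-down crops into full-frame instances
#'
#' For each anchored crop, the centered animal's parts are recovered by
#' global peak finding plus integral refinement on the crop's confidence
#' maps, then translated back to full-frame coordinates using the crop's
#' recorded offset. Crops whose channels all fall below the threshold yield
#' no instance and are dropped with a message.
#'
#' @param crop_cms list of `confidence_maps`, one per crop (grids span the
#'   crop, not the full frame).
#' @param crop_set the [make_anchor_crops()] result the maps correspond to
#'   (provides per-crop offsets).
#' @param skeleton the skeleton (for channel names/count).
#' @param threshold peak confidence threshold.
#' @param refine apply subpixel refinement.
#' @return list of [pose_instance()] in full-frame coordinates.
#' @export
topdown_decode <- function(crop_cms, crop_set, skeleton, threshold = 0.2,
                           refine = TRUE) {
  stopifnot(inherits(crop_set, "crop_set"),
            length(crop_cms) == length(crop_set$crops))
  out <- list()
  for (k in seq_along(crop_cms)) {
    pk <- find_global_peaks(crop_cms[[k]], threshold = threshold)
    if (refine && nrow(pk)) pk <- refine_peaks(crop_cms[[k]], pk)
    if (nrow(pk) == 0L) {
      message(sprintf("crop %d: no channel above threshold %.2f, dropped",
                      k, threshold))
      next
    }
    nn <- n_nodes(skeleton)
    pts <- matrix(NA_real_, nn, 2L)
    pscore <- rep(NA_real_, nn)
    pts[pk$channel, 1] <- pk$x + crop_set$offsets[k, 1]
    pts[pk$channel, 2] <- pk$y + crop_set$offsets[k, 2]
    pscore[pk$channel] <- pk$value
    out[[length(out) + 1L]] <- pose_instance(
      pts, skeleton, visible = !is.na(pts[, 1]),
      point_scores = pscore, instance_score = mean(pk$value))
  }
  out
}

#' Assign identity classes from class maps
#'
#' Scores each instance against each class channel as the mean class-map
#' value sampled (nearest grid pixel) at the instance's visible points, then
#' solves the one-to-one assignment maximizing the total score. When there
#' are more instances than classes, the surplus lowest-scoring instances are
#' left unassigned with a message.
#'
#' @param instances list of [pose_instance()] (n_instances <= n_classes for
#'   a full assignment).
#' @param class_maps an [encode_class_maps()] result (or predicted maps).
#' @return the instances with `class_id` set (NA class ids removed, i.e.
#'   left NULL) plus attribute `class_scores` (the score matrix).
#' @export
assign_ids_class_maps <- function(instances, class_maps) {
  stopifnot(inherits(class_maps, "class_maps"))
  n_classes <- dim(class_maps$tensor)[3]
  n_inst <- length(instances)
  if (n_inst == 0L) return(instances)
  stride <- class_maps$grid$stride
  scorem <- matrix(0, n_inst, n_classes)
  for (i in seq_len(n_inst)) {
    vis <- which(instances[[i]]$visible)
    gr <- clamp(round(instances[[i]]$points[vis, 2] / stride),
                0, dim(class_maps$tensor)[1] - 1) + 1
    gc <- clamp(round(instances[[i]]$points[vis, 1] / stride),
                0, dim(class_maps$tensor)[2] - 1) + 1
    for (ch in seq_len(n_classes)) {
      scorem[i, ch] <- mean(class_maps$tensor[, , ch][cbind(gr, gc)])
    }
  }
  assigned <- assign_ids_probabilities(scorem)
  for (k in seq_len(nrow(assigned))) {
    i <- assigned$instance[k]
    if (assigned$score[k] > 0) {
      instances[[i]]$class_id <- assigned$class[k]
    }
  }
  unas <- setdiff(seq_len(n_inst),
                  assigned$instance[assigned$score > 0])
  if (length(unas)) {
    message("instance(s) left unassigned (no class support): ",
            paste(unas, collapse = ", "))
  }
  attr(instances, "class_scores") <- scorem
  instances
}

#' Optimal identity assignment from a probability matrix
#'
#' Aggregates per-instance class probabilities for a frame and solves the
#' one-to-one assignment maximizing total probability, which enforces
#' mutually exclusive class assignments. Surplus instances (more instances
#' than classes) are left out.
#'
#' @param prob_matrix n_instances x n_classes matrix with nonnegative rows.
#' @return data.frame with columns `instance`, `class`, `score`.
#' @export
assign_ids_probabilities <- function(prob_matrix) {
  if (is.null(dim(prob_matrix)) || any(dim(prob_matrix) == 0L)) {
    return(data.frame(instance = integer(), class = integer(),
                      score = numeric()))
  }
  if (any(prob_matrix < 0)) stop("probabilities must be nonnegative")
  pairs <- solve_assignment(prob_matrix, maximize = TRUE)
  data.frame(instance = pairs$row, class = pairs$col, score = pairs$cost)
}
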