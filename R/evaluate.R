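#' OKS parameters
#'
#' @param sigma per-node uncertainty factor; the default 0.025 corresponds
#'   to the least ambiguous human keypoint (eyes), making the score a lower
#'   bound on true accuracy. May be a scalar or one value per node.
#' @param min_area floor on the ground-truth bounding-box area (px^2) so
#'   degenerate single-point instances still score (default 1).
#' @return object of class `oks_params`.
#' @export
oks_params <- function(sigma = 0.025, min_area = 1) {
  stopifnot(is.numeric(sigma), all(sigma > 0), is.numeric(min_area),
            min_area > 0)
  structure(list(sigma = sigma, min_area = min_area), class = "oks_params")
}

#' Object keypoint similarity between two instances
#'
#' `OKS = sum_i exp(-||X_i - Xhat_i||^2 / (2 alpha sigma_i^2)) delta_i /
#' sum_i delta_i`, where `delta_i` is the ground-truth visibility, `alpha`
#' the area of the ground truth's visible bounding box, and `sigma_i` the
#' per-node uncertainty. A node visible in the ground truth but missing from
#' the prediction contributes 0 to the numerator, so with k of n visible
#' nodes recovered exactly, the score is k/n.
#'
#' @param gt,pred [pose_instance()] objects on a shared skeleton.
#' @param params an [oks_params()].
#' @return scalar in \[0, 1\].
#' @export
compute_oks <- function(gt, pred, params = oks_params()) {
  stopifnot(inherits(gt, "pose_instance"), inherits(pred, "pose_instance"))
  delta <- gt$visible
  if (!any(delta)) stop("ground-truth instance has no visible nodes")
  nn <- length(delta)
  sigma <- rep(params$sigma, length.out = nn)
  bb <- instance_bbox(gt)
  alpha <- max((bb$xmax - bb$xmin) * (bb$ymax - bb$ymin), params$min_area)
  num <- 0
  for (i in which(delta)) {
    if (!pred$visible[i]) next  # missing prediction contributes 0
    d2 <- sum((gt$points[i, ] - pred$points[i, ])^2)
    num <- num + exp(-d2 / (2 * alpha * sigma[i]^2))
  }
  num / sum(delta)
}

#' Greedy OKS matching of instances within one frame
#'
#' Pairs ground-truth and predicted instances by repeatedly taking the
#' highest remaining OKS value (each instance used at most once). Leftover
#' ground truths become false negatives; leftover predictions false
#' positives.
#'
#' @param gt_list,pred_list lists of [pose_instance()] from the same frame.
#' @param params an [oks_params()].
#' @return list with `pairs` (data.frame gt, pred, oks), `unmatched_gt`,
#'   `unmatched_pred` (integer indices) and the full `oks` matrix.
#' @export
match_frame_instances <- function(gt_list, pred_list, params = oks_params()) {
  ng <- length(gt_list); np <- length(pred_list)
  oks <- matrix(0, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      oks[i, j] <- compute_oks(gt_list[[i]], pred_list[[j]], params)
    }
  }
  pairs <- data.frame(gt = integer(), pred = integer(), oks = numeric())
  used_g <- logical(ng); used_p <- logical(np)
  work <- oks
  while (any(!used_g) && any(!used_p)) {
    sub <- work
    sub[used_g, ] <- -Inf
    sub[, used_p] <- -Inf
    best <- max(sub)
    if (!is.finite(best)) break
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2])[1], , drop = TRUE]
    pairs <- rbind(pairs, data.frame(gt = unname(hit[1]),
                                     pred = unname(hit[2]), oks = best))
    used_g[hit[1]] <- TRUE
    used_p[hit[2]] <- TRUE
  }
  list(pairs = pairs,
       unmatched_gt = which(!used_g),
       unmatched_pred = which(!used_p),
       oks = oks)
}

#' PoseTrack-style mAP/mAR over OKS thresholds
#'
#' For each OKS threshold in \{0.50, 0.55, ..., 0.95\}: predictions (matched
#' pairs plus unmatched predictions at OKS 0) are sorted by OKS; cumulative
#' true/false positives give precision `TP/(TP+FP)` and recall `TP/(TP+FN)`
#' with the total ground-truth count fixed; average precision is the mean of
#' interpolated precision at 101 evenly spaced recall points (the best
#' precision among samples at recall at or beyond each point, 0 when
#' unreachable); average recall is the best recall at that threshold.
#' mAP/mAR average over the ten thresholds. Matched pairs below a threshold
#' count as both FP and FN at that threshold.
#'
#' @param matches list of [match_frame_instances()] results (one per frame),
#'   or a single such result.
#' @param thresholds OKS cutoffs (default the PoseTrack ten).
#' @return object of class `eval_result`: list with `mAP`, `mAR`,
#'   `per_threshold` (data.frame threshold/AP/AR/TP/FP/FN) and the pooled
#'   prediction table.
#' @export
compute_map <- function(matches, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (!is.null(matches$pairs)) matches <- list(matches)
  pred_oks <- numeric()
  n_gt <- 0L
  for (m in matches) {
    pred_oks <- c(pred_oks, m$pairs$oks, rep(0, length(m$unmatched_pred)))
    n_gt <- n_gt + nrow(m$pairs) + length(m$unmatched_gt)
  }
  if (!length(pred_oks)) {
    warning("no predictions; mAP = 0")
    per <- data.frame(threshold = thresholds, AP = 0, AR = 0,
                      TP = 0L, FP = 0L, FN = n_gt)
    return(structure(list(mAP = 0, mAR = 0, per_threshold = per,
                          predictions = data.frame(oks = numeric())),
                     class = "eval_result"))
  }
  pred_oks <- sort(pred_oks, decreasing = TRUE)
  recall_points <- seq(0, 1, length.out = 101L)
  per <- lapply(thresholds, function(th) {
    tp <- cumsum(pred_oks >= th)
    fp <- cumsum(pred_oks < th)
    precision <- tp / (tp + fp)
    recall <- if (n_gt > 0L) tp / n_gt else rep(0, length(tp))
    ap <- mean(vapply(recall_points, function(r) {
      ok <- recall >= r
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
    data.frame(threshold = th, AP = ap, AR = max(recall),
               TP = tp[length(tp)], FP = fp[length(fp)],
               FN = n_gt - tp[length(tp)])
  })
  per <- do.call(rbind, per)
  structure(list(mAP = mean(per$AP), mAR = mean(per$AR), per_threshold = per,
                 predictions = data.frame(oks = pred_oks)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: mAP = %.4f, mAR = %.4f over %d thresholds>\n",
              x$mAP, x$mAR, nrow(x$per_threshold)))
  invisible(x)
}

#' Per-node localization-error distribution
#'
#' Euclidean error for every jointly visible node of every matched pair,
#' with 50/90/95th percentile summaries per node and overall.
#'
#' @param matches as in [compute_map()], each paired with its instances:
#'   supply a list of lists with elements `gt_list`, `pred_list` and `match`
#'   (a [match_frame_instances()] result), or use
#'   [evaluate_frames()] which wires this up.
#' @return list with `errors` (data.frame node, error) and `percentiles`
#'   (data.frame node, p50, p90, p95; last row "all").
#' @export
localization_errors <- function(matches) {
  if (!is.null(matches$match)) matches <- list(matches)
  rows <- list()
  for (m in matches) {
    for (k in seq_len(nrow(m$match$pairs))) {
      g <- m$gt_list[[m$match$pairs$gt[k]]]
      p <- m$pred_list[[m$match$pairs$pred[k]]]
      shared <- which(g$visible & p$visible)
      if (!length(shared)) next
      d <- g$points[shared, , drop = FALSE] - p$points[shared, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        node = g$skeleton$nodes[shared], error = sqrt(rowSums(d^2)))
    }
  }
  errors <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(node = character(), error = numeric())
  }
  pct <- function(e) stats::quantile(e, c(0.5, 0.9, 0.95), names = FALSE,
                                     type = 7)
  percs <- lapply(split(errors$error, errors$node), pct)
  percentiles <- data.frame(
    node = c(names(percs), "all"),
    do.call(rbind, c(percs, list(if (nrow(errors)) pct(errors$error)
                                 else c(NA, NA, NA)))))
  names(percentiles)[2:4] <- c("p50", "p90", "p95")
  rownames(percentiles) <- NULL
  list(errors = errors, percentiles = percentiles)
}

#' Convenience frame-set evaluation
#'
#' Greedily matches each frame of predictions to ground truth and bundles
#' the structures [compute_map()] and [localization_errors()] consume.
#'
#' @param gt,pred [labels_dataset()] objects covering the same frames.
#' @param params an [oks_params()].
#' @return list of per-frame lists (gt_list, pred_list, match).
#' @export
evaluate_frames <- function(gt, pred, params = oks_params()) {
  stopifnot(length(gt$frames) == length(pred$frames))
  lapply(seq_along(gt$frames), function(fi) {
    gl <- gt$frames[[fi]]$instances
    pl <- pred$frames[[fi]]$instances
    list(gt_list = gl, pred_list = pl,
         match = match_frame_instances(gl, pl, params))
  })
}

#' Count identity switches between tracked sessions
#'
#' Instances are matched per frame by greedy OKS; a switch is counted
#' whenever a ground-truth identity's assigned predicted track differs from
#' its most recent previous assignment (the standard multi-object-tracking
#' definition). The rate is normalized per 100,000 frames.
#'
#' @param gt_tracked,pred_tracked tracked [labels_dataset()] objects
#'   covering the same frames in the same order.
#' @param params an [oks_params()].
#' @return list with `switches` (count), `rate_per_100k`, `n_frames` and
#'   the per-frame assignment table.
#' @export
count_id_switches <- function(gt_tracked, pred_tracked,
                              params = oks_params()) {
  stopifnot(length(gt_tracked$frames) == length(pred_tracked$frames))
  n_frames <- length(gt_tracked$frames)
  last_seen <- list()  # gt track id (chr) -> last assigned pred track id
  switches <- 0L
  rows <- list()
  for (fi in seq_len(n_frames)) {
    gl <- gt_tracked$frames[[fi]]$instances
    pl <- pred_tracked$frames[[fi]]$instances
    m <- match_frame_instances(gl, pl, params)
    for (k in seq_len(nrow(m$pairs))) {
      gtid <- gl[[m$pairs$gt[k]]]$track_id
      ptid <- pl[[m$pairs$pred[k]]]$track_id
      if (is.null(gtid) || is.null(ptid)) next
      key <- as.character(gtid)
      prev <- last_seen[[key]]
      if (!is.null(prev) && prev != ptid) switches <- switches + 1L
      last_seen[[key]] <- ptid
      rows[[length(rows) + 1L]] <- data.frame(
        frame = gt_tracked$frames[[fi]]$frame_index,
        gt_track = gtid, pred_track = ptid)
    }
  }
  list(switches = switches,
       rate_per_100k = switches / n_frames * 1e5,
       n_frames = n_frames,
       assignments = if (length(rows)) do.call(rbind, rows) else
         data.frame(frame = integer(), gt_track = integer(),
                    pred_track = integer()))
}
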