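#' Trigger configuration for closed-loop approach detection
#'
#' Criteria for the male "approach" pose: head-to-abdomen-tip distance under
#' `dist_max` mm, female thorax within `ang_f_max` degrees of the male's
#' heading, and male thorax more than `ang_m_min` degrees away from the
#' female's heading (i.e. the male is behind her). Evaluated every
#' `eval_period_ms` in the acquisition loop.
#'
#' @param dist_max mm (default 2).
#' @param ang_f_max degrees (default 25).
#' @param ang_m_min degrees (default 145).
#' @param eval_period_ms evaluation period (default 25; bookkeeping only).
#' @param px_per_mm image scale.
#' @return object of class `trigger_config`.
#' @export
trigger_config <- function(dist_max = 2, ang_f_max = 25, ang_m_min = 145,
                           eval_period_ms = 25, px_per_mm = 30.3) {
  vals <- c(dist_max, ang_f_max, ang_m_min, eval_period_ms, px_per_mm)
  stopifnot(is.numeric(vals), all(vals > 0))
  structure(list(dist_max = dist_max, ang_f_max = ang_f_max,
                 ang_m_min = ang_m_min, eval_period_ms = eval_period_ms,
                 px_per_mm = px_per_mm),
            class = "trigger_config")
}

# signed angle (degrees, CCW positive in y-down image coordinates, wrapped
# to (-180, 180]) from vector a to vector b
signed_angle_deg <- function(a, b) {
  ang <- atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Social pose-pair features for a male-female dyad
#'
#' Computes the features the approach trigger evaluates:
#' \describe{
#'   \item{min_dist}{male head to female abdomen tip, mm}
#'   \item{ang_f_rel_m}{angular location of the female thorax relative to
#'     the male's heading (thorax-to-head vector), degrees in (-180, 180]}
#'   \item{ang_m_rel_f}{angular location of the male thorax relative to the
#'     female's heading}
#' }
#' A feature whose required nodes are invisible, or whose defining vectors
#' are degenerate (coincident thoraxes, zero-length heading), is `NA`.
#'
#' @param female,male [pose_instance()] objects.
#' @param px_per_mm image scale (pixels per millimetre).
#' @param nodes named list mapping roles `head`, `thorax`, `abdomen` to node
#'   names or indices of the instances' skeleton.
#' @return list with `min_dist`, `ang_f_rel_m`, `ang_m_rel_f`.
#' @export
pose_pair_features <- function(female, male, px_per_mm,
                               nodes = list(head = "head", thorax = "thorax",
                                            abdomen = "abdomen")) {
  stopifnot(px_per_mm > 0)
  idx <- function(inst, role) {
    nd <- nodes[[role]]
    if (is.character(nd)) nd <- match(nd, inst$skeleton$nodes)
    if (is.na(nd)) stop("unknown node for role ", role)
    nd
  }
  pt <- function(inst, role) {
    i <- idx(inst, role)
    if (!inst$visible[i]) return(NULL)
    inst$points[i, ]
  }

  m_head <- pt(male, "head"); m_thor <- pt(male, "thorax")
  f_thor <- pt(female, "thorax"); f_abd <- pt(female, "abdomen")
  f_head <- pt(female, "head")

  min_dist <- if (!is.null(m_head) && !is.null(f_abd)) {
    sqrt(sum((m_head - f_abd)^2)) / px_per_mm
  } else NA_real_

  rel_angle <- function(thor_a, head_a, thor_b) {
    if (is.null(thor_a) || is.null(head_a) || is.null(thor_b)) {
      return(NA_real_)
    }
    heading <- head_a - thor_a
    to_b <- thor_b - thor_a
    if (sum(heading^2) == 0 || sum(to_b^2) == 0) return(NA_real_)
    signed_angle_deg(heading, to_b)
  }
  list(min_dist = min_dist,
       ang_f_rel_m = rel_angle(m_thor, m_head, f_thor),
       ang_m_rel_f = rel_angle(f_thor, f_head, m_thor))
}

#' Approach-trigger predicate
#'
#' True exactly when `min_dist < dist_max` and `|ang_f_rel_m| < ang_f_max`
#' and `|ang_m_rel_f| > ang_m_min`, all strict. Any unavailable feature
#' makes the trigger false.
#'
#' @param features a [pose_pair_features()] result.
#' @param cfg a [trigger_config()].
#' @return logical scalar.
#' @export
approach_trigger <- function(features, cfg = trigger_config()) {
  f <- features
  if (anyNA(c(f$min_dist, f$ang_f_rel_m, f$ang_m_rel_f))) return(FALSE)
  (f$min_dist < cfg$dist_max) &&
    (abs(f$ang_f_rel_m) < cfg$ang_f_max) &&
    (abs(f$ang_m_rel_f) > cfg$ang_m_min)
}

#' Per-frame trigger trace for a tracked session
#'
#' Evaluates the approach trigger on every frame of a tracked dataset with
#' exactly two identified animals.
#'
#' @param dataset tracked [labels_dataset()].
#' @param female_track,male_track track ids of the two animals.
#' @param cfg a [trigger_config()].
#' @param nodes role mapping passed to [pose_pair_features()].
#' @return data.frame with columns `frame` and `trigger`.
#' @export
trigger_trace <- function(dataset, female_track, male_track,
                          cfg = trigger_config(),
                          nodes = list(head = "head", thorax = "thorax",
                                       abdomen = "abdomen")) {
  rows <- lapply(dataset$frames, function(fr) {
    tid <- vapply(fr$instances, function(i) i$track_id %||% NA_integer_,
                  integer(1))
    fi <- match(female_track, tid)
    mi <- match(male_track, tid)
    trig <- FALSE
    if (!is.na(fi) && !is.na(mi)) {
      feats <- pose_pair_features(fr$instances[[fi]], fr$instances[[mi]],
                                  cfg$px_per_mm, nodes)
      trig <- approach_trigger(feats, cfg)
    }
    data.frame(frame = fr$frame_index, trigger = trig)
  })
  do.call(rbind, rows)
}
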