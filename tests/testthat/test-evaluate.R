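mouse5 <- example_skeletons()$mouse5

test_that("OKS reproduces identity, missing-node and closed-form cases", {
  set.seed(1)
  pts <- cbind(runif(5, 10, 90), runif(5, 10, 90))
  gt <- pose_instance(pts, mouse5)
  expect_equal(compute_oks(gt, gt), 1.0)

  # 4 of 5 recovered exactly, fifth missing -> 4/5
  pp <- pts; pp[5, ] <- NA
  expect_equal(compute_oks(gt, pose_instance(pp, mouse5)), 0.8)

  # one node displaced by d: (4 + exp(-d^2/(2 a s^2))) / 5, direct evaluation
  d <- 3
  pd <- pts; pd[2, 1] <- pd[2, 1] + d
  bb <- instance_bbox(gt)
  alpha <- (bb$xmax - bb$xmin) * (bb$ymax - bb$ymin)
  expected <- (4 + exp(-d^2 / (2 * alpha * 0.025^2))) / 5
  expect_equal(compute_oks(gt, pose_instance(pd, mouse5)), expected)
})

test_that("OKS with 10 of 11 nodes rounds to 0.91", {
  sk <- example_skeletons()$mouse11
  set.seed(2)
  pts <- cbind(runif(11, 10, 90), runif(11, 10, 90))
  gt <- pose_instance(pts, sk)
  pp <- pts; pp[11, ] <- NA
  expect_equal(round(compute_oks(gt, pose_instance(pp, sk)), 2), 0.91)
})

test_that("OKS is permutation-symmetric, translation-invariant, monotone", {
  set.seed(3)
  pts <- cbind(runif(5, 10, 90), runif(5, 10, 90))
  noise <- matrix(rnorm(10, 0, 2), 5, 2)
  gt <- pose_instance(pts, mouse5)
  pred <- pose_instance(pts + noise, mouse5)
  base <- compute_oks(gt, pred)

  perm <- sample(5)
  gt_p <- pose_instance(pts[perm, ], mouse5)
  pred_p <- pose_instance((pts + noise)[perm, ], mouse5)
  expect_equal(compute_oks(gt_p, pred_p), base)

  shift <- c(11.5, -7.25)
  expect_equal(compute_oks(pose_instance(sweep(pts, 2, shift, `+`), mouse5),
                           pose_instance(sweep(pts + noise, 2, shift, `+`),
                                         mouse5)),
               base)

  # strictly decreasing in any single-node displacement
  worse <- pts + noise
  worse[3, ] <- worse[3, ] + c(5, 5)
  expect_lt(compute_oks(gt, pose_instance(worse, mouse5)), base)

  expect_error(compute_oks(gt, gt, oks_params(sigma = -1)))
})

test_that("greedy frame matching follows the sorted-exhaustive trace", {
  set.seed(4)
  g1 <- rand_instance(mouse5)
  g2 <- rand_instance(mouse5)
  m <- match_frame_instances(list(g1), list(g1))
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$oks, 1)

  # crossed OKS: pred1 matches g2 perfectly, pred2 is a noisy g1
  p1 <- g2
  p2 <- pose_instance(g1$points + matrix(rnorm(10, 0, 1), 5, 2), mouse5)
  mm <- match_frame_instances(list(g1, g2), list(p1, p2))
  # greedy-trace oracle: repeatedly take the largest OKS cell
  oks <- mm$oks
  expect_equal(mm$pairs$gt[1], 2)   # global best pair first (g2, p1)
  expect_equal(mm$pairs$pred[1], 1)
  expect_equal(mm$pairs$oks[1], max(oks))

  # extra prediction is an unmatched FP
  m3 <- match_frame_instances(list(g1), list(g1, p2))
  expect_equal(length(m3$unmatched_pred), 1)
})

test_that("mAP is 1 for exact predictions and 0 for none", {
  set.seed(5)
  matches <- lapply(1:3, function(i) {
    g <- rand_instance(mouse5)
    match_frame_instances(list(g), list(g))
  })
  r <- compute_map(matches)
  expect_equal(r$mAP, 1.0)
  expect_equal(r$mAR, 1.0)
  expect_equal(r$per_threshold$AP, rep(1, 10))

  g <- rand_instance(mouse5)
  expect_warning(r0 <- compute_map(match_frame_instances(list(g), list())),
                 "no predictions")
  expect_equal(r0$mAP, 0)
})

test_that("mAP equals the independent VOC-interpolation oracle", {
  # constructed OKS values straddling the thresholds, plus unmatched items
  oks_values <- c(0.97, 0.93, 0.88, 0.82, 0.77, 0.71, 0.66, 0.52, 0.49, 0.31)
  sk <- chain_skeleton(2)
  frames <- lapply(seq_along(oks_values), function(i) {
    gt <- pose_instance(rbind(c(20, 20), c(60, 60)), sk)
    # displace both nodes equally so OKS = exp(-d2/(2 a s^2)) hits the
    # target exactly
    target <- oks_values[i]
    alpha <- 40 * 40
    d <- sqrt(-2 * alpha * 0.025^2 * log(target))
    pred_pts <- rbind(c(20 + d, 20), c(60 + d, 60))
    match_frame_instances(list(gt), list(pose_instance(pred_pts, sk)))
  })
  # two extra FNs and one extra FP
  gt_extra <- pose_instance(rbind(c(10, 10), c(30, 30)), sk)
  frames[[length(frames) + 1]] <-
    match_frame_instances(list(gt_extra, gt_extra), list())
  frames[[length(frames) + 1]] <-
    match_frame_instances(list(), list(gt_extra))

  r <- compute_map(frames)
  oracle <- voc_map_oracle(c(oks_values, 0), n_gt = 12)
  expect_equal(r$mAP, oracle$mAP, tolerance = 1e-12)
  expect_equal(r$mAR, oracle$mAR, tolerance = 1e-12)
  expect_equal(r$per_threshold$AP, oracle$AP, tolerance = 1e-12)
})

test_that("duplicate perfect predictions are booked as FPs, not TPs", {
  g <- pose_instance(rbind(c(20, 20), c(60, 60)), chain_skeleton(2))
  m <- match_frame_instances(list(g), list(g, g))
  r <- compute_map(m)
  oracle <- voc_map_oracle(c(1, 0), n_gt = 1)
  expect_equal(r$mAP, oracle$mAP)
  expect_equal(r$per_threshold$TP, rep(1L, 10))
  expect_equal(r$per_threshold$FP, rep(1L, 10))
})

test_that("localization errors report exact percentiles", {
  set.seed(6)
  g <- rand_instance(mouse5)
  exact <- list(gt_list = list(g), pred_list = list(g),
                match = match_frame_instances(list(g), list(g)))
  le <- localization_errors(exact)
  expect_true(all(le$errors$error == 0))

  shifted <- pose_instance(g$points + cbind(rep(1, 5), 0), mouse5)
  le1 <- localization_errors(list(gt_list = list(g),
                                  pred_list = list(shifted),
                                  match = match_frame_instances(
                                    list(g), list(shifted))))
  expect_true(all(abs(le1$errors$error - 1) < 1e-12))
  expect_equal(le1$percentiles$p95[le1$percentiles$node == "all"], 1)
})

test_that("noisy predictions match the Rayleigh error model", {
  # isotropic Gaussian noise with sd s gives Rayleigh errors; the 95th
  # percentile is s * sqrt(-2 log(0.05)) (distributional oracle)
  sk <- mouse5
  s <- 2
  set.seed(7)
  frames <- lapply(1:200, function(i) {
    g <- rand_instance(sk, c(30, 200), c(30, 200))
    p <- pose_instance(g$points + matrix(rnorm(10, 0, s), 5, 2), sk)
    list(gt_list = list(g), pred_list = list(p),
         match = match_frame_instances(list(g), list(p),
                                       oks_params(sigma = 0.1)))
  })
  le <- localization_errors(frames)
  expect_equal(nrow(le$errors), 1000)
  theo <- s * sqrt(-2 * log(0.05))
  got <- le$percentiles$p95[le$percentiles$node == "all"]
  expect_lt(abs(got - theo) / theo, 0.10)
})

test_that("ID switches follow the hand-traced oracle and rate arithmetic", {
  sk <- chain_skeleton(2)
  mk_session <- function(assign) {
    # two static, well-separated animals; assign[[k]] gives the predicted
    # track id carried by GT identity k in each frame
    pts <- list(rbind(c(20, 20), c(26, 20)), rbind(c(70, 70), c(76, 70)))
    n <- length(assign[[1]])
    gt_frames <- pred_frames <- vector("list", n)
    for (t in seq_len(n)) {
      gt_frames[[t]] <- labeled_frame("v", t - 1L, list(
        pose_instance(pts[[1]], sk, track_id = 1L),
        pose_instance(pts[[2]], sk, track_id = 2L)))
      pred_frames[[t]] <- labeled_frame("v", t - 1L, list(
        pose_instance(pts[[1]], sk, track_id = assign[[1]][t]),
        pose_instance(pts[[2]], sk, track_id = assign[[2]][t])))
    }
    tracks <- data.frame(track_id = 1:2, name = c("a", "b"))
    list(gt = labels_dataset(sk, gt_frames, tracks = tracks,
                             image_size = c(100L, 100L)),
         pred = labels_dataset(sk, pred_frames, tracks = tracks,
                               image_size = c(100L, 100L)))
  }

  # identical assignments: zero switches
  same <- mk_session(list(rep(1L, 10), rep(2L, 10)))
  expect_equal(count_id_switches(same$gt, same$pred)$switches, 0)

  # one sustained swap at frame 5 of 10: one switch per identity = 2
  a1 <- c(rep(1L, 5), rep(2L, 5))
  a2 <- c(rep(2L, 5), rep(1L, 5))
  swapped <- mk_session(list(a1, a2))
  got <- count_id_switches(swapped$gt, swapped$pred)
  expect_equal(got$switches, 2)
  expect_equal(got$switches, id_switch_oracle(list(a1, a2)))

  # rate arithmetic: 5 switches in 50,000 frames -> 10 per 100k
  expect_equal(5 / 50000 * 1e5, 10)
  expect_equal(got$rate_per_100k, 2 / 10 * 1e5)
})

test_that("ID switch counting agrees with the oracle on random assignments", {
  sk <- chain_skeleton(2)
  set.seed(8)
  for (rep in 1:5) {
    a1 <- sample(1:3, 20, replace = TRUE)
    a2 <- 4L + sample(0:2, 20, replace = TRUE)
    pts <- list(rbind(c(20, 20), c(26, 20)), rbind(c(70, 70), c(76, 70)))
    gt_frames <- pred_frames <- vector("list", 20)
    for (t in 1:20) {
      gt_frames[[t]] <- labeled_frame("v", t - 1L, list(
        pose_instance(pts[[1]], sk, track_id = 1L),
        pose_instance(pts[[2]], sk, track_id = 2L)))
      pred_frames[[t]] <- labeled_frame("v", t - 1L, list(
        pose_instance(pts[[1]], sk, track_id = a1[t]),
        pose_instance(pts[[2]], sk, track_id = a2[t])))
    }
    gt <- labels_dataset(sk, gt_frames,
                         tracks = data.frame(track_id = 1:2,
                                             name = c("a", "b")),
                         image_size = c(100L, 100L))
    pred <- labels_dataset(sk, pred_frames,
                           tracks = data.frame(track_id = 1:6,
                                               name = paste0("t", 1:6)),
                           image_size = c(100L, 100L))
    expect_equal(count_id_switches(gt, pred)$switches,
                 id_switch_oracle(list(a1, a2)))
  }
})
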