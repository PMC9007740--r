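test_that("score_connection handles aligned, orthogonal and empty fields", {
  sk <- chain_skeleton(2)
  g <- grid_spec(32, 32, output_stride = 1, sigma_base = 1)
  # constant synthetic field pointing along +x for edge 1
  pafs <- structure(list(tensor = array(0, c(32, 32, 2)), grid = g,
                         edges = sk$edges, paf_sigma = 5),
                    class = "part_affinity_fields")
  pafs$tensor[, , 1] <- 1
  expect_equal(score_connection(pafs, 1, c(2, 10), c(20, 10)), 1.0)
  # perpendicular candidate direction
  expect_equal(score_connection(pafs, 1, c(10, 2), c(10, 20)), 0.0)
  # zero-length candidate
  expect_equal(score_connection(pafs, 1, c(5, 5), c(5, 5)), 0)
})

test_that("10-point scores agree with dense integration on encoded scenes", {
  sk <- example_skeletons()$mouse5
  sc <- generate_scene(scene_spec(image_size = c(160L, 160L), n_instances = 2,
                                  min_separation = 64, pose_scale = 24,
                                  seed = 21))
  g <- grid_spec(160, 160, output_stride = 1, sigma_base = 1)
  pafs <- encode_pafs(sc$instances, sk, g)
  for (e in seq_len(nrow(sk$edges))) {
    s_node <- sk$edges[e, 1]; d_node <- sk$edges[e, 2]
    for (inst in sc$instances) {
      src <- inst$points[s_node, ]; dst <- inst$points[d_node, ]
      got <- score_connection(pafs, e, src, dst)
      oracle <- dense_line_integral(pafs, e, src, dst)
      expect_equal(got, oracle, tolerance = 0.05)
    }
    # true connection outscores the cross-animal swap
    true1 <- score_connection(pafs, e, sc$instances[[1]]$points[s_node, ],
                              sc$instances[[1]]$points[d_node, ])
    swap <- score_connection(pafs, e, sc$instances[[1]]$points[s_node, ],
                             sc$instances[[2]]$points[d_node, ])
    expect_gt(true1, swap)
  }
})

test_that("match_edge equals the permutation oracle and filters by score", {
  # 1 source, 1 dest, positive score
  one <- data.frame(src = 1L, dst = 2L, score = 0.9)
  expect_equal(nrow(match_edge(one)), 1)
  expect_equal(nrow(match_edge(data.frame(src = 1L, dst = 2L, score = 0.01))),
               0)

  set.seed(5)
  for (rep in 1:10) {
    ns <- sample(2:4, 1); nd <- sample(2:4, 1)
    cand <- expand.grid(src = seq_len(ns), dst = ns + seq_len(nd))
    cand$score <- runif(nrow(cand), 0.1, 1)  # all above min_score
    got <- match_edge(cand)
    m <- matrix(cand$score, ns, nd)
    expect_equal(sum(got$score), brute_force_assignment(m)$total,
                 tolerance = 1e-12)
    expect_equal(nrow(got), min(ns, nd))
  }
})

test_that("assembly recovers clean encoded scenes exactly", {
  sk <- example_skeletons()$fly13
  g <- grid_spec(192, 192, output_stride = 2, sigma_base = 1)
  sc1 <- generate_scene(scene_spec(image_size = c(192L, 192L), skeleton = sk,
                                   n_instances = 1, pose_scale = 40,
                                   seed = 31))
  cms <- encode_confidence_maps(sc1$instances, g)
  pafs <- encode_pafs(sc1$instances, sk, g)
  out <- bottomup_decode(cms, pafs, sk)
  expect_length(out, 1)
  expect_true(all(out[[1]]$visible))
  expect_lt(max(abs(out[[1]]$points - sc1$instances[[1]]$points)), 0.5)

  sc3 <- generate_scene(scene_spec(image_size = c(256L, 256L), skeleton = sk,
                                   n_instances = 3, min_separation = 90,
                                   pose_scale = 36, seed = 33))
  cms3 <- encode_confidence_maps(sc3$instances, g3 <- grid_spec(256, 256, 2, 1))
  pafs3 <- encode_pafs(sc3$instances, sk, g3)
  out3 <- bottomup_decode(cms3, pafs3, sk)
  expect_length(out3, 3)
  for (inst in out3) {
    cen <- colMeans(inst$points[inst$visible, , drop = FALSE])
    truth <- sc3$instances[[which.min(vapply(sc3$instances, function(t)
      sum((colMeans(t$points) - cen)^2), numeric(1)))]]
    expect_true(all(inst$visible))
    expect_lt(max(abs(inst$points - truth$points)), 0.5)
  }
})

test_that("assembly matches the exhaustive max-score partition on a toy", {
  # 3 instances on a 4-node chain: enumerate every per-edge permutation
  # combination and pick the grouping with the best total score, then check
  # greedy assembly returns that grouping.
  sk <- chain_skeleton(4)
  g <- grid_spec(224, 224, output_stride = 1, sigma_base = 1)
  sc <- generate_scene(scene_spec(image_size = c(224L, 224L), skeleton = sk,
                                  n_instances = 3, min_separation = 70,
                                  pose_scale = 24, seed = 55))
  cms <- encode_confidence_maps(sc$instances, g)
  pafs <- encode_pafs(sc$instances, sk, g)
  peaks <- refine_peaks(cms, find_local_peaks(cms))
  expect_equal(nrow(peaks), 12)  # 3 instances x 4 nodes

  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  score_of <- function(e, si, di) {
    ids_s <- which(peaks$channel == sk$edges[e, 1])
    ids_d <- which(peaks$channel == sk$edges[e, 2])
    score_connection(pafs, e, c(peaks$x[ids_s[si]], peaks$y[ids_s[si]]),
                     c(peaks$x[ids_d[di]], peaks$y[ids_d[di]]))
  }
  smat <- lapply(1:3, function(e)
    outer(1:3, 1:3, Vectorize(function(si, di) score_of(e, si, di))))
  best <- -Inf; best_combo <- NULL
  for (p1 in perms3) for (p2 in perms3) for (p3 in perms3) {
    tot <- sum(smat[[1]][cbind(1:3, p1)]) + sum(smat[[2]][cbind(1:3, p2)]) +
      sum(smat[[3]][cbind(1:3, p3)])
    if (tot > best) { best <- tot; best_combo <- list(p1, p2, p3) }
  }
  out <- bottomup_decode(cms, pafs, sk)
  expect_length(out, 3)
  expect_equal(sum(vapply(out, `[[`, numeric(1), "instance_score")), best,
               tolerance = 1e-9)
  # the optimal grouping is the ground-truth one on clean encodings
  for (inst in out) {
    cen <- colMeans(inst$points)
    truth <- sc$instances[[which.min(vapply(sc$instances, function(t)
      sum((colMeans(t$points) - cen)^2), numeric(1)))]]
    expect_lt(max(abs(inst$points - truth$points)), 0.5)
  }
})

test_that("an occluded node yields an instance with that node invisible", {
  sk <- example_skeletons()$mouse5
  sc <- generate_scene(scene_spec(image_size = c(128L, 128L), n_instances = 1,
                                  pose_scale = 24, seed = 8))
  inst <- sc$instances[[1]]
  inst$points[5, ] <- NA  # delete the tail tip from the maps
  inst$visible[5] <- FALSE
  g <- grid_spec(128, 128, output_stride = 1, sigma_base = 1)
  cms <- encode_confidence_maps(list(inst), g)
  pafs <- encode_pafs(list(inst), sk, g)
  out <- bottomup_decode(cms, pafs, sk)
  expect_length(out, 1)
  expect_identical(out[[1]]$visible, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("no peak is ever assigned to two instances", {
  sk <- example_skeletons()$mouse5
  for (seed in 1:5) {
    sc <- generate_scene(scene_spec(image_size = c(192L, 192L),
                                    n_instances = 4, min_separation = 48,
                                    pose_scale = 20, seed = seed))
    g <- grid_spec(192, 192, output_stride = 2, sigma_base = 1)
    cms <- encode_confidence_maps(sc$instances, g)
    pafs <- encode_pafs(sc$instances, sk, g)
    out <- bottomup_decode(cms, pafs, sk, allow_singletons = TRUE)
    used <- unlist(lapply(out, function(i) attr(i, "peak_ids")))
    used <- used[!is.na(used)]
    expect_false(anyDuplicated(used) > 0)
  }
})

test_that("top-down decoding restores full-frame coordinates", {
  sk <- example_skeletons()$mouse5
  sc <- generate_scene(scene_spec(image_size = c(160L, 160L), n_instances = 2,
                                  min_separation = 64, pose_scale = 20,
                                  seed = 12))
  anchors <- t(vapply(sc$instances, select_anchor, numeric(2),
                      anchor_node = "snout"))
  img <- render_scene(sc$instances, 160, 160)
  crops <- make_anchor_crops(img, anchors, crop_size = 64)
  # oracle-encode each crop: shift the centered instance into crop coords
  crop_cms <- lapply(seq_along(sc$instances), function(k) {
    pts <- sweep(sc$instances[[k]]$points, 2, crops$offsets[k, ])
    encode_confidence_maps(
      list(pose_instance(pts, sk, visible = sc$instances[[k]]$visible)),
      grid_spec(64, 64, output_stride = 1, sigma_base = 1))
  })
  out <- topdown_decode(crop_cms, crops, sk)
  expect_length(out, 2)
  for (k in 1:2) {
    expect_lt(max(abs(out[[k]]$points - sc$instances[[k]]$points)), 0.25)
  }
})

test_that("top-down decoding survives corner anchors and drops empty crops", {
  sk <- chain_skeleton(2)
  truth <- pose_instance(rbind(c(3, 4), c(10, 6)), sk)
  img <- render_scene(list(truth), 64, 64)
  crops <- make_anchor_crops(img, rbind(c(3, 4)), crop_size = 32)
  pts <- sweep(truth$points, 2, crops$offsets[1, ])
  crop_cms <- list(encode_confidence_maps(
    list(pose_instance(pts, sk)), grid_spec(32, 32, 1, 1)))
  out <- topdown_decode(crop_cms, crops, sk)
  expect_lt(max(abs(out[[1]]$points - truth$points)), 0.25)

  empty <- list(structure(list(tensor = array(0, c(32, 32, 2)),
                               grid = grid_spec(32, 32, 1, 1),
                               node_names = sk$nodes),
                          class = "confidence_maps"))
  expect_message(out2 <- topdown_decode(empty, crops, sk), "dropped")
  expect_length(out2, 0)
})

test_that("class-map identity assignment is exact on one-hot maps", {
  sk <- chain_skeleton(2)
  g <- grid_spec(64, 64, output_stride = 1, sigma_base = 1)
  i1 <- pose_instance(rbind(c(10, 10), c(16, 10)), sk, class_id = 1L)
  i2 <- pose_instance(rbind(c(40, 40), c(46, 40)), sk, class_id = 2L)
  cm <- encode_class_maps(list(i1, i2), 2, radius = 5, g)
  blank1 <- pose_instance(i1$points, sk)
  blank2 <- pose_instance(i2$points, sk)
  got <- assign_ids_class_maps(list(blank2, blank1), cm)
  expect_equal(got[[1]]$class_id, 2L)
  expect_equal(got[[2]]$class_id, 1L)

  # instance entirely inside an ambiguous (zeroed) region stays unassigned
  i3 <- pose_instance(rbind(c(12, 10), c(18, 10)), sk, class_id = 2L)
  cm2 <- encode_class_maps(list(i1, i3), 2, radius = 6, g)
  mid <- pose_instance(rbind(c(14, 10), c(15, 10)), sk)
  expect_message(got2 <- assign_ids_class_maps(list(mid), cm2), "unassigned")
  expect_null(got2[[1]]$class_id)
})

test_that("probability assignment equals the permutation oracle", {
  expect_equal(assign_ids_probabilities(diag(3))$class, 1:3)
  swapped <- diag(3)[, c(2, 1, 3)]
  expect_equal(assign_ids_probabilities(swapped)$class, c(2, 1, 3))
  expect_equal(nrow(assign_ids_probabilities(matrix(numeric(), 0, 0))), 0)
  expect_error(assign_ids_probabilities(matrix(-1, 2, 2)), "nonnegative")

  set.seed(77)
  m <- matrix(runif(16), 4, 4)
  got <- assign_ids_probabilities(m)
  expect_equal(sum(got$score), brute_force_assignment(m)$total,
               tolerance = 1e-12)
})
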