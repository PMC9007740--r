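# Independent oracles and fixture builders. Each oracle deliberately uses a
# different algorithm than the implementation it checks.

# best total over all permutations (exhaustive); n <= ~6
brute_force_assignment <- function(m, maximize = TRUE) {
  n <- min(dim(m))
  rows <- seq_len(nrow(m))
  cols <- seq_len(ncol(m))
  best <- if (maximize) -Inf else Inf
  best_pairs <- NULL
  rec <- function(r_left, c_left, acc, pairs) {
    if (length(pairs) == 2L * n) {
      if ((maximize && acc > best) || (!maximize && acc < best)) {
        best <<- acc
        best_pairs <<- matrix(pairs, ncol = 2, byrow = TRUE)
      }
      return(invisible())
    }
    r <- r_left[1]
    if (length(r_left) > length(c_left)) {
      # more rows than columns: row r may stay unassigned
      rec(r_left[-1], c_left, acc, pairs)
    }
    for (cc in c_left) {
      rec(r_left[-1], setdiff(c_left, cc), acc + m[r, cc], c(pairs, r, cc))
    }
  }
  rec(rows, cols, 0, integer())
  list(total = best, pairs = best_pairs)
}

# literal eight-neighbor definition, pixel by pixel
brute_force_local_peaks <- function(m, threshold) {
  h <- nrow(m); w <- ncol(m)
  out <- NULL
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- m[r, c]
      if (v < threshold) next
      is_peak <- TRUE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > h || cc < 1 || cc > w) next  # -Inf border
          if (m[rr, cc] >= v) { is_peak <- FALSE; break }
        }
        if (!is_peak) break
      }
      if (is_peak) out <- rbind(out, c(r, c, v))
    }
  }
  out
}

# dense sampled line integral (bilinear), independent of nearest-pixel path
dense_line_integral <- function(pafs, edge, src, dst, n = 1000L) {
  v <- dst - src
  len <- sqrt(sum(v^2))
  if (len == 0) return(0)
  u <- v / len
  t <- seq(0, 1, length.out = n)
  stride <- pafs$grid$stride
  fx <- pafs$tensor[, , 2 * edge - 1]
  fy <- pafs$tensor[, , 2 * edge]
  bil <- function(m, x, y) {
    x <- pmin(pmax(x, 0), ncol(m) - 1); y <- pmin(pmax(y, 0), nrow(m) - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, ncol(m) - 1); y1 <- pmin(y0 + 1, nrow(m) - 1)
    fxr <- x - x0; fyr <- y - y0
    m[cbind(y0 + 1, x0 + 1)] * (1 - fxr) * (1 - fyr) +
      m[cbind(y0 + 1, x1 + 1)] * fxr * (1 - fyr) +
      m[cbind(y1 + 1, x0 + 1)] * (1 - fxr) * fyr +
      m[cbind(y1 + 1, x1 + 1)] * fxr * fyr
  }
  sx <- (src[1] + t * v[1]) / stride
  sy <- (src[2] + t * v[2]) / stride
  mean(bil(fx, sx, sy) * u[1] + bil(fy, sx, sy) * u[2])
}

# naive 101-point interpolated AP, straight from the definition
voc_map_oracle <- function(pred_oks, n_gt,
                           thresholds = seq(0.5, 0.95, by = 0.05)) {
  pred_oks <- sort(pred_oks, decreasing = TRUE)
  aps <- ars <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    tp <- 0; fp <- 0
    precision <- recall <- numeric(length(pred_oks))
    for (k in seq_along(pred_oks)) {
      if (pred_oks[k] >= th) tp <- tp + 1 else fp <- fp + 1
      precision[k] <- tp / (tp + fp)
      recall[k] <- tp / n_gt
    }
    ps <- numeric(101)
    for (ri in 0:100) {
      r <- ri / 100
      sel <- which(recall >= r)
      ps[ri + 1] <- if (length(sel)) max(precision[sel]) else 0
    }
    aps[ti] <- mean(ps)
    ars[ti] <- if (length(recall)) max(recall) else 0
  }
  list(mAP = mean(aps), mAR = mean(ars), AP = aps)
}

# receptive field term by term, no vectorization shared with the package
rf_direct <- function(kernels, strides, inclusive = TRUE) {
  rf <- 1
  for (i in seq_along(kernels)) {
    prod_s <- 1
    upper <- if (inclusive) i else i - 1
    j <- 1
    while (j <= upper) { prod_s <- prod_s * strides[j]; j <- j + 1 }
    rf <- rf + (kernels[i] - 1) * prod_s
  }
  rf
}

# independent ID-switch counter over explicit assignment sequences:
# seqs[[gt]] is the vector of predicted ids over frames (NA = unmatched)
id_switch_oracle <- function(seqs) {
  total <- 0L
  for (s in seqs) {
    s <- s[!is.na(s)]
    if (length(s) < 2) next
    total <- total + sum(s[-1] != s[-length(s)])
  }
  total
}

# simple chain skeleton a1 -> a2 -> ... -> an
chain_skeleton <- function(n, name = sprintf("chain%d", n)) {
  skeleton(sprintf("p%d", seq_len(n)),
           if (n > 1) cbind(seq_len(n - 1), 2:n) else matrix(integer(), ncol = 2),
           name = name)
}

rand_instance <- function(skel, xr = c(10, 90), yr = c(10, 90),
                          track_id = NULL, class_id = NULL) {
  nn <- length(skel$nodes)
  pose_instance(cbind(stats::runif(nn, xr[1], xr[2]),
                      stats::runif(nn, yr[1], yr[2])),
                skel, track_id = track_id, class_id = class_id)
}

# randomized dataset for container round-trip property tests
rand_dataset <- function(seed, n_frames = 4, with_tracks = TRUE) {
  set.seed(seed)
  skel <- chain_skeleton(sample(2:6, 1))
  tracks <- data.frame(track_id = 1:3, name = paste0("t", 1:3))
  frames <- lapply(seq_len(n_frames), function(fi) {
    insts <- lapply(seq_len(sample(0:3, 1)), function(k) {
      inst <- rand_instance(skel, track_id = if (with_tracks) k)
      if (length(skel$nodes) > 1 && runif(1) < 0.5) {
        hide <- sample(length(skel$nodes), 1)
        if (sum(inst$visible) > 1) {
          inst$points[hide, ] <- NA
          inst$visible[hide] <- FALSE
        }
      }
      inst
    })
    labeled_frame("vid0", fi - 1L, insts)
  })
  labels_dataset(skel, frames, tracks = tracks, image_size = c(100L, 100L),
                 provenance = sprintf("rand_dataset seed %d", seed))
}
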