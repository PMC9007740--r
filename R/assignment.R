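#' Solve the linear assignment problem
#'
#' Finds a one-to-one assignment of rows to columns of a cost matrix that
#' minimizes (or maximizes) the total cost, via the shortest-augmenting-path
#' formulation of the Hungarian algorithm (O(n^3)). When the matrix is
#' rectangular, `min(nrow, ncol)` pairs are returned. Non-finite entries are
#' treated as prohibitively expensive (for minimization) or worthless (for
#' maximization); callers that need to reject such pairs should filter the
#' returned scores.
#'
#' This is the matching engine behind per-edge candidate matching in
#' bottom-up grouping, appearance-based identity assignment and track
#' assignment.
#'
#' @param cost numeric matrix of pairwise costs (rows x cols).
#' @param maximize if `TRUE`, maximize total cost instead of minimizing.
#' @return a data.frame with columns `row`, `col` and `cost` (the original
#'   matrix entry), one line per assigned pair, ordered by `row`.
#' @examples
#' m <- rbind(c(1, 5), c(5, 1))
#' solve_assignment(m)       # picks the diagonal
#' solve_assignment(m, maximize = TRUE)
#' @export
solve_assignment <- function(cost, maximize = FALSE) {
  if (!is.matrix(cost) || !is.numeric(cost)) {
    stop("`cost` must be a numeric matrix")
  }
  if (any(is.nan(cost))) stop("`cost` contains NaN entries")
  empty <- data.frame(row = integer(), col = integer(), cost = numeric())
  if (nrow(cost) == 0L || ncol(cost) == 0L) return(empty)

  a <- if (maximize) -cost else cost
  # Replace infinities by a finite sentinel larger than any achievable total.
  fin <- a[is.finite(a)]
  big <- if (length(fin)) {
    max(fin) + (max(fin) - min(fin) + 1) * (length(a) + 1)
  } else 1
  a[!is.finite(a)] <- big

  transposed <- nrow(a) > ncol(a)
  if (transposed) a <- t(a)
  col_of_row <- lsap_core(a)

  if (transposed) {
    pairs <- data.frame(row = col_of_row, col = seq_along(col_of_row))
  } else {
    pairs <- data.frame(row = seq_along(col_of_row), col = col_of_row)
  }
  pairs <- pairs[order(pairs$row), , drop = FALSE]
  pairs$cost <- cost[cbind(pairs$row, pairs$col)]
  rownames(pairs) <- NULL
  pairs
}

# Shortest augmenting path Hungarian core; requires nrow(a) <= ncol(a) and
# finite entries. Returns, for each row i, the assigned column.
lsap_core <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  u <- numeric(n)            # row potentials
  v <- numeric(m + 1L)       # column potentials; m+1 is the virtual column
  p <- integer(m + 1L)       # p[j]: row currently assigned to column j
  way <- integer(m + 1L)     # way[j]: previous column on the alternating path

  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }

  col_of_row <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) col_of_row[p[j]] <- j
  col_of_row
}
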