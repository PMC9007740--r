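#' Define a skeleton (directed tree over named body parts)
#'
#' A skeleton is the grouping scaffold for multi-animal pose estimation: a
#' set of named nodes (body parts) plus directed edges (source -> destination)
#' forming a tree or forest. Edges drive both target encoding (part affinity
#' fields) and bottom-up instance assembly.
#'
#' @param nodes character vector of unique part names, in channel order.
#' @param edges two-column matrix of edges; either 1-based node indices or
#'   node names. May have zero rows (single-node skeletons).
#' @param name optional skeleton name.
#' @return an object of class `pose_skeleton` with elements `nodes`,
#'   `edges` (integer matrix, 1-based) and `name`.
#' @seealso [validate_skeleton()], [example_skeletons()]
#' @export
skeleton <- function(nodes, edges = matrix(integer(), ncol = 2), name = "skeleton") {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("a skeleton needs at least one node")
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix of (source, destination)")
  }
  if (is.character(edges)) {
    idx <- match(edges, nodes)
    if (anyNA(idx)) {
      stop("unknown node name(s) in edges: ",
           paste(unique(edges[is.na(idx)]), collapse = ", "))
    }
    edges <- matrix(idx, ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("source", "dest")
  structure(list(nodes = nodes, edges = edges, name = as.character(name)[1]),
            class = "pose_skeleton")
}

#' @export
print.pose_skeleton <- function(x, ...) {
  cat(sprintf("<pose_skeleton '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
format.pose_skeleton <- function(x, ...) {
  sprintf("%s (%d nodes, %d edges)", x$name, length(x$nodes), nrow(x$edges))
}

n_nodes <- function(skel) length(skel$nodes)

#' Validate skeleton invariants
#'
#' Checks that a skeleton is a well-formed directed tree/forest: all edge
#' indices in range, no self-edges, no duplicate edges, at most one incoming
#' edge per node, and no directed cycles. Violations are described, not
#' raised, so a GUI or config loader can report all of them at once.
#'
#' @param skel a [skeleton()].
#' @return character vector of human-readable violations; empty when the
#'   skeleton satisfies every invariant.
#' @examples
#' validate_skeleton(skeleton(c("a", "b"), rbind(c(1, 2))))  # character(0)
#' validate_skeleton(skeleton(c("a", "b"), rbind(c(1, 1))))  # self-edge
#' @export
validate_skeleton <- function(skel) {
  stopifnot(inherits(skel, "pose_skeleton"))
  viol <- character()
  n <- n_nodes(skel)
  e <- skel$edges
  if (nrow(e) == 0L) return(viol)

  bad <- which(e[, 1] < 1L | e[, 1] > n | e[, 2] < 1L | e[, 2] > n)
  for (i in bad) {
    viol <- c(viol, sprintf("edge %d (%d -> %d): node index out of range [1, %d]",
                            i, e[i, 1], e[i, 2], n))
  }
  ok <- setdiff(seq_len(nrow(e)), bad)

  self <- ok[e[ok, 1] == e[ok, 2]]
  for (i in self) {
    viol <- c(viol, sprintf("edge %d (%d -> %d): self-edge", i, e[i, 1], e[i, 2]))
  }

  key <- paste(e[, 1], e[, 2])
  dup <- ok[duplicated(key[ok])]
  for (i in dup) {
    viol <- c(viol, sprintf("edge %d (%d -> %d): duplicate edge", i, e[i, 1], e[i, 2]))
  }

  indeg <- tabulate(e[ok, 2], nbins = n)
  for (d in which(indeg > 1L)) {
    viol <- c(viol, sprintf("node %d ('%s'): %d incoming edges (max 1 allowed)",
                            d, skel$nodes[d], indeg[d]))
  }

  # Cycle detection by iterative DFS coloring over the directed graph
  # (self-edges excluded: they are already reported above).
  ok2 <- ok[e[ok, 1] != e[ok, 2]]
  adj <- lapply(seq_len(n), function(s) e[ok2, 2][e[ok2, 1] == s])
  color <- integer(n)  # 0 white, 1 on stack, 2 done
  has_cycle <- FALSE
  for (start in seq_len(n)) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, next_i = 1L))
    color[start] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      kids <- adj[[top$node]]
      if (top$next_i <= length(kids)) {
        stack[[length(stack)]]$next_i <- top$next_i + 1L
        child <- kids[top$next_i]
        if (color[child] == 1L) {
          has_cycle <- TRUE
        } else if (color[child] == 0L) {
          color[child] <- 1L
          stack[[length(stack) + 1L]] <- list(node = child, next_i = 1L)
        }
      } else {
        color[top$node] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  if (has_cycle) viol <- c(viol, "skeleton contains a directed cycle")
  viol
}

#' Topological order of skeleton edges
#'
#' Orders edges so that edges nearer the roots come first; used by greedy
#' bottom-up assembly. Requires a valid tree/forest.
#' @return integer vector of edge row indices.
#' @noRd
edge_topological_order <- function(skel) {
  e <- skel$edges
  if (nrow(e) == 0L) return(integer())
  n <- n_nodes(skel)
  depth <- rep(NA_integer_, n)
  indeg <- tabulate(e[, 2], nbins = n)
  roots <- which(indeg == 0L)
  depth[roots] <- 0L
  frontier <- roots
  while (length(frontier)) {
    nxt <- integer()
    for (s in frontier) {
      kids <- e[, 2][e[, 1] == s]
      kids <- kids[is.na(depth[kids])]
      depth[kids] <- depth[s] + 1L
      nxt <- c(nxt, kids)
    }
    frontier <- nxt
  }
  order(depth[e[, 1]], seq_len(nrow(e)))
}

#' Example skeletons spanning common lab species
#'
#' Returns the skeletons used throughout the package's tests and examples:
#' a 13-node fly, a 21-node bee, 5- and 11-node mice, and a 14-node gerbil.
#' Each is a valid directed tree rooted at a central, rarely occluded part.
#'
#' @return named list of [skeleton()] objects.
#' @export
example_skeletons <- function() {
  fly <- skeleton(
    c("head", "thorax", "abdomen", "wingL", "wingR", "forelegL4", "forelegR4",
      "midlegL4", "midlegR4", "hindlegL4", "hindlegR4", "eyeL", "eyeR"),
    rbind(c("thorax", "head"), c("thorax", "abdomen"),
          c("thorax", "wingL"), c("thorax", "wingR"),
          c("thorax", "forelegL4"), c("thorax", "forelegR4"),
          c("thorax", "midlegL4"), c("thorax", "midlegR4"),
          c("thorax", "hindlegL4"), c("thorax", "hindlegR4"),
          c("head", "eyeL"), c("head", "eyeR")),
    name = "fly13")
  bee <- skeleton(
    c("thor", "head", "abdo", "Lant1", "Lant2", "Rant1", "Rant2",
      "fLleg1", "fLleg2", "fRleg1", "fRleg2", "mLleg1", "mLleg2",
      "mRleg1", "mRleg2", "hLleg1", "hLleg2", "hRleg1", "hRleg2",
      "Lwing", "Rwing"),
    rbind(c("thor", "head"), c("thor", "abdo"),
          c("head", "Lant1"), c("head", "Rant1"),
          c("Lant1", "Lant2"), c("Rant1", "Rant2"),
          c("thor", "fLleg1"), c("fLleg1", "fLleg2"),
          c("thor", "fRleg1"), c("fRleg1", "fRleg2"),
          c("thor", "mLleg1"), c("mLleg1", "mLleg2"),
          c("thor", "mRleg1"), c("mRleg1", "mRleg2"),
          c("thor", "hLleg1"), c("thor", "hRleg1"),
          c("hLleg1", "hLleg2"), c("hRleg1", "hRleg2"),
          c("thor", "Lwing"), c("thor", "Rwing")),
    name = "bee21")
  mouse_hc <- skeleton(
    c("snout", "earL", "earR", "tb", "tt"),
    rbind(c("snout", "earL"), c("snout", "earR"),
          c("snout", "tb"), c("tb", "tt")),
    name = "mouse5")
  mouse_of <- skeleton(
    c("nose", "neck", "L_ear", "R_ear", "L_Fr_paw", "R_Fr_paw",
      "tail_base", "L_Hi_paw", "R_Hi_paw", "tail_mid", "tail_end"),
    rbind(c("neck", "L_Fr_paw"), c("neck", "R_Fr_paw"),
          c("tail_base", "R_Hi_paw"), c("tail_base", "L_Hi_paw"),
          c("tail_base", "tail_mid"), c("tail_mid", "tail_end"),
          c("neck", "nose"), c("neck", "R_ear"), c("neck", "L_ear"),
          c("tail_base", "neck")),
    name = "mouse11")
  gerbil <- skeleton(
    c("nose", "eyeL", "eyeR", "earL", "earR", "spine1", "spine2", "spine3",
      "spine4", "spine5", "tail1", "tail2", "tail3", "tail4"),
    rbind(c("spine3", "spine2"), c("spine2", "spine1"),
          c("spine1", "eyeL"), c("spine1", "earL"), c("spine1", "nose"),
          c("spine1", "eyeR"), c("spine1", "earR"),
          c("spine3", "spine4"), c("spine4", "spine5"),
          c("spine5", "tail1"), c("tail1", "tail2"),
          c("tail2", "tail3"), c("tail3", "tail4")),
    name = "gerbil14")
  list(fly13 = fly, bee21 = bee, mouse5 = mouse_hc,
       mouse11 = mouse_of, gerbil14 = gerbil)
}
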