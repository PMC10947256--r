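# Skeletonization and the skeleton graph: branch points, end points, edges
# with geodesic (along-skeleton) pixel lengths, spur trimming and commissural
# vein removal.

#' Skeletonize a binary mask
#'
#' Morphological thinning (Zhang-Suen, with a staircase cleanup pass) reduces
#' every foreground object to an 8-connected line one pixel wide while
#' preserving topology: connected components and holes survive, end points are
#' never eroded. An empty mask yields an empty skeleton.
#'
#' @param mask Logical/binary matrix, veins as foreground.
#' @return Logical skeleton matrix of identical dimensions.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  if (!any(m)) return(m)
  .thin_cpp(m)
}

.nbr_dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.nbr_dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

# neighbour id matrix (n x 8) over foreground pixels of a mask;
# 0 marks "no foreground neighbour in that direction"
.neighbour_ids <- function(sk, fg) {
  h <- nrow(sk); w <- ncol(sk)
  n <- length(fg)
  idmap <- integer(h * w)
  idmap[fg] <- seq_len(n)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  nbr <- matrix(0L, n, 8L)
  for (k in 1:8) {
    rr <- r + .nbr_dr[k]
    cc <- c + .nbr_dc[k]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    v <- integer(n)
    v[ok] <- idmap[(cc[ok] - 1L) * h + rr[ok]]
    nbr[, k] <- v
  }
  list(nbr = nbr, row = r, col = c)
}

#' Decompose a skeleton into a branch-point/end-point graph
#'
#' Classifies every skeleton pixel by its number of 8-connected neighbours:
#' end points have exactly one, junction pixels three or more. Junction pixels
#' that touch each other are merged into a single branch point (thinning
#' leaves small junction clusters), reported at the cluster pixel nearest its
#' centroid. Edges are traced by walking pixel paths between branch points and
#' end points; each edge records its pixel path, its geodesic length and the
#' Euclidean distance between its terminals. Geodesic length is measured from
#' the branch point itself, as a geodesic-distance transform would: the
#' number of path pixels beyond the junction cluster, plus one step per
#' branch-point terminal. A 3-pixel stem hanging off a crossbar is a spur of
#' length 3; a straight line of 50 pixels is one edge of length 50; abutting
#' edges share no length. A pure cycle with no junctions is stored as one
#' closed edge with coincident terminals. Coordinates are 1-based `(row,
#' col)`, the R matrix convention.
#'
#' @param skeleton Logical/binary 1-pixel-wide skeleton matrix.
#' @return A `skeleton_graph` object: a list with `skeleton`, `n_pixels`,
#'   `branch_points` and `end_points` (matrices of `(row, col)`, 1-based),
#'   `branch_clusters`, `isolated`, and `edges` (a list; each edge has
#'   `path` — linear pixel indices —, `a`/`b` terminal descriptors, `length`,
#'   `euclid`, `spur`, `closed` and `del`, the deletable non-junction pixels).
#' @export
build_graph <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  sk <- skeleton != 0
  h <- nrow(sk); w <- ncol(sk)
  fg <- which(sk)
  n <- length(fg)
  empty <- list(
    skeleton = sk, n_pixels = n, h = h, w = w,
    branch_points = matrix(integer(), 0L, 2L),
    branch_clusters = list(),
    end_points = matrix(integer(), 0L, 2L),
    isolated = matrix(integer(), 0L, 2L),
    edges = list()
  )
  class(empty) <- "skeleton_graph"
  if (n == 0L) return(empty)

  nb <- .neighbour_ids(sk, fg)
  nbr <- nb$nbr
  deg <- rowSums(nbr > 0L)
  junction <- deg >= 3L
  endpoint <- deg == 1L

  # merge 8-adjacent junction pixels into branch-point clusters
  clust <- integer(n)
  n_clust <- 0L
  for (j in which(junction)) {
    if (clust[j] != 0L) next
    n_clust <- n_clust + 1L
    queue <- j
    clust[j] <- n_clust
    head <- 1L
    while (head <= length(queue)) {
      cur <- queue[head]; head <- head + 1L
      for (nb_id in nbr[cur, ]) {
        if (nb_id > 0L && junction[nb_id] && clust[nb_id] == 0L) {
          clust[nb_id] <- n_clust
          queue <- c(queue, nb_id)
        }
      }
    }
  }
  reps <- integer(n_clust)
  clusters <- vector("list", n_clust)
  if (n_clust > 0L) {
    for (ci in seq_len(n_clust)) {
      px <- which(clust == ci)
      clusters[[ci]] <- px
      cr <- mean(nb$row[px]); cc <- mean(nb$col[px])
      d2 <- (nb$row[px] - cr)^2 + (nb$col[px] - cc)^2
      reps[ci] <- px[order(d2, nb$row[px], nb$col[px])[1L]]
    }
  }

  used <- matrix(FALSE, n, 8L)
  visited <- junction | endpoint
  edges <- list()
  ne <- 0L

  terminal_desc <- function(id) {
    if (junction[id]) {
      ci <- clust[id]
      list(type = "branch", id = ci,
           row = nb$row[reps[ci]], col = nb$col[reps[ci]])
    } else {
      list(type = "end", id = id, row = nb$row[id], col = nb$col[id])
    }
  }

  add_edge <- function(path_ids) {
    a <- terminal_desc(path_ids[1L])
    b <- terminal_desc(path_ids[length(path_ids)])
    non_j <- path_ids[!junction[path_ids]]
    spur <- (a$type == "branch" && b$type == "end") ||
      (a$type == "end" && b$type == "branch")
    commissural_candidate <- a$type == "branch" && b$type == "branch" &&
      !(a$id == b$id)
    # geodesic length measured from the branch point itself: the pixels
    # beyond the junction cluster, plus one step per branch terminal
    len <- length(non_j) + (a$type == "branch") + (b$type == "branch")
    e <- list(
      path = fg[path_ids],
      a = a, b = b,
      length = as.integer(len),
      euclid = sqrt((a$row - b$row)^2 + (a$col - b$col)^2),
      spur = spur,
      bridge = commissural_candidate,
      closed = FALSE,
      del = fg[non_j]
    )
    ne <<- ne + 1L
    edges[[ne]] <<- e
  }

  for (s in which(junction | endpoint)) {
    for (k in which(nbr[s, ] > 0L)) {
      if (used[s, k]) next
      used[s, k] <- TRUE
      path <- integer(64L)
      path[1L] <- s
      len <- 1L
      prev <- s
      cur <- nbr[s, k]
      repeat {
        len <- len + 1L
        if (len > length(path)) path <- c(path, integer(length(path)))
        path[len] <- cur
        if (junction[cur] || endpoint[cur]) break
        visited[cur] <- TRUE
        nbs <- nbr[cur, ]
        nbs <- nbs[nbs > 0L]
        nxt <- nbs[nbs != prev]
        if (length(nxt) == 0L) break  # defensive; deg-2 pixels have an exit
        prev <- cur
        cur <- nxt[1L]
      }
      kk <- which(nbr[cur, ] == prev)
      used[cur, kk] <- TRUE
      path <- path[seq_len(len)]
      # a direct contact between two junction pixels is cluster-internal
      # wiring (same cluster by construction), not an edge
      if (len == 2L && junction[path[1L]] && junction[path[2L]]) next
      add_edge(path)
    }
  }

  # pure cycles: chains never reached from a node
  for (s in which(deg == 2L & !visited)) {
    if (visited[s]) next
    path <- integer(64L)
    path[1L] <- s
    len <- 1L
    visited[s] <- TRUE
    prev <- s
    cur <- nbr[s, which(nbr[s, ] > 0L)[1L]]
    while (cur != s) {
      len <- len + 1L
      if (len > length(path)) path <- c(path, integer(length(path)))
      path[len] <- cur
      visited[cur] <- TRUE
      nbs <- nbr[cur, ]
      nbs <- nbs[nbs > 0L]
      nxt <- nbs[nbs != prev]
      prev <- cur
      cur <- nxt[1L]
    }
    path <- path[seq_len(len)]
    term <- list(type = "cycle", id = s, row = nb$row[s], col = nb$col[s])
    ne <- ne + 1L
    edges[[ne]] <- list(
      path = fg[path], a = term, b = term,
      length = len, euclid = 0,
      spur = FALSE, bridge = FALSE, closed = TRUE,
      del = fg[path]
    )
  }

  g <- list(
    skeleton = sk, n_pixels = n, h = h, w = w,
    branch_points = cbind(row = nb$row[reps], col = nb$col[reps]),
    branch_clusters = lapply(clusters, function(px) {
      cbind(row = nb$row[px], col = nb$col[px])
    }),
    end_points = cbind(row = nb$row[endpoint], col = nb$col[endpoint]),
    isolated = cbind(row = nb$row[deg == 0L], col = nb$col[deg == 0L]),
    edges = edges
  )
  class(g) <- "skeleton_graph"
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph> ", x$n_pixels, " px; ",
      nrow(x$branch_points), " branch point(s), ",
      nrow(x$end_points), " end point(s), ",
      length(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}

# after edge pixels are deleted, junction-cluster pixels that only existed
# to host the deleted branch can be left dangling; remove any pixel that
# became redundant (>= 2 foreground neighbours forming a single mutually
# 8-connected group), sweeping outward from the deletion sites in sorted
# order so the result is deterministic
.prune_redundant <- function(mask, deleted) {
  h <- nrow(mask); w <- ncol(mask)
  nb_of <- function(p) {
    r <- ((p - 1L) %% h) + 1L
    c <- ((p - 1L) %/% h) + 1L
    rr <- r + .nbr_dr; cc <- c + .nbr_dc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    lin <- (cc[ok] - 1L) * h + rr[ok]
    lin[mask[lin]]
  }
  one_group <- function(px) {
    r <- ((px - 1L) %% h) + 1L
    c <- ((px - 1L) %/% h) + 1L
    n <- length(px)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (abs(r[i] - r[j]) <= 1L && abs(c[i] - c[j]) <= 1L) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
  }
  frontier <- sort(unique(unlist(lapply(deleted, nb_of))))
  while (length(frontier)) {
    p <- frontier[1L]
    frontier <- frontier[-1L]
    if (!mask[p]) next
    nb <- nb_of(p)
    if (length(nb) >= 2L && one_group(nb)) {
      mask[p] <- FALSE
      frontier <- sort(unique(c(frontier, nb)))
    }
  }
  mask
}

#' Trim superfluous spur branches from a skeleton
#'
#' A spur is an edge running from a branch point to an end point, typically a
#' thinning artefact. Every spur whose geodesic length is strictly below
#' `trim_factor` is deleted: its pixels beyond the junction cluster are
#' removed, together with any cluster pixels left redundant by the removal.
#' Deletion can demote a branch point and expose a new spur, so deletion and
#' branch-point re-detection iterate until a fixed point. `trim_factor = 0` is
#' the identity. Trimming is idempotent and monotone in `trim_factor`.
#'
#' @param graph A `skeleton_graph`, or a skeleton mask (a graph is built).
#' @param trim_factor Non-negative integer pixel threshold (strict `<`).
#' @return The trimmed skeleton as a logical mask.
#' @export
trim_spurs <- function(graph, trim_factor) {
  trim_factor <- as.integer(trim_factor)
  stopifnot(trim_factor >= 0L)
  g <- if (is.matrix(graph)) build_graph(graph) else graph
  stopifnot(inherits(g, "skeleton_graph"))
  if (trim_factor == 0L) return(g$skeleton)
  repeat {
    doomed <- Filter(function(e) e$spur && e$length < trim_factor, g$edges)
    if (length(doomed) == 0L) return(g$skeleton)
    mask <- g$skeleton
    del <- unlist(lapply(doomed, `[[`, "del"))
    mask[del] <- FALSE
    mask <- .prune_redundant(mask, del)
    g <- build_graph(mask)
  }
}

#' Automatic trim factor from the mode spur length
#'
#' When a skeleton carries many superfluous pixels relative to the vein signal
#' — here, when spur pixels exceed `trigger_fraction` of all skeleton pixels —
#' the trim factor is derived from the data as the mode of the spur-length
#' multiset plus one (so spurs of the modal length fall under the strict-`<`
#' trimming rule). Ties in the mode break toward the smaller length. Otherwise
#' (including when there are no spurs) the user's `trim_factor` is returned
#' unchanged.
#'
#' @param graph A `skeleton_graph`.
#' @param trim_factor The user-supplied trim factor.
#' @param trigger_fraction Spur-pixel fraction in \[0, 1\] that triggers the
#'   automatic value (default 0.15).
#' @return Integer trim factor to apply.
#' @export
auto_trim_factor <- function(graph, trim_factor, trigger_fraction = 0.15) {
  g <- if (is.matrix(graph)) build_graph(graph) else graph
  stopifnot(inherits(g, "skeleton_graph"))
  trim_factor <- as.integer(trim_factor)
  spurs <- Filter(function(e) e$spur, g$edges)
  lens <- vapply(spurs, `[[`, integer(1), "length")
  if (length(lens) == 0L || g$n_pixels == 0L) return(trim_factor)
  spur_px <- sum(vapply(spurs, function(e) length(e$del), integer(1)))
  if (spur_px / g$n_pixels <= trigger_fraction) return(trim_factor)
  tab <- table(lens)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  modal + 1L
}

#' Remove commissural veins from a monocot skeleton
#'
#' Commissural veins are the short transverse connections between parallel
#' longitudinal veins in grass leaves; they are not wrapped in bundle sheath
#' and are excluded from Kranz vein density. An edge is removed when both its
#' terminals are (distinct) branch points and the Euclidean distance between
#' them is strictly below `keep_length`. Spur edges are never touched by this
#' operation, and `keep_length = 0` disables removal entirely.
#'
#' @param graph A `skeleton_graph`, or a skeleton mask.
#' @param keep_length Non-negative Euclidean span threshold in pixels.
#' @return Skeleton mask with commissural edges removed.
#' @export
remove_commissural <- function(graph, keep_length) {
  stopifnot(is.numeric(keep_length), keep_length >= 0)
  g <- if (is.matrix(graph)) build_graph(graph) else graph
  stopifnot(inherits(g, "skeleton_graph"))
  if (keep_length == 0) return(g$skeleton)
  doomed <- Filter(function(e) e$bridge && e$euclid < keep_length, g$edges)
  mask <- g$skeleton
  if (length(doomed)) {
    del <- unlist(lapply(doomed, `[[`, "del"))
    mask[del] <- FALSE
    mask <- .prune_redundant(mask, del)
  }
  mask
}

#' Skeleton length in pixels
#'
#' The primary length estimate is the raw foreground pixel count (`"pixel"`),
#' matching the density definition used throughout the package. A
#' diagonal-corrected variant (`"diagonal"`) weights diagonal pixel-to-pixel
#' steps by `sqrt(2)` and is exposed as an optional diagnostic only.
#'
#' @param skeleton Logical/binary skeleton mask.
#' @param method `"pixel"` (default) or `"diagonal"`.
#' @return Length in pixel units.
#' @export
skeleton_length <- function(skeleton, method = c("pixel", "diagonal")) {
  method <- match.arg(method)
  sk <- skeleton != 0
  if (method == "pixel") return(sum(sk))
  fg <- which(sk)
  if (length(fg) == 0L) return(0)
  nb <- .neighbour_ids(sk, fg)$nbr
  orth <- sum(nb[, c(1L, 3L, 5L, 7L)] > 0L) / 2
  diag <- sum(nb[, c(2L, 4L, 6L, 8L)] > 0L) / 2
  # each adjacency contributes one inter-pixel step; add one pixel per
  # component to convert steps to pixels-equivalent length
  orth + sqrt(2) * diag + max(0L, length(fg) - orth - diag)
}
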