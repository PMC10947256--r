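# Brute-force oracles and fixtures, independent of the package's
# implementation paths.

# direct O(k^2) windowed mean with replicate (clamped-index) padding
oracle_mean_blur <- function(img, w) {
  h <- nrow(img); wd <- ncol(img)
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) {
    for (j in seq_len(wd)) {
      ri <- pmin(pmax((i - w):(i + w), 1L), h)
      ci <- pmin(pmax((j - w):(j + w), 1L), wd)
      out[i, j] <- mean(img[ri, ci])
    }
  }
  out
}

# exhaustive search over all 255 cuts of a 256-bin histogram, between-class
# variance computed directly from the two classes' bin values
oracle_otsu_bin <- function(img, nbins = 256L) {
  b <- pmin(as.integer(floor(as.numeric(img) * nbins)), nbins - 1L)
  n <- length(b)
  best <- -Inf
  bestk <- NA_integer_
  for (k in 0:(nbins - 2L)) {
    g0 <- b[b <= k]
    g1 <- b[b > k]
    if (length(g0) == 0L || length(g1) == 0L) next
    w0 <- length(g0) / n
    v <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (v > best) {
      best <- v
      bestk <- k
    }
  }
  bestk
}

# ---- naive pixel-graph pruning oracle ---------------------------------------

oracle_neighbours <- function(mask, i, j) {
  h <- nrow(mask); w <- ncol(mask)
  out <- list()
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= h && jj >= 1L && jj <= w && mask[ii, jj]) {
        out[[length(out) + 1L]] <- c(ii, jj)
      }
    }
  }
  out
}

oracle_degree_map <- function(mask) {
  deg <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    deg[idx[r, 1], idx[r, 2]] <-
      length(oracle_neighbours(mask, idx[r, 1], idx[r, 2]))
  }
  deg
}

# are the pixels in `coords` (list of c(i, j)) one mutually 8-connected
# group? checked by naive flood fill over the list
oracle_one_group <- function(coords) {
  n <- length(coords)
  if (n <= 1L) return(TRUE)
  adj <- function(a, b) abs(a[1] - b[1]) <= 1L && abs(a[2] - b[2]) <= 1L
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (k in seq_len(n)) {
      if (!seen[k] && adj(coords[[cur]], coords[[k]])) {
        seen[k] <- TRUE
        queue <- c(queue, k)
      }
    }
  }
  all(seen)
}

# sequential removal of redundant pixels next to deletions: a pixel with
# >= 2 neighbours that form one mutually adjacent group carries no path;
# processed in sorted column-major order for determinism
oracle_prune_near <- function(mask, deleted) {
  h <- nrow(mask)
  lin <- function(p) (p[2] - 1L) * h + p[1]
  frontier <- list()
  for (d in deleted) {
    for (p in oracle_neighbours(mask, d[1], d[2])) {
      frontier[[length(frontier) + 1L]] <- p
    }
  }
  repeat {
    if (length(frontier) == 0L) return(mask)
    ord <- order(vapply(frontier, lin, numeric(1)))
    frontier <- frontier[ord]
    p <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (!mask[p[1], p[2]]) next
    nbs <- oracle_neighbours(mask, p[1], p[2])
    if (length(nbs) >= 2L && oracle_one_group(nbs)) {
      mask[p[1], p[2]] <- FALSE
      frontier <- c(frontier, nbs)
    }
  }
}

# batch fixpoint spur pruning: walk from every end point to the first
# junction pixel; the spur's geodesic length is the walked pixel count plus
# the final step onto the branch point; spurs strictly shorter than
# trim_factor are deleted (with redundant junction pixels cleaned up) and
# the process repeats until stable
oracle_trim <- function(mask, trim_factor) {
  mask <- mask != 0
  repeat {
    deg <- oracle_degree_map(mask)
    junction <- mask & deg >= 3L
    ends <- which(mask & deg == 1L, arr.ind = TRUE)
    del <- list()
    if (nrow(ends) > 0L) {
      for (r in seq_len(nrow(ends))) {
        path <- list(c(ends[r, 1], ends[r, 2]))
        prev <- NULL
        cur <- c(ends[r, 1], ends[r, 2])
        hit_junction <- FALSE
        repeat {
          nbs <- oracle_neighbours(mask, cur[1], cur[2])
          if (!is.null(prev)) {
            nbs <- Filter(function(p) !(p[1] == prev[1] && p[2] == prev[2]),
                          nbs)
          }
          if (length(nbs) == 0L) break
          nxt <- nbs[[1L]]
          if (junction[nxt[1], nxt[2]]) {
            hit_junction <- TRUE
            break
          }
          path[[length(path) + 1L]] <- nxt
          if (deg[nxt[1], nxt[2]] == 1L) break
          prev <- cur
          cur <- nxt
        }
        if (hit_junction && length(path) + 1L < trim_factor) {
          del <- c(del, path)
        }
      }
    }
    if (length(del) == 0L) return(mask)
    for (p in del) mask[p[1], p[2]] <- FALSE
    mask <- oracle_prune_near(mask, del)
  }
}

# 8-connected component count via flood fill
oracle_component_count <- function(mask) {
  mask <- mask != 0
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (p in oracle_neighbours(mask, cur[1], cur[2])) {
        if (!seen[p[1], p[2]]) {
          seen[p[1], p[2]] <- TRUE
          queue[[length(queue) + 1L]] <- p
        }
      }
    }
  }
  n
}

# ---- fixtures ---------------------------------------------------------------

# thin random skeleton: a chain of digital line segments between random
# lattice points (consecutive pixels differ by at most 1 in each coordinate)
random_skeleton <- function(h = 48L, w = 48L, n_seg = 8L, seed = 1L) {
  set.seed(seed)
  mask <- matrix(FALSE, h, w)
  pts <- cbind(sample.int(h, n_seg + 1L, replace = TRUE),
               sample.int(w, n_seg + 1L, replace = TRUE))
  for (i in seq_len(n_seg)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    nstep <- max(abs(b - a)) + 1L
    rr <- round(seq(a[1], b[1], length.out = nstep))
    cc <- round(seq(a[2], b[2], length.out = nstep))
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

# ladder raster: two vertical rails joined by horizontal rungs
ladder_mask <- function(h, rail_cols, rung_rows, w = max(rail_cols) + 10L) {
  mask <- matrix(FALSE, h, w)
  for (cc in rail_cols) mask[seq_len(h), cc] <- TRUE
  for (rr in rung_rows) mask[rr, rail_cols[1]:rail_cols[2]] <- TRUE
  mask
}

# T-shaped skeleton: horizontal crossbar with a vertical stem below
t_mask <- function(bar_row = 10L, bar_cols = 10:39, stem_col = 25L,
                   stem_rows = 11:30, h = 40L, w = 50L) {
  mask <- matrix(FALSE, h, w)
  mask[bar_row, bar_cols] <- TRUE
  mask[stem_rows, stem_col] <- TRUE
  mask
}

# minimal valid configuration for unit tests
test_config <- function(...) {
  load_config(list(input_path = ".", trim_factor = 0, pixel_length_um = 1,
                   x_pixels = 100, y_pixels = 100), overrides = list(...))
}

# compact synthetic spec that keeps unit tests fast
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_height = 256L, image_width = 256L, n_primaries = 3L,
         rail_spacing_px = 70, waviness_amplitude_px = 4,
         commissural_spacing_px = 90),
    list(...))
  do.call(vein_spec, args)
}
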