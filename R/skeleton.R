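# Binary-image thinning and skeleton-path utilities backing medial_axis().
# Guo-Hall thinning (the two-subiteration parallel algorithm) is
# implemented here because no installed imaging package exposes a 2-D
# skeletonization; unlike Zhang-Suen it does not disconnect 2-pixel-wide
# diagonal bands, which matters for obliquely oriented rods. It operates
# on small per-cell bounding boxes only.

# logical matrix in -> logical matrix out (1-pixel-wide 8-connected skeleton)
thin_mask <- function(m) {
  stopifnot(is.logical(m))
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  m <- pad
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    rs <- max(1L, 1L + dr):min(nrow(x), nrow(x) + dr)
    cs <- max(1L, 1L + dc):min(ncol(x), ncol(x) + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours p1..p8 = N, NE, E, SE, S, SW, W, NW
      p1 <- shift(m, -1L, 0L); p2 <- shift(m, -1L, 1L)
      p3 <- shift(m, 0L, 1L);  p4 <- shift(m, 1L, 1L)
      p5 <- shift(m, 1L, 0L);  p6 <- shift(m, 1L, -1L)
      p7 <- shift(m, 0L, -1L); p8 <- shift(m, -1L, -1L)
      cc <- (!p1 & (p2 | p3)) + (!p3 & (p4 | p5)) +
            (!p5 & (p6 | p7)) + (!p7 & (p8 | p1))
      n1 <- (p1 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p1)
      nn <- pmin(n1, n2)
      ok <- if (step == 1L) !((p5 | p6 | !p8) & p7) else
        !((p1 | p2 | !p4) & p3)
      cond <- m & cc == 1 & nn >= 2 & nn <= 3 & ok
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(pad) - 1L), 2:(ncol(pad) - 1L), drop = FALSE]
}

# longest geodesic path on a skeleton: double-sweep BFS over the
# 8-connected pixel graph, restricted to the largest connected component
# (thinning artifacts can leave stray fragments); ties broken by
# lexicographically smallest (row, col) so branched skeletons prune
# deterministically
skeleton_path <- function(skel) {
  skel <- largest_component(skel)
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  if (nrow(idx) == 1L) return(idx)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  id_of <- matrix(0L, nrow(skel), ncol(skel))
  id_of[idx] <- seq_len(nrow(idx))
  nbr <- function(i) {
    r <- idx[i, 1L]; c <- idx[i, 2L]
    rr <- rep(r + (-1:1), times = 3L)
    cc <- rep(c + (-1:1), each = 3L)
    keep <- rr >= 1L & rr <= nrow(skel) & cc >= 1L & cc <= ncol(skel) &
      !(rr == r & cc == c)
    ids <- id_of[cbind(rr[keep], cc[keep])]
    sort(ids[ids > 0L])
  }
  bfs <- function(src) {
    dist <- rep(NA_integer_, nrow(idx))
    parent <- rep(NA_integer_, nrow(idx))
    dist[src] <- 0L
    queue <- src
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in nbr(v)) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          parent[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  farthest <- function(dist) {
    dmax <- max(dist, na.rm = TRUE)
    cands <- which(!is.na(dist) & dist == dmax)
    cands[1L]  # idx rows are lexicographically ordered
  }
  s1 <- bfs(1L)
  u <- farthest(s1$dist)
  s2 <- bfs(u)
  v <- farthest(s2$dist)
  path <- integer(0)
  w <- v
  while (!is.na(w)) {
    path <- c(w, path)
    w <- s2$parent[w]
  }
  idx[path, , drop = FALSE]
}

# keep only the largest 8-connected component of a binary image
largest_component <- function(m) {
  if (!any(m)) return(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (lab[idx[s, 1L], idx[s, 2L]] > 0L) next
    cur <- cur + 1L
    queue <- list(idx[s, ])
    lab[idx[s, 1L], idx[s, 2L]] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r < 1L || r > nrow(m) || c < 1L || c > ncol(m)) next
        if (m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  if (cur == 1L) return(m)
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  lab == which.max(sizes)
}
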