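# Geometric fixtures and independent brute-force oracles shared across tests.
# Oracles are deliberately naive (O(n^2) scans, BFS/Dijkstra over explicit
# edge lists) and never call the package's compiled paths.

# Disc mask: pixels strictly inside radius r around an integer center.
mk_disc <- function(n, r, ci = (n + 1) / 2, cj = ci) {
  sqrt(outer((seq_len(n) - ci)^2, (seq_len(n) - cj)^2, "+")) < r
}

mk_annulus <- function(n, r_in, r_out, ci = (n + 1) / 2) {
  mk_disc(n, r_out, ci) & !mk_disc(n, r_in, ci)
}

# One-pixel-wide square ring.
mk_square_ring <- function(n, half) {
  c0 <- (n + 1) %/% 2
  m <- matrix(FALSE, n, n)
  m[(c0 - half):(c0 + half), c(c0 - half, c0 + half)] <- TRUE
  m[c(c0 - half, c0 + half), (c0 - half):(c0 + half)] <- TRUE
  m
}

# Polar angle map for an n x n grid around its center.
theta_map <- function(n, ci = (n + 1) / 2) {
  atan2(outer(seq_len(n) - ci, rep(1, n)), outer(rep(1, n), seq_len(n) - ci))
}

# Brute-force Euclidean distance transform (distance to nearest FALSE pixel).
bf_edt <- function(mask) {
  idx <- which(!mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out
}

# Brute-force geodesic distances (Dijkstra over an explicit 8-neighbour edge
# list, priority by repeated linear minimum scan).
bf_geodesic <- function(mask, src) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  dist[src[1], src[2]] <- 0
  visited <- matrix(FALSE, nr, nc)
  repeat {
    u <- which(!visited & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- ui + di; vj <- uj + dj
      if (vi < 1 || vj < 1 || vi > nr || vj > nc) next
      if (!mask[vi, vj]) next
      w <- if (di != 0 && dj != 0) sqrt(2) else 1
      if (dist[ui, uj] + w < dist[vi, vj]) dist[vi, vj] <- dist[ui, uj] + w
    }
  }
  dist
}

# Direct windowed mean/SD oracle for moving_profile.
bf_moving <- function(d, v, grid, window) {
  t(vapply(grid, function(g) {
    sel <- d >= g - window / 2 & d <= g + window / 2
    if (sum(sel) < 3) return(c(NA_real_, NA_real_))
    c(mean(v[sel]), sd(v[sel]))
  }, numeric(2)))
}

default_oc <- function(...) optical_config(pixel_size = 0.5, ...)
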