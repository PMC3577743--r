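# Independent oracles and shared fixtures for the test suite.

# Exhaustive path-sum POPAN likelihood: enumerate entry occasion b and
# death-after occasion d for every history, multiply the latent-path and
# detection probabilities directly. Usable for small T only.
oracle_history_prob <- function(w, phi, p, pent) {
  T <- length(w)
  tot <- 0
  for (b in 1:T) for (d in b:T) {
    outside <- setdiff(seq_len(T), b:d)
    if (length(outside) && any(w[outside] == 1)) next
    pr <- pent[b]
    if (d > b) pr <- pr * prod(phi[b:(d - 1)])
    if (d < T) pr <- pr * (1 - phi[d])
    det <- prod(ifelse(w[b:d] == 1, p[b:d], 1 - p[b:d]))
    tot <- tot + pr * det
  }
  tot
}

oracle_popan_loglik <- function(ch, phi, p, pent, N) {
  T <- ncol(ch)
  phi <- rep_len(phi, T - 1)
  p <- rep_len(p, T)
  key <- apply(ch, 1, paste, collapse = "")
  tab <- table(key)
  D <- nrow(ch)
  p0 <- oracle_history_prob(rep(0L, T), phi, p, pent)
  ll <- lgamma(N + 1) - lgamma(N - D + 1) - sum(lgamma(as.vector(tab) + 1))
  for (k in names(tab)) {
    w <- as.integer(strsplit(k, "")[[1]])
    ll <- ll + tab[[k]] * log(oracle_history_prob(w, phi, p, pent))
  }
  if (N > D) ll <- ll + (N - D) * log(p0)
  ll
}

# Gift-wrapping (Jarvis march) convex hull area: an algorithm independent
# of grDevices::chull.
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- if (length(hull) == 1L) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    best <- cand[1]
    for (k in cand[-1]) {
      cr <- (pts[best, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[best, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_best <- sum((pts[best, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_k > d_best)) best <- k
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrap failed to close")
  }
  h <- pts[hull, , drop = FALSE]
  m <- nrow(h)
  j <- c(m, seq_len(m - 1))
  abs(sum(h[j, 1] * h[, 2] - h[, 1] * h[j, 2]) / 2)
}

# Table-2-style worked example: per-class habitat areas (km2) and school
# counts within the 95% UD.
table2_areas <- c(57.4, 153.5, 83.9, 30.2, 5.6)
table2_counts <- c(28, 274, 170, 67, 2)

# small aligned depth grid builder for habitat tests
make_depth_grid <- function(depths, nx, ny, cell = 50, x0 = 0, y0 = 0) {
  g <- grid_spec(x0, y0, nx, ny, cell)
  structure(list(grid = g, depth = matrix(depths, nx, ny)),
            class = "depth_grid")
}
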