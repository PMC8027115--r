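# Independent oracles kept deliberately naive: they share no code with the
# package internals they check.

# breadth-first search distances from `from` over an adjacency list
bfs_distances <- function(adj, from) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# adjacency list straight from the igraph edge list (structure only)
adj_list <- function(obj) {
  el <- igraph::as_edgelist(obj$graph)
  adj <- vector("list", obj$p)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# plain SOM trained step by step with the same schedules as the package map;
# returns the BMU sequence.  Content distance only - the reference for the
# zeta = 0 equivalence.
plain_som_bmus <- function(W0, X, lr_start, lr_end, sigma_start, sigma_end,
                           t_max, n) {
  n2 <- ncol(W0)
  gx <- rep(seq_len(n), each = n); gy <- rep(seq_len(n), times = n)
  bmus <- integer(nrow(X))
  W <- W0
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    d <- colSums((W - x)^2)
    bmu <- which.min(d)
    bmus[t] <- bmu
    frac <- min((t - 1) / t_max, 1)
    lr <- lr_start * (lr_end / lr_start)^frac
    sg <- sigma_start * (sigma_end / sigma_start)^frac
    gd2 <- (gx - gx[bmu])^2 + (gy - gy[bmu])^2
    h <- lr * exp(-gd2 / (2 * sg^2))
    for (i in seq_len(n2)) W[, i] <- W[, i] + h[i] * (x - W[, i])
  }
  bmus
}

# scalar re-implementation of the blended distance for one unit
scalar_blend_distance <- function(x, w, cmap, cw, zeta) {
  s1 <- 0; s2 <- 0
  for (k in seq_along(x)) {
    s1 <- s1 + (x[k] - w[k])^2
    s2 <- s2 + (cmap[k] - cw[k])^2
  }
  (1 - zeta) * s1 + zeta * s2
}

cube_fixture <- function() build_cuboid(c(2, 2, 2))
cuboid_fixture <- function() build_cuboid(c(3, 2, 1))
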