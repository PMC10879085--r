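# shared fixture builders: everything is generated in code at test time

# small two-network time-course set with known structure
make_tc <- function(T_ = 60, C = 4, seed = 1, tr = 2,
                    labels = rep(c("DMN", "VIS"), each = C / 2)) {
  withr::with_seed(seed, {
    tc_set(matrix(rnorm(T_ * C), T_, C), tr = tr, network_labels = labels)
  })
}

# compact synthetic config for fast cohort tests: C = 10, two networks
small_config <- function(..., seed = 1) {
  synthetic_config(
    n_patient = 4, n_control = 4,
    network_sizes = c(DMN = 5L, VIS = 5L),
    n_timepoints = 120,
    block_correlations = list(
      low = list(within = 0.05, between = 0),
      moderate = list(within = 0.05, between = 0,
                      within_override = c(DMN = 0.6)),
      strong = list(within = 0.6, between = 0.05)),
    seed = seed, ...)
}

# brute-force L1 k-means objective: exhaustive search over all assignments
brute_force_l1_within <- function(X, k) {
  n <- nrow(X)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- grid[g, ]
    if (length(unique(lab)) < k) next
    tot <- 0
    for (c_ in seq_len(k)) {
      rows <- X[lab == c_, , drop = FALSE]
      ctr <- apply(rows, 2, median)
      tot <- tot + sum(abs(sweep(rows, 2, ctr)))
    }
    if (tot < best) best <- tot
  }
  best
}

# independent graph-metric oracle: triangle enumeration + Floyd-Warshall
oracle_graph_metrics <- function(adj) {
  C <- nrow(adj)
  deg <- rowSums(adj)
  clust <- numeric(C)
  for (i in seq_len(C)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] == 1) links <- links + 1
    }
    clust[i] <- 2 * links / (deg[i] * (deg[i] - 1))
  }
  D <- matrix(Inf, C, C)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k_ in seq_len(C)) for (i in seq_len(C)) for (j in seq_len(C)) {
    if (D[i, k_] + D[k_, j] < D[i, j]) D[i, j] <- D[i, k_] + D[k_, j]
  }
  off <- D[upper.tri(D)]
  lp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else Inf
  effs <- vapply(seq_len(C), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)]) / (C - 1)
  }, numeric(1))
  list(degree = deg, clustering = clust, lp = lp, cp = mean(clust),
       efficiency = effs)
}

# canonical pair vector of a symmetric matrix (row-major upper triangle)
upper_vec <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}
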