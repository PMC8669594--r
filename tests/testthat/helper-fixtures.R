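# Shared fixtures and independent oracles for the test suite.
# Expensive simulated objects are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small but complete two-session experiment (moderate noise)
small_experiment <- function() {
  cached("small_experiment", function()
    simulate_experiment(sim_config(n_sessions = 2,
                                   trials_per_task_per_session = 2,
                                   seed = 42)))
}

# its preprocessed epochs + rest
small_preprocessed <- function() {
  cached("small_preprocessed", function()
    preprocess_experiment(small_experiment()))
}

# source-space planted epochs at snr 10 on the 16-Hz decoding grid
planted_sources_16 <- function() {
  cached("planted_sources_16", function() {
    truth <- default_ground_truth(sim_config())
    simulate_source_epochs(truth, n_per_class = 10, snr = 10, rate = 16,
                           seed = 7)
  })
}

# ---- graph-metric oracles (independent of the implementation) ----

# brute-force DE / DS / CC / CPL from a weighted adjacency matrix
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  DE <- mean(rowSums(adj))
  DS <- (sum(adj > 0) / 2) / (n * (n - 1) / 2)
  # Onnela clustering by explicit triangle enumeration
  wmax <- max(adj)
  cc <- numeric(n)
  if (wmax > 0) {
    Wn <- adj / wmax
    for (i in seq_len(n)) {
      nb <- which(adj[i, ] > 0)
      k <- length(nb)
      if (k < 2) next
      s <- 0
      for (a in seq_along(nb)) for (b in seq_along(nb)) {
        if (a == b) next
        j <- nb[a]; h <- nb[b]
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
      cc[i] <- s / (k * (k - 1))
    }
  }
  # CPL by Floyd-Warshall on 1/w distances, connected pairs only
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1 / adj[adj > 0]
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  CPL <- if (length(vals)) mean(vals) else NA_real_
  list(DE = DE, DS = DS, CC = mean(cc), CPL = CPL)
}

# all labelled graphs on n nodes as edge-presence vectors
all_graphs_edges <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    as.logical(bitwAnd(rep(code, m), 2^(seq_len(m) - 1)) > 0)
  })
}

adj_from_edges <- function(n, present, weights) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  adj <- matrix(0, n, n)
  w <- weights[seq_len(nrow(pairs))]
  for (e in which(present)) {
    adj[pairs[e, 1], pairs[e, 2]] <- w[e]
    adj[pairs[e, 2], pairs[e, 1]] <- w[e]
  }
  adj
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(adj[, frontier, drop = FALSE] > 0) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

# random symmetric PLV-like matrix in [0, 1]
random_plv_matrix <- function(n = 24, density = 0.3) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- sample(up, round(density * length(up)))
  m[on] <- runif(length(on), 0.65, 1)
  off <- setdiff(up, on)
  m[off] <- runif(length(off), 0, 0.6)
  m <- m + t(m)
  diag(m) <- 1
  m
}

# exhaustive two-sided rank-sum p-value by permutation enumeration
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  W_obs <- sum(rank(pooled)[seq_len(na)])
  combos <- utils::combn(n, na)
  r <- rank(pooled)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}
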