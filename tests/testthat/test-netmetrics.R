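# Graph metrics vs hand computations and brute-force oracles.

adj_graph <- function(adj) {
  labels <- paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adj = adj, labels = labels, threshold = 0),
            class = "brain_graph")
}

test_that("degree and density match hand computations", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  dd <- degree_density(adj_graph(tri))
  expect_equal(dd[["DE"]], 2)
  expect_equal(dd[["DS"]], 1)

  empty <- degree_density(adj_graph(matrix(0, 24, 24)))
  expect_equal(empty[["DE"]], 0)
  expect_equal(empty[["DS"]], 0)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.8
  dd2 <- degree_density(adj_graph(star))
  expect_equal(dd2[["DE"]], (4 * 0.8 + 4 * 0.8) / 5)   # 1.28
  expect_equal(dd2[["DS"]], 4 / 10)
})

test_that("clustering matches triangle enumeration", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coef(adj_graph(tri)), 1)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(clustering_coef(adj_graph(path)), 0)

  clique <- matrix(1, 4, 4); diag(clique) <- 0
  clique[3, 4] <- clique[4, 3] <- 0.5
  expect_equal(clustering_coef(adj_graph(clique)),
               oracle_graph_metrics(clique)$CC, tolerance = 1e-12)
})

test_that("characteristic path length uses 1/weight distances over connected pairs", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(char_path_length(adj_graph(path)), 4 / 3)

  comp <- matrix(1, 5, 5); diag(comp) <- 0
  expect_equal(char_path_length(adj_graph(comp)), 1)

  # disconnected pairs are excluded
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 0.5
  expect_equal(char_path_length(adj_graph(two)), 2)    # 1/0.5 both pairs

  expect_warning(v <- char_path_length(adj_graph(matrix(0, 3, 3))),
                 "edgeless")
  expect_true(is.na(v))
})

test_that("all four scalar metrics match the brute-force oracle on random graphs", {
  set.seed(18)
  for (rep in 1:20) {
    n <- sample(5:24, 1)
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    on <- sample(up, max(1, round(0.25 * length(up))))
    adj[on] <- runif(length(on), 0.65, 1)
    adj <- adj + t(adj)
    g <- adj_graph(adj)
    o <- oracle_graph_metrics(adj)
    dd <- degree_density(g)
    expect_equal(dd[["DE"]], o$DE, tolerance = 1e-10)
    expect_equal(dd[["DS"]], o$DS, tolerance = 1e-10)
    expect_equal(clustering_coef(g), o$CC, tolerance = 1e-10)
    expect_equal(char_path_length(g), o$CPL, tolerance = 1e-10)
  }
})

test_that("modularity finds planted structure", {
  # two disconnected unit triangles: Q = 0.5 with 2 modules
  two_tri <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    two_tri[p[1], p[2]] <- two_tri[p[2], p[1]] <- 1
  }
  mp <- modularity_partition(adj_graph(two_tri), seed = 1)
  expect_equal(mp$M, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mp$modules)), 2)

  # edgeless: M undefined, singleton modules
  mp0 <- modularity_partition(adj_graph(matrix(0, 5, 5)))
  expect_true(is.na(mp0$M))
  expect_equal(length(unique(mp0$modules)), 5)

  # planted 6-module graph (within 0.9, between 0) is recovered exactly
  blocks <- rep(1:6, each = 4)
  adj <- outer(blocks, blocks, "==") * 0.9
  diag(adj) <- 0
  mp6 <- modularity_partition(adj_graph(adj), seed = 2)
  expect_equal(length(unique(mp6$modules)), 6)
  expect_equal(unname(vapply(split(mp6$modules, blocks),
                             function(m) length(unique(m)), 1L)),
               rep(1L, 6))
})

test_that("metric rows over time follow the PLV tensor", {
  fake_tensor <- function(vals) {
    structure(list(values = vals,
                   window_centers = seq(-1.5, 3, by = 0.1),
                   window_s = 1, step_s = 0.1, averaged = TRUE,
                   roi = grasp_rois()),
              class = "plv_tensor")
  }
  ones <- array(1, c(46, 24, 24))
  rows <- metrics_timecourse(fake_tensor(ones), "palmar")
  expect_equal(nrow(rows), 3)
  expect_true(all(rows$DS == 1))
  expect_true(all(rows$condition == "palmar"))

  # within-module coupling strengthening over time: CC rises, CPL falls
  # (a fixed unit-weight reference edge anchors the Onnela normalisation)
  blocks <- rep(1:6, each = 4)
  base <- outer(blocks, blocks, "==")
  vals <- array(0.2, c(46, 24, 24))
  for (w in 1:46) {
    grow <- 0.68 + 0.25 * (w - 1) / 45
    m <- matrix(0.2, 24, 24)
    m[base] <- grow
    m[1, 2] <- m[2, 1] <- 1
    diag(m) <- 1
    vals[w, , ] <- m
  }
  rows2 <- metrics_timecourse(fake_tensor(vals), "palmar",
                              times = c(-1, 0, 1.4))
  expect_true(all(diff(rows2$CC) > 0))
  expect_true(all(diff(rows2$CPL) < 0))

  expect_error(metrics_timecourse(fake_tensor(ones), times = 99),
               "coverage")
})
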