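test_that("cosine similarities follow the definition", {
  F <- make_feature_matrix(rbind(c(1, 0, 1), c(1, 1, 0), c(1, 0, 1),
                                 c(0, 1, 0), c(1, 0, 0)))
  S <- cosine_similarity_matrix(F)$values
  expect_equal(S[1, 2], 0.5)               # direct evaluation of the formula
  expect_equal(S[1, 3], 1)                 # identical rows
  expect_equal(S[4, 5], 0)                 # orthogonal rows
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 5))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("cosine matrix errors on a zero-norm row, naming the respondent", {
  F <- make_feature_matrix(rbind(c(1, 0), c(0, 0)), ids = c("ok", "empty"))
  expect_error(cosine_similarity_matrix(F), "zero-norm.*empty")
})

test_that("cosine is invariant to positive row rescaling", {
  set.seed(5)
  V <- matrix(runif(30), 6, 5)
  S1 <- cosine_similarity_matrix(make_feature_matrix(V))$values
  V2 <- V * runif(6, 0.1, 10)   # scale each row
  S2 <- cosine_similarity_matrix(make_feature_matrix(V2))$values
  expect_equal(S1, S2, tolerance = 1e-12)
})

test_that("one-hot-only similarity equals shared-level matching", {
  # with one-hot features, S_ij = (# shared active levels) / sqrt(k_i k_j)
  set.seed(9)
  n <- 12; vars <- 4; L <- 3
  blocks <- lapply(1:vars, function(v) {
    lev <- sample(L, n, replace = TRUE)
    m <- matrix(0, n, L); m[cbind(1:n, lev)] <- 1; m
  })
  V <- do.call(cbind, blocks)
  S <- cosine_similarity_matrix(make_feature_matrix(V))$values
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    shared <- sum(V[i, ] * V[j, ])
    expect_equal(S[i, j], shared / sqrt(sum(V[i, ]) * sum(V[j, ])))
  }
})

test_that("thresholding includes ties and spans the trivial extremes", {
  set.seed(13)
  V <- matrix(runif(40, 0.1, 1), 8, 5)
  sim <- cosine_similarity_matrix(make_feature_matrix(V))
  n <- 8
  g0 <- threshold_network(sim, 0)
  expect_equal(nrow(g0$edges), n * (n - 1) / 2)  # complete graph
  tmax <- max(sim$values[upper.tri(sim$values)])
  gempty <- threshold_network(sim, min(1, tmax + 1e-9))
  expect_equal(nrow(gempty$edges), 0)
  expect_equal(gempty$n, n)                      # isolated nodes retained
  # edge count at t equals the brute-force count of entries >= t
  for (t in c(0.7799, quantile(sim$values[upper.tri(sim$values)], 0.5))) {
    g <- threshold_network(sim, t)
    expect_equal(nrow(g$edges), sum(sim$values[upper.tri(sim$values)] >= t))
  }
  # ties at t are all included
  S <- matrix(0.6, 4, 4); diag(S) <- 1
  simt <- structure(list(values = S, ids = letters[1:4]),
                    class = "similarity_matrix")
  expect_equal(nrow(threshold_network(simt, 0.6)$edges), 6)
  expect_error(threshold_network(sim, 1.5), "\\[0, 1\\]")
})

test_that("threshold calibration hits the target average degree", {
  set.seed(77)
  V <- matrix(runif(300), 30, 10)
  sim <- cosine_similarity_matrix(make_feature_matrix(V))
  n <- 30
  s_off <- sim$values[upper.tri(sim$values)]
  expect_equal(length(unique(s_off)), length(s_off))  # all distinct
  for (target in c(2, 5.5, 11, 20)) {
    t_hat <- calibrate_threshold(sim, target)
    deg <- 2 * sum(s_off >= t_hat) / n
    expect_gte(deg, target - 1e-12)
    expect_lte(deg, target + 2 / n)
    # sort-and-scan oracle: t_hat is the largest candidate meeting the target
    cand <- sort(s_off, decreasing = TRUE)
    expect_equal(t_hat, max(cand[2 * seq_along(cand) / n >= target]))
  }
  # saturation: target N-1 admits every pair
  t_full <- calibrate_threshold(sim, n - 1)
  expect_lte(t_full, min(s_off))
  expect_equal(nrow(threshold_network(sim, t_full)$edges), n * (n - 1) / 2)
  expect_error(calibrate_threshold(sim, 0), "target_avg_degree")
  expect_error(calibrate_threshold(sim, n), "target_avg_degree")
})

test_that("average degree is nonincreasing in the threshold (property)", {
  set.seed(21)
  for (rep_i in 1:5) {
    V <- matrix(runif(120, 0, 1), 12, 10)
    sim <- cosine_similarity_matrix(make_feature_matrix(V))
    degs <- vapply(seq(0, 1, by = 0.05), function(t)
      network_summary(threshold_network(sim, t))$avg_degree, 0)
    expect_true(all(diff(degs) <= 1e-12))
  }
})

test_that("network summaries and TSV round-trips are exact", {
  # K4: density 1
  k4 <- make_network(rep(c("low", "high"), 2),
                     t(combn(4, 2)))
  expect_equal(network_summary(k4)$density, 1)
  expect_equal(network_summary(make_network(rep("low", 5)))$density, 0)
  # Erdos-Renyi fixture: density matches the edge count by formula
  g <- simulate_network(c(-1, 0, 0), rep(c("low", "high"), 25), seed = 3)
  s <- network_summary(g)
  expect_equal(s$density, 2 * s$n_edges / (50 * 49))
  expect_equal(s$avg_degree, 2 * s$n_edges / 50)
  expect_equal(as.integer(s$status_counts), c(25L, 25L))
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, ep, np)
  g2 <- read_network(ep, np)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$status, g$status)
})
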