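test_that("change statistics follow the endpoint-pattern rules", {
  spec <- ergm_spec()
  lev <- c("low", "high")
  expect_equal(unname(change_statistics("low", "low", spec, lev)), c(1, 0, 1))
  expect_equal(unname(change_statistics("low", "high", spec, lev)), c(1, 1, 0))
  expect_equal(unname(change_statistics("high", "high", spec, lev)), c(1, 2, 1))
  expect_named(change_statistics("high", "high", spec, lev),
               c("edges", "nodefactor.burnout.high", "nodematch.burnout"))
})

test_that("sufficient statistics count configurations correctly", {
  spec <- ergm_spec()
  empty <- make_network(c("low", "high", "low"))
  expect_equal(unname(sufficient_statistics(empty, spec)), c(0, 0, 0))
  # triangle on (high, high, low): edges 3, high endpoints 4, one match
  tri <- make_network(c("high", "high", "low"), rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(unname(sufficient_statistics(tri, spec)), c(3, 4, 1))
})

test_that("statistics equal the sum of change statistics over edges", {
  spec <- ergm_spec()
  set.seed(15)
  for (rep_i in 1:10) {
    n <- sample(5:12, 1)
    status <- sample(c("low", "high"), n, replace = TRUE, prob = c(0.6, 0.4))
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    g <- make_network(status, pairs[keep, , drop = FALSE])
    lev <- sort(unique(status)); if (all(c("low","high") %in% lev)) lev <- c("low","high")
    brute <- Reduce(`+`, c(list(rep(0, 3)), lapply(which(keep), function(r)
      change_statistics(status[pairs[r, 1]], status[pairs[r, 2]], spec, lev))))
    if (length(unique(status)) == 2)
      expect_equal(unname(sufficient_statistics(g, spec)), unname(brute))
  }
})

test_that("edges-only exact fit recovers logit(density)", {
  g <- simulate_network(c(-2, 0, 0), rep(c("low", "high"), 30), seed = 2)
  fit <- fit_exact(g, ergm_spec("edges"))
  d <- network_summary(g)$density
  expect_equal(unname(fit$coefficients), qlogis(d), tolerance = 1e-10)
  expect_equal(fit$dyads, 60 * 59 / 2)
})

test_that("three-term exact fit equals the closed-form density solution", {
  status <- rep(c("low", "high"), c(40, 25))
  g <- simulate_network(c(-1.2, -0.3, 0.6), status, seed = 8)
  fit <- fit_exact(g)
  # saturated three-pattern model: logit within/between densities
  nl <- 40; nh <- 25
  e <- g$edges; si <- status[e[, 1]]; sj <- status[e[, 2]]
  yLL <- sum(si == "low" & sj == "low")
  yHH <- sum(si == "high" & sj == "high")
  yLH <- nrow(e) - yLL - yHH
  lLL <- qlogis(yLL / (nl * (nl - 1) / 2))
  lLH <- qlogis(yLH / (nl * nh))
  lHH <- qlogis(yHH / (nh * (nh - 1) / 2))
  # rows: (theta1 + theta3, theta1 + theta2, theta1 + 2 theta2 + theta3)
  A <- rbind(c(1, 0, 1), c(1, 1, 0), c(1, 2, 1))
  theta_closed <- solve(A, c(lLL, lLH, lHH))
  expect_lt(max(abs(unname(fit$coefficients) - theta_closed)), 1e-8)
})

test_that("collapsed-pattern fit equals a brute-force all-dyad logistic fit", {
  status <- rep(c("low", "high"), c(35, 25))
  g <- simulate_network(c(-1, -0.2, 0.4), status, seed = 5)
  fit <- fit_exact(g)
  # expand every dyad and fit with glm as an independent oracle
  n <- 60
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  y <- logical(length(i))
  y[(g$edges[, 1] - 1) * n - g$edges[, 1] * (g$edges[, 1] - 1) / 2 +
      (g$edges[, 2] - g$edges[, 1])] <- TRUE
  nf <- (status[i] == "high") + (status[j] == "high")
  nm <- as.numeric(status[i] == status[j])
  oracle <- glm(y ~ nf + nm, family = binomial())
  expect_lt(max(abs(unname(fit$coefficients) - unname(coef(oracle)))), 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(oracle)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-8)
})

test_that("the fitted likelihood is a local maximum", {
  status <- rep(c("low", "high"), c(30, 20))
  g <- simulate_network(c(-1, 0.2, 0.3), status, seed = 6)
  fit <- fit_exact(g)
  des <- burnoutnet:::dyad_pattern_design(g, ergm_spec())
  ll <- function(th) {
    eta <- drop(des$X %*% th)
    sum(des$y * eta - des$m * log1p(exp(eta)))
  }
  set.seed(30)
  for (k in 1:20) {
    pert <- fit$coefficients + rnorm(3, 0, 0.2)
    expect_lte(ll(pert), ll(fit$coefficients) + 1e-10)
  }
})

test_that("AIC/BIC satisfy their defining identities", {
  status <- rep(c("low", "high"), c(30, 20))
  g <- simulate_network(c(-1, 0, 0.3), status, seed = 9)
  for (spec in list(ergm_spec("edges"), ergm_spec())) {
    fit <- fit_exact(g, spec)
    k <- length(fit$coefficients)
    expect_equal(fit$aic, 2 * k - 2 * fit$loglik)
    expect_equal(fit$bic, k * log(fit$dyads) - 2 * fit$loglik)
    expect_equal(fit$bic - fit$aic, k * (log(fit$dyads) - 2))
    expect_equal(unname(fit$z), unname(fit$coefficients / fit$se))
  }
})

test_that("separation is reported as non-convergence, not silence", {
  # no high-high edges at all: the saturated pattern model separates
  status <- rep(c("low", "high"), c(10, 5))
  pairs <- t(combn(15, 2))
  ll_pairs <- pairs[status[pairs[, 1]] == "low" & status[pairs[, 2]] == "low", ]
  g <- make_network(status, ll_pairs[1:20, ])
  expect_warning(fit <- fit_exact(g), "did not converge")
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|non-converged")
})

test_that("the dyad-independent simulator matches its Bernoulli law", {
  status <- rep(c("low", "high"), 40)
  g_empty <- simulate_network(c(-50, 0, 0), status, seed = 1)
  expect_equal(nrow(g_empty$edges), 0)
  g_half <- simulate_network(c(0, 0, 0), status, seed = 2)
  D <- 80 * 79 / 2
  expect_lt(abs(nrow(g_half$edges) - D / 2), 3 * sqrt(D) / 2)
  expect_identical(simulate_network(c(-1, 0.1, 0.2), status, seed = 4)$edges,
                   simulate_network(c(-1, 0.1, 0.2), status, seed = 4)$edges)
})

test_that("nodematch sign is recovered under generated homophily", {
  status <- rep(c("low", "high"), 250)
  for (th3 in c(0.5, -0.5)) {
    signs <- vapply(1:20, function(s) {
      g <- simulate_network(c(-3, -0.1, th3), status, seed = 1000 + s)
      sign(fit_exact(g)$coefficients[["nodematch.burnout"]])
    }, 0)
    expect_gte(mean(signs == sign(th3)), 0.95)
  }
})

test_that("model comparison reports AIC/BIC selection with flags", {
  status <- rep(c("low", "high"), 100)
  # homophilous network: node-attribute model wins
  g <- simulate_network(c(-2.5, -0.1, 0.9), status, seed = 3)
  f0 <- fit_exact(g, ergm_spec("edges"))
  f1 <- fit_exact(g)
  cmp <- compare_models(f0, f1)
  expect_equal(cmp$selected, "node_attribute")
  expect_false(cmp$tie)
  # identical fits tie
  cmp_tie <- compare_models(f0, f0)
  expect_true(cmp_tie$tie)
  # pure Erdos-Renyi: BIC selects the zero model in most replicates
  zero_by_bic <- vapply(1:12, function(s) {
    ger <- simulate_network(c(-2.5, 0, 0), status, seed = 100 + s)
    compare_models(fit_exact(ger, ergm_spec("edges")),
                   fit_exact(ger))$selected_bic == "zero"
  }, TRUE)
  expect_gt(mean(zero_by_bic), 0.5)
  # different networks are rejected
  g2 <- simulate_network(c(-2.5, -0.1, 0.9), status, seed = 4)
  expect_error(compare_models(f0, fit_exact(g2)), "different networks")
})

test_that("predicted edge probabilities follow the logistic form", {
  status <- rep(c("low", "high"), 60)
  g <- simulate_network(c(-2, -0.2, 0.4), status, seed = 7)
  fit <- fit_exact(g)
  th <- fit$coefficients
  expect_equal(predicted_edge_probability(fit, "low", "low"),
               plogis(th[[1]] + th[[3]]))
  expect_equal(predicted_edge_probability(fit, "low", "high"),
               plogis(th[[1]] + th[[2]]))
  expect_equal(predicted_edge_probability(fit, "high", "high"),
               plogis(th[[1]] + 2 * th[[2]] + th[[3]]))
  # p(high,high) > p(low,high) iff theta2 + theta3 > 0
  expect_equal(predicted_edge_probability(fit, "high", "high") >
                 predicted_edge_probability(fit, "low", "high"),
               th[[2]] + th[[3]] > 0)
})

test_that("ergm fit export writes JSON and a report-style table", {
  status <- rep(c("low", "high"), 30)
  g <- simulate_network(c(-1.5, -0.1, 0.3), status, seed = 19)
  fit <- fit_exact(g)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".txt")
  write_ergm_fit(fit, jp, tp)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(parsed$coefficients$edges, fit$coefficients[["edges"]])
  expect_true(any(grepl("Std. Error", readLines(tp), fixed = TRUE)))
})
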