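test_that("chi-squared test reproduces the published cohort p-values", {
  # printed two-digit p-values recomputable from the reference counts
  expect_equal(round(chi_squared_test(cohort_contingency("high_blood_pressure"))$p_value, 2), 0.09)
  expect_equal(round(chi_squared_test(cohort_contingency("overweight"))$p_value, 2), 0.07)
  expect_equal(round(chi_squared_test(cohort_contingency("sex"))$p_value, 2), 0.11)
  expect_equal(round(chi_squared_test(cohort_contingency("smoking"))$p_value, 2), 0.08)
  expect_equal(round(suppressWarnings(
    chi_squared_test(cohort_contingency("marital_status")))$p_value, 2), 0.01)
  expect_lt(chi_squared_test(cohort_contingency("cardiovascular"))$p_value, 0.01)
})

test_that("chi-squared statistic is zero under exact independence", {
  res <- chi_squared_test(rbind(c(10, 10), c(20, 20)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)
})

test_that("chi-squared p agrees with a fixed-margin permutation oracle", {
  m <- rbind(c(858, 143), c(4208, 585))  # overweight yes/no x low/high
  obs <- chisq_stat(m)
  B <- 20000
  set.seed(1234)
  sims <- r2dtable(B, rowSums(m), colSums(m))
  stats <- vapply(sims, chisq_stat, 0)
  p_mc <- mean(stats >= obs - 1e-9)
  p_asym <- chi_squared_test(m)$p_value
  mc_se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(p_asym - p_mc), 3 * mc_se + 1e-3)
})

test_that("chi-squared validates margins and table shape", {
  expect_error(chi_squared_test(matrix(c(1, 2), 1, 2)), "2 x 2")
  m <- rbind(A = c(0, 0), B = c(5, 3))
  expect_error(chi_squared_test(m), "empty level.*A")
  m2 <- cbind(low = c(3, 5), high = c(0, 0))
  expect_error(chi_squared_test(m2), "empty group.*high")
  expect_warning(chi_squared_test(rbind(c(2, 1), c(50, 60)), variable = "rare"),
                 "below 5.*rare")
})

test_that("chi-squared test is invariant to row and column permutation", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(8, 30) + 1, 4, 2)
    base <- chi_squared_test(m)
    perm <- chi_squared_test(m[sample(4), sample(2)])
    expect_equal(perm$statistic, base$statistic)
    expect_equal(perm$p_value, base$p_value)
    expect_gte(base$statistic, 0)
    expect_true(base$p_value >= 0 && base$p_value <= 1)
  }
})

test_that("wilcoxon rank-sum handles the symmetric null and tiny samples", {
  x <- c(1, 2, 2, 3, 5)
  res <- wilcoxon_rank_sum(x, x)
  expect_equal(res$p_value, 1, tolerance = 1e-8)
  expect_error(wilcoxon_rank_sum(numeric(), x), "nonempty")

  # exact enumeration oracle over all C(6,3) group assignments
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  pooled <- c(x, y)
  assignments <- combn(6, 3)
  u_all <- apply(assignments, 2, function(ix)
    sum(rank(pooled)[ix]) - 3 * 4 / 2)
  u_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  expect_equal(u_obs, min(u_all))  # the extreme rank-sum
  p_exact <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  res <- wilcoxon_rank_sum(x, y, exact = TRUE)
  expect_equal(res$statistic, u_obs, ignore_attr = TRUE)
  expect_equal(res$p_value, p_exact)
})

test_that("wilcoxon normal approximation holds its type-I error rate", {
  set.seed(2024)
  rej <- vapply(1:1000, function(i) {
    x <- rnorm(200); y <- rnorm(200)
    wilcoxon_rank_sum(x, y)$p_value < 0.05
  }, TRUE)
  ci_half <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), ci_half)
})

test_that("the screen selects by p < alpha, grouped by category", {
  sch <- make_tiny_schema()
  tab <- generate_survey(sch, simulation_config(400, seed = 31))
  scr1 <- suppressWarnings(screen_variables(tab, sch, alpha = 1.0))
  expect_setequal(unlist(scr1$selected), names(sch$variables))
  expect_named(scr1$selected,
               c("demographic", "work_related", "health", "lifestyle"))
  # schema ordering is preserved in the results
  expect_equal(scr1$results$variable, names(sch$variables))
  expect_error(screen_variables(tab[, -6], sch), "burnout")
})

test_that("a strongly shifted variable is always selected", {
  sch <- make_tiny_schema()
  for (s in 1:10) {
    cfg <- simulation_config(500, burnout_prevalence = 0.3,
                             effect_sizes = list(disease = c(2.5, -1)),
                             seed = s)
    tab <- generate_survey(sch, cfg)
    scr <- suppressWarnings(screen_variables(tab, sch, alpha = 0.05))
    expect_true("disease" %in% scr$selected$health)
  }
})

test_that("the cohort report mirrors the descriptive-table layout", {
  sch <- make_tiny_schema()
  tab <- generate_survey(sch, simulation_config(500, seed = 12))
  rep <- suppressWarnings(table1_report(tab, sch))
  # one row per level of each categorical variable, one per numeric
  expect_equal(nrow(rep), 1 + 3 + 2 + 4)
  # within-group percentages sum to 100 up to rounding, per variable
  for (v in c("grade", "disease", "diet")) {
    rows <- rep[rep$variable == v, ]
    for (col in c("overall", "low", "high")) {
      pct <- as.numeric(sub(".*\\(([0-9.]+)\\)", "\\1", rows[[col]]))
      expect_lt(abs(sum(pct) - 100), 0.5)
    }
  }
  # median/IQR matches direct order statistics
  q <- quantile(tab$age, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(rep$overall[rep$variable == "Age (years)" | rep$variable == "age"],
               sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3]))
  # writers emit both formats
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".md")
  write_report(rep, p1, "tsv")
  write_report(rep, p2, "markdown")
  expect_gt(length(readLines(p1)), 1)
  expect_true(any(grepl("^\\|", readLines(p2))))
})
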