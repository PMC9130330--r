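test_that("cross-validation folds partition the indices with balanced sizes", {
  f <- kfold_indices(100, 10, seed = 1)
  expect_equal(sort(unlist(f)), 1:100)
  expect_true(all(lengths(f) == 10L))

  f2 <- kfold_indices(95, 10, seed = 2)
  expect_equal(sort(unlist(f2)), 1:95)
  expect_equal(sort(lengths(f2)), c(rep(9L, 5), rep(10L, 5)))

  labels <- rep(c("+", "-"), c(20, 80))
  f3 <- kfold_indices(100, 10, seed = 3, stratified = TRUE,
                      labels = labels)
  expect_equal(sort(unlist(f3)), 1:100)
  per_fold_minority <- vapply(f3, function(ix) sum(labels[ix] == "+"), 0L)
  expect_true(all(per_fold_minority == 2L))
  expect_true(all(lengths(f3) == 10L))

  # ragged stratification still differs by at most one per fold
  labels4 <- rep(c("+", "-"), c(23, 72))
  f4 <- kfold_indices(95, 10, seed = 4, stratified = TRUE,
                      labels = labels4)
  pm <- vapply(f4, function(ix) sum(labels4[ix] == "+"), 0L)
  expect_lte(diff(range(pm)), 1L)
  expect_lte(diff(range(lengths(f4))), 1L)

  expect_error(kfold_indices(5, 10), "exceeds")
})

test_that("the CV harness scores the untouched validation fold and is seed-deterministic", {
  prob <- make_gt_problem(m_plus = 20L, m_minus = 80L, seed = 41L,
                          n_features = 3L)
  always_majority <- list(
    name = "maj",
    fit = function(table) NULL,
    predict = function(model, table) rep("-", nrow(table)))
  cfg <- eval_config(k = 5, runs = 2, seed = 99)
  sc <- run_cv_experiment(prob$table, list(none = oversampler_none()),
                          list(always_majority), cost_spec(gamma = 5),
                          cfg)
  # accuracy of the constant-majority classifier = fold majority rate,
  # recomputed here from the fold indices
  labels <- as.character(prob$table$class)
  for (r in unique(sc$run)) {
    run_seed <- bosme:::derive_seed(cfg$seed, r)
    folds <- kfold_indices(nrow(prob$table), cfg$k, seed = run_seed,
                           stratified = TRUE, labels = labels)
    for (f in unique(sc$fold)) {
      expected_acc <- mean(labels[folds[[f]]] == "-")
      expect_equal(sc$accuracy[sc$run == r & sc$fold == f], expected_acc)
    }
  }
  # expected cost of all-majority = p_plus_fold * c_plus
  expect_equal(sc$expected_cost,
               (1 - sc$accuracy) * 5, tolerance = 1e-12)

  sc2 <- run_cv_experiment(prob$table, list(none = oversampler_none()),
                           list(always_majority), cost_spec(gamma = 5),
                           cfg)
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
  # shape contract: k rows per (run, method, classifier)
  expect_equal(nrow(sc), cfg$runs * cfg$k)
})

test_that("the paired comparison gates on normality and handles degenerate differences", {
  x <- c(0.8, 0.81, 0.83, 0.85, 0.9, 0.7, 0.75, 0.82, 0.88, 0.84)
  expect_false(paired_compare(x, x)$significant)
  expect_equal(paired_compare(x, x)$direction, "none")

  v <- paired_compare(x + 0.05, x)
  expect_equal(v$test_used, "degenerate")
  expect_true(v$significant)
  expect_equal(v$direction, "first")

  # a clearly normal difference sample takes the t branch; its p-value
  # matches the closed-form paired t computation
  set.seed(8)
  d <- rnorm(10, mean = 0.5, sd = 0.1)
  y <- runif(10)
  v2 <- paired_compare(y + d, y)
  expect_equal(v2$test_used, "paired_t")
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(v2$test_p, 2 * pt(-abs(tstat), 9), tolerance = 1e-9)
  expect_true(v2$significant)
  expect_equal(v2$direction, "first")

  # a heavy-tailed difference fails the normality gate -> Wilcoxon
  d3 <- c(0.001, 0.002, 0.001, 0.003, 0.002, 0.001, 0.002, 0.9, 0.001,
          0.002)
  v3 <- paired_compare(y + d3, y)
  expect_equal(v3$test_used, "wilcoxon")
  expect_lt(v3$normality_p, 0.05)
})

test_that("run counters tally significant verdicts per direction", {
  # synthetic fold scores: method A beats B by a constant in runs 1-3,
  # loses in run 4, ties in run 5
  rows <- list()
  for (r in 1:5) {
    base <- seq(0.5, 0.95, length.out = 10)
    shift <- c(0.05, 0.05, 0.05, -0.05, 0)[r]
    for (f in 1:10) {
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f, method = "A", classifier = "clf",
        accuracy = base[f] + shift, expected_cost = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f, method = "B", classifier = "clf",
        accuracy = base[f], expected_cost = 0)
    }
  }
  sc <- do.call(rbind, rows)
  led <- count_run_verdicts(sc, "A", "B", "clf", metric = "accuracy")
  expect_equal(led$counter_plus, 3L)
  expect_equal(led$counter_minus, 1L)
  expect_lte(led$counter_plus + led$counter_minus, led$runs)
})

test_that("exact binomial point probabilities are exact and normalize", {
  expect_identical(binomial_point_p(9, 0), 0.001953125)
  expect_identical(binomial_point_p(8, 1), 0.017578125)
  expect_identical(binomial_point_p(1, 0), 0.5)
  for (n in c(1, 5, 9, 10, 17)) {
    total <- sum(vapply(0:n, function(k) binomial_point_p(k, n - k), 0))
    expect_equal(total, 1, tolerance = 1e-15)
  }
  expect_error(binomial_point_p(0, 0), "zero")
})

test_that("the beta score sums signed cell verdicts", {
  expect_identical(beta_score(rep(1L, 36)), 36L)
  expect_identical(beta_score(integer(0)), 0L)
  expect_identical(beta_score(c(rep(1L, 5), rep(-1L, 2), rep(0L, 29))), 3L)
  expect_error(beta_score(c(2L, 0L)))
})

test_that("Mann-Kendall statistics match exhaustive pair enumeration", {
  inc <- c(1, 3, 4, 7, 9, 12)
  mk <- mann_kendall_trend(inc)
  expect_equal(mk$S, 15)                 # n(n-1)/2
  expect_equal(mk$tau, 1)
  expect_lt(mk$p_two_sided, 0.05)

  const <- rep(2, 6)
  mk0 <- mann_kendall_trend(const)
  expect_equal(mk0$S, 0)
  expect_equal(mk0$p_two_sided, 1)
  expect_equal(mk0$sen_slope, 0)

  series <- c(8, 13, 12, 14, 15, 16, 16, 16, 16, 17)
  mk2 <- mann_kendall_trend(series)
  # independent brute-force enumeration of all pairs
  S <- 0; n <- length(series)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    S <- S + sign(series[j] - series[i])
  expect_equal(mk2$S, S)
  expect_equal(S, 37)
  expect_equal(mk2$tau, 37 / sqrt(45 * 39), tolerance = 1e-9)
  expect_true(mk2$sen_ci[1] <= mk2$sen_slope &&
                mk2$sen_slope <= mk2$sen_ci[2])
  # median pairwise slope recomputed directly
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    slopes <- c(slopes, (series[j] - series[i]) / (j - i))
  expect_equal(mk2$sen_slope, median(slopes))
})

test_that("Spearman trend matches the exact rank formula and reference values", {
  series <- c(8, 13, 12, 14, 15, 16, 16, 16, 16, 17)
  sp <- spearman_trend(series)
  expect_equal(sp$rho, 0.95672, tolerance = 5e-6)
  expect_equal(round(sp$rho_p_one_sided, 6), 0.000007, tolerance = 5e-7)

  expect_equal(spearman_trend(c(9, 7, 5, 4, 2))$rho, -1)

  # tie-free series: the classical 1 - 6 sum(d^2) / (n (n^2-1)) formula
  set.seed(6)
  y <- sample(1:50, 12)
  d <- rank(y) - seq_along(y)
  rho_exact <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
  expect_equal(spearman_trend(y)$rho, rho_exact, tolerance = 1e-12)
})
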