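#' Evaluation configuration
#'
#' @param k Fold count for cross-validation.
#' @param runs Number of repeated runs with different fold splits.
#' @param alpha Significance level for the paired tests.
#' @param gamma_grid Cost ratios to sweep.
#' @param stratified Stratify folds by class? Default on: with a rare
#'   minority, unstratified folds can strand every minority row in one
#'   fold, making training-fold over-sampling impossible. Setting it to
#'   `FALSE` restores a plain random split.
#' @param seed Master seed; run/fold/over-sampler seeds are derived from it
#'   by a fixed splitting rule and recorded in the result.
#' @return A list of class `"eval_config"`.
#' @export
eval_config <- function(k = 10L, runs = 10L, alpha = 0.05,
                        gamma_grid = seq(5, 50, by = 5),
                        stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2L, runs >= 1L, alpha > 0, alpha < 1,
            all(gamma_grid > 1))
  structure(list(k = as.integer(k), runs = as.integer(runs), alpha = alpha,
                 gamma_grid = gamma_grid, stratified = stratified,
                 seed = as.integer(seed)),
            class = "eval_config")
}

# fixed seed-splitting rule: everything derives from the master seed and
# stays below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + p * 104729 + 12345) %% 2147483647
  as.integer(s)
}

#' Disjoint cross-validation folds
#'
#' Partitions `1:n_rows` into `k` folds whose sizes differ by at most one.
#' With `stratified = TRUE`, each class's indices are dealt cyclically so
#' per-fold minority counts also differ by at most one.
#'
#' @param n_rows Number of rows.
#' @param k Fold count.
#' @param seed Integer seed.
#' @param stratified Stratify by `labels`?
#' @param labels Class labels, required when stratifying.
#' @return List of `k` integer index vectors.
#' @export
kfold_indices <- function(n_rows, k, seed = 1L, stratified = FALSE,
                          labels = NULL) {
  if (k > n_rows) stop("k = ", k, " exceeds the number of rows ", n_rows)
  if (stratified && is.null(labels))
    stop("stratified folds need the label vector")
  set.seed(seed)
  folds <- vector("list", k)
  if (!stratified) {
    idx <- sample.int(n_rows)
    sizes <- rep(n_rows %/% k, k)
    extra <- n_rows %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    start <- cumsum(c(1L, sizes[-k]))
    for (f in seq_len(k))
      folds[[f]] <- sort(idx[seq(start[f], length.out = sizes[f])])
  } else {
    labels <- as.character(labels)
    offset <- 0L
    for (cl in sort(unique(labels))) {
      rows <- which(labels == cl)
      rows <- rows[sample.int(length(rows))]
      assign_to <- ((seq_along(rows) - 1L + offset) %% k) + 1L
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], rows[assign_to == f])
      offset <- (offset + length(rows)) %% k
    }
    folds <- lapply(folds, sort)
  }
  folds
}

#' Repeated cross-validated comparison of over-samplers
#'
#' The first experimental stage: for each run, the data set is split into
#' `k` folds; for each fold, each over-sampler is applied to the training
#' portion only — with target proportion `q` derived from the costs and
#' the training fold's own class balance — each classifier is fitted on
#' the enlarged training data, and accuracy and expected cost are measured
#' on the untouched validation fold.
#'
#' @param table A binary-class [dataset_table()] with minority label `"+"`.
#' @param oversamplers Named list of functions
#'   `function(table, costs, seed)` returning an enlarged `dataset_table`
#'   (use `oversampler_none()`, `oversampler_bosme()`,
#'   `oversampler_smote()`).
#' @param classifiers List of classifier adapters (see [classifiers]).
#' @param costs A [cost_spec()].
#' @param config An [eval_config()].
#' @return A data frame of class `"fold_scores"`: one row per
#'   (run, fold, method, classifier) with `accuracy` and `expected_cost`,
#'   plus a seed ledger in the `"seeds"` attribute.
#' @export
run_cv_experiment <- function(table, oversamplers, classifiers, costs,
                              config = eval_config()) {
  cn <- attr(table, "class_name")
  labels <- as.character(table[[cn]])
  rows <- list()
  seeds <- list()
  for (run in seq_len(config$runs)) {
    run_seed <- derive_seed(config$seed, run)
    folds <- kfold_indices(nrow(table), config$k, seed = run_seed,
                           stratified = config$stratified, labels = labels)
    for (f in seq_len(config$k)) {
      val_idx <- folds[[f]]
      tr_idx <- setdiff(seq_len(nrow(table)), val_idx)
      train <- table[tr_idx, , drop = FALSE]
      val <- table[val_idx, , drop = FALSE]
      if (sum(as.character(train[[cn]]) == "+") < 2L) {
        warning("run ", run, " fold ", f,
                ": training fold has < 2 minority rows; skipped")
        next
      }
      for (mname in names(oversamplers)) {
        os_seed <- derive_seed(config$seed, run, f, match(mname,
                                                          names(oversamplers)))
        seeds[[length(seeds) + 1L]] <-
          list(run = run, fold = f, method = mname, run_seed = run_seed,
               oversampler_seed = os_seed)
        enlarged <- oversamplers[[mname]](train, costs, os_seed)
        for (clf in classifiers) {
          model <- clf$fit(enlarged)
          pred <- clf$predict(model, val)
          truth <- as.character(val[[cn]])
          conf <- confusion_counts(truth, pred)
          rows[[length(rows) + 1L]] <- data.frame(
            run = run, fold = f, method = mname, classifier = clf$name,
            accuracy = mean(pred == truth),
            expected_cost = expected_cost(conf, costs),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- seeds
  class(out) <- c("fold_scores", "data.frame")
  out
}

#' @rdname run_cv_experiment
#' @export
oversampler_none <- function() function(table, costs, seed) table

#' @rdname run_cv_experiment
#' @param control A [bn_control()] passed to the structure search.
#' @export
oversampler_bosme <- function(control = bn_control()) {
  function(table, costs, seed)
    bosme(table, costs = costs, control = control, seed = seed)$data
}

#' @rdname run_cv_experiment
#' @param k Neighbour count for the SMOTE baseline.
#' @export
oversampler_smote <- function(k = 5) {
  function(table, costs, seed) smote(table, costs = costs, k = k,
                                     seed = seed)$data
}

#' Normality-gated paired comparison of two score vectors
#'
#' Runs a Shapiro–Wilk normality test on the paired differences
#' `d = x - y`. If its p-value is below 0.05, normality cannot be assumed
#' and the Wilcoxon signed-rank test is used (zero differences dropped;
#' exact p when the sample is small with no rank ties, normal
#' approximation with continuity correction otherwise); otherwise the
#' paired t-test. Direction is the sign of the mean (t branch) or median
#' (Wilcoxon branch) of the differences. Degenerate cases: all-zero
#' differences give a non-significant verdict; constant nonzero
#' differences give a "degenerate" significant verdict with the sign's
#' direction.
#'
#' @param x,y Equal-length score vectors (length >= 3), e.g. per-fold
#'   accuracies of two over-samplers.
#' @param alpha Significance level.
#' @return List of class `"comparison_verdict"`: `normality_p`,
#'   `test_used`, `test_p`, `direction` (`"first"`, `"second"`, `"none"`),
#'   `significant`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  verdict <- function(test_used, test_p, stat_center, normality_p = NA_real_,
                      significant = NULL) {
    direction <- if (stat_center > 0) "first"
                 else if (stat_center < 0) "second" else "none"
    if (is.null(significant))
      significant <- isTRUE(test_p < alpha) && direction != "none"
    structure(list(normality_p = normality_p, test_used = test_used,
                   test_p = test_p, direction = direction,
                   significant = significant),
              class = "comparison_verdict")
  }
  if (all(d == 0))
    return(verdict("degenerate", 1, 0, significant = FALSE))
  if (stats::sd(d) == 0)   # constant nonzero shift: no dispersion to test
    return(verdict("degenerate", 0, d[[1L]], significant = TRUE))
  sw <- stats::shapiro.test(d)
  if (sw$p.value < 0.05) {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              correct = TRUE))
    verdict("wilcoxon", wt$p.value, stats::median(d[d != 0]),
            normality_p = sw$p.value)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    verdict("paired_t", tt$p.value, mean(d), normality_p = sw$p.value)
  }
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat(sprintf(
    "paired comparison: %s test, p = %.4g, direction = %s%s\n",
    x$test_used, x$test_p, x$direction,
    if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Run counters from repeated paired comparisons
#'
#' Tallies, over the runs of a repeated experiment, in how many runs the
#' first method is significantly better (`counter_plus`) and in how many
#' the second is (`counter_minus`).
#'
#' @param scores A `fold_scores` frame from [run_cv_experiment()].
#' @param method_first,method_second Method names to compare.
#' @param classifier Classifier name.
#' @param metric `"accuracy"` or `"expected_cost"`. For costs, lower is
#'   better, so the comparison is run on the negated values.
#' @param alpha Significance level.
#' @return List of class `"counter_ledger"` with `counter_plus`,
#'   `counter_minus`, `runs` and the per-run verdicts.
#' @export
count_run_verdicts <- function(scores, method_first, method_second,
                               classifier, metric = "accuracy",
                               alpha = 0.05) {
  sgn <- if (metric == "expected_cost") -1 else 1
  runs <- sort(unique(scores$run))
  cp <- 0L; cm <- 0L
  verdicts <- list()
  for (r in runs) {
    sub <- scores[scores$run == r & scores$classifier == classifier, ]
    a <- sub[sub$method == method_first, ]
    b <- sub[sub$method == method_second, ]
    a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
    v <- paired_compare(sgn * a[[metric]], sgn * b[[metric]], alpha)
    verdicts[[length(verdicts) + 1L]] <- v
    if (v$significant && v$direction == "first") cp <- cp + 1L
    if (v$significant && v$direction == "second") cm <- cm + 1L
  }
  structure(list(counter_plus = cp, counter_minus = cm,
                 runs = length(runs), verdicts = verdicts),
            class = "counter_ledger")
}

#' @export
print.counter_ledger <- function(x, ...) {
  cat(sprintf("counters over %d runs: +%d / -%d\n", x$runs,
              x$counter_plus, x$counter_minus))
  invisible(x)
}

#' Exact-binomial point probability of a counter pair
#'
#' The point mass `P(B(n, 1/2) = counter_plus)` with
#' `n = counter_plus + counter_minus`:
#' `choose(n, counter_plus) / 2^n`. Both factors are exactly
#' representable, so the result is exact (not merely approximate) for the
#' counter ranges that arise from repeated runs.
#'
#' @param counter_plus,counter_minus Non-negative counts, not both zero.
#' @return The point probability.
#' @export
#' @examples
#' binomial_point_p(9, 0)   # 0.001953125
#' binomial_point_p(8, 1)   # 0.017578125
binomial_point_p <- function(counter_plus, counter_minus) {
  stopifnot(counter_plus >= 0, counter_minus >= 0)
  n <- counter_plus + counter_minus
  if (n < 1) stop("both counters are zero")
  choose(n, counter_plus) * 0.5^n
}

#' Beta score of a ledger of significance verdicts
#'
#' Each (data set, classifier) cell contributes +1 when the first method
#' is significantly better, -1 when the second is, 0 otherwise; the beta
#' score is the sum, bounded by +/- (number of cells).
#'
#' @param verdicts Integer vector of +1 / -1 / 0 cell verdicts.
#' @return The signed sum.
#' @export
beta_score <- function(verdicts) {
  if (length(verdicts) == 0L) return(0L)
  stopifnot(all(verdicts %in% c(-1L, 0L, 1L)))
  as.integer(sum(verdicts))
}

#' Mann-Kendall monotonic-trend test with Sen's slope
#'
#' Nonparametric test for a monotonic trend of an ordered series:
#' `S` is the sum over pairs `i < j` of `sign(y_j - y_i)`; the variance of
#' `S` is tie-corrected,
#' `var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`;
#' the z statistic uses a continuity correction; `tau` is reported as
#' tau-b (tie-adjusted). Sen's slope is the median of the pairwise slopes
#' `(y_j - y_i) / (j - i)` with the rank-based normal-approximation 95%
#' confidence interval.
#'
#' @param series Numeric vector (length >= 4) in its natural order.
#' @return List of class `"trend_result"`: `S`, `var_S`, `tau`,
#'   `p_two_sided`, `sen_slope`, `sen_ci`.
#' @export
mann_kendall_trend <- function(series) {
  n <- length(series)
  stopifnot(n >= 4L)
  pairs <- utils::combn(n, 2L)
  diffs <- series[pairs[2L, ]] - series[pairs[1L, ]]
  S <- sum(sign(diffs))
  ties <- table(series)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (S == 0 || var_S == 0) {
    z <- 0; p <- 1
  } else {
    z <- (S - sign(S)) / sqrt(var_S)
    p <- 2 * stats::pnorm(-abs(z))
  }
  # tau-b: tie-adjusted denominator on both margins (the index has no ties)
  n0 <- n * (n - 1) / 2
  n_ties <- sum(ties * (ties - 1) / 2)
  tau <- if (n0 > n_ties) S / sqrt(n0 * (n0 - n_ties)) else 0
  slopes <- sort(diffs / (pairs[2L, ] - pairs[1L, ]))
  sen <- stats::median(slopes)
  N <- length(slopes)
  C <- stats::qnorm(0.975) * sqrt(var_S)
  lo <- max(1L, floor((N - C) / 2))
  hi <- min(N, ceiling((N + C) / 2 + 1))
  structure(list(S = S, var_S = var_S, tau = tau, p_two_sided = p,
                 sen_slope = sen, sen_ci = c(slopes[lo], slopes[hi])),
            class = "trend_result")
}

#' Spearman rank-correlation trend test
#'
#' Correlation of the mid-ranked series values against their index order,
#' with the one-sided p-value (alternative: positive association) from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param series Numeric vector (length >= 4) in its natural order.
#' @return List of class `"trend_result"` with `rho` and
#'   `rho_p_one_sided`.
#' @export
#' @examples
#' spearman_trend(c(8, 13, 12, 14, 15, 16, 16, 16, 16, 17))
spearman_trend <- function(series) {
  n <- length(series)
  stopifnot(n >= 4L)
  r <- rank(series)
  if (stats::sd(r) == 0) stop("zero rank variance: series is constant")
  rho <- stats::cor(rank(seq_len(n)), r)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  structure(list(rho = rho, rho_p_one_sided = p), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  if (!is.null(x$S))
    cat(sprintf(
      "Mann-Kendall: S = %d, tau = %.4f, two-sided p = %.3g, Sen slope = %.4g [%.4g, %.4g]\n",
      x$S, x$tau, x$p_two_sided, x$sen_slope, x$sen_ci[1], x$sen_ci[2]))
  if (!is.null(x$rho))
    cat(sprintf("Spearman: rho = %.5f, one-sided p = %.3g\n",
                x$rho, x$rho_p_one_sided))
  invisible(x)
}
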