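test_that("required_n solves the enlargement equation with half-away rounding", {
  expect_equal(required_n(balance_counts(2, 8), 0.5), 6L)
  expect_equal(required_n(balance_counts(10, 90), 0.3), 29L)
  expect_equal((10 + 29) / (100 + 29), 0.3023, tolerance = 1e-4)
  # cost-derived proportion collapses algebraically to n = m+ (gamma - 1)
  b <- balance_counts(134, 1594)
  expect_equal(required_n(b, target_q(b, cost_spec(gamma = 10))), 1206L)
  expect_error(required_n(balance_counts(2, 8), 0.1), "must lie")
  expect_error(required_n(balance_counts(2, 8), 1), "must lie")
})

test_that("composing the cost-derived q with the count formula gives n = m+ (gamma - 1) exactly", {
  for (m_plus in c(5, 24, 134, 332)) for (m_minus in c(64, 229, 1594)) {
    if (m_plus >= m_minus) next
    for (gamma in 2:50) {
      b <- balance_counts(m_plus, m_minus)
      n <- required_n(b, target_q(b, cost_spec(gamma = gamma)))
      expect_identical(n, as.integer(m_plus * (gamma - 1)))
    }
  }
})

test_that("the achieved minority proportion deviates from q by at most 1/(M+n)", {
  set.seed(11)
  for (i in 1:200) {
    m_plus <- sample(2:400, 1)
    m_minus <- m_plus + sample(1:1500, 1)
    b <- balance_counts(m_plus, m_minus)
    q <- runif(1, b$p_plus + 1e-6, 1 - 1e-6)
    n <- required_n(b, q)
    achieved <- (m_plus + n) / (b$M + n)
    expect_lte(abs(achieved - q), 1 / (b$M + n) + 1e-12)
  }
})

test_that("the BN over-sampler appends exactly n synthetic minority rows after the originals", {
  prob <- make_gt_problem(m_plus = 20L, m_minus = 80L, seed = 31L,
                          n_features = 3L)
  fit <- bosme(prob$table, q = 0.5, seed = 99)
  expect_equal(nrow(fit$data), 160L)
  expect_equal(sum(fit$data$class == "+"), 80L)
  strip <- function(d) data.frame(lapply(as.data.frame(d), identity))
  expect_identical(strip(fit$data[1:100, ]), strip(prob$table))
  expect_equal(attr(fit$data, "provenance"), "enlarged")
  expect_equal(sum(attr(fit$data, "row_provenance") == "synthetic"),
               fit$plan$n)
  # q at (or below) the current proportion is refused
  expect_error(bosme(prob$table, q = 0.2), "must lie")
})

test_that("over-sampling is seed-deterministic and depends only on the minority subset", {
  prob <- make_gt_problem(m_plus = 25L, m_minus = 100L, seed = 17L,
                          n_features = 3L)
  tbl <- prob$table
  a <- bosme(tbl, q = 0.5, seed = 7)$data
  b <- bosme(tbl, q = 0.5, seed = 7)$data
  expect_identical(as.data.frame(a), as.data.frame(b))

  # permuting the majority rows must not change the synthetic rows
  cn <- attr(tbl, "class_name")
  idx <- seq_len(nrow(tbl))
  maj <- idx[as.character(tbl[[cn]]) == "-"]
  set.seed(1); perm <- idx
  perm[maj] <- maj[sample.int(length(maj))]
  tbl2 <- tbl[perm, , drop = FALSE]
  n_syn <- required_n(class_balance(tbl), 0.5)
  synth1 <- utils::tail(as.data.frame(a), n_syn)
  synth2 <- utils::tail(as.data.frame(bosme(tbl2, q = 0.5, seed = 7)$data),
                        n_syn)
  rownames(synth1) <- rownames(synth2) <- NULL
  expect_identical(synth1, synth2)

  t1 <- utils::tail(as.data.frame(smote(tbl, q = 0.5, k = 3,
                                        seed = 7)$data), n_syn)
  t2 <- utils::tail(as.data.frame(smote(tbl2, q = 0.5, k = 3,
                                        seed = 7)$data), n_syn)
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
})

test_that("synthetic rows reproduce the minority joint distribution (two-stage sampling)", {
  spec <- gt_spec(n_features = 3, arc_density = 1.2, divergence = 1,
                  seed = 13, m_plus = 500L, m_minus = 1000L)
  bn_pos <- random_ground_truth_bn(spec, "positive")
  bn_neg <- random_ground_truth_bn(spec, "negative")
  tbl <- sample_imbalanced_dataset(bn_pos, bn_neg, 500L, 1000L, seed = 13)
  fit <- bosme(tbl, q = 500 * 11 / (500 * 11 + 1000), seed = 13)  # n = 5000
  expect_equal(fit$plan$n, 5000L)
  synth <- utils::tail(as.data.frame(fit$data), 5000)
  synth$class <- NULL
  expect_lt(tv_to_joint(bn_pos, synth), 0.06)
})

test_that("the SMOTE baseline interpolates within segments and copies categorical values", {
  schema <- list(feature_schema("x", "continuous"))
  df <- data.frame(x = c(0, 1, 0.1, 0.9, 5, 6, 7, 8, 9, 10),
                   y = c("+", "+", "+", "+", "-", "-", "-", "-", "-", "-"))
  tbl <- dataset_table(df, schema, "y")
  out <- smote(tbl, q = 0.5, k = 1, seed = 5)
  synth <- utils::tail(as.data.frame(out$data), out$plan$n)
  expect_true(all(synth$x >= 0 & synth$x <= 1))    # hull of the minority
  expect_equal(nrow(synth), required_n(class_balance(tbl), 0.5))

  schema2 <- list(feature_schema("a", "categorical", c("u", "v", "w")),
                  feature_schema("b", "categorical", c("0", "1")))
  set.seed(2)
  df2 <- data.frame(a = sample(c("u", "v", "w"), 40, TRUE),
                    b = sample(c("0", "1"), 40, TRUE),
                    y = rep(c("+", "-"), c(10, 30)))
  tbl2 <- dataset_table(df2, schema2, "y")
  out2 <- smote(tbl2, q = 0.45, k = 3, seed = 6)
  synth2 <- utils::tail(as.data.frame(out2$data), out2$plan$n)
  minority_vals <- unique(df2$a[df2$y == "+"])
  expect_true(all(synth2$a %in% minority_vals))    # copied, never invented
})

test_that("over-sampling distributional fit improves with minority size (KL, 10 seeds)", {
  kl_at <- function(m_plus, seed) {
    spec <- gt_spec(n_features = 3, arc_density = 1, divergence = 1,
                    seed = 500 + seed)
    bn_pos <- random_ground_truth_bn(spec, "positive")
    df <- logic_sample(bn_pos, m_plus, seed = seed)
    kl_true_vs_learned(bn_pos, bn_fit(df))
  }
  kl_small <- vapply(1:10, function(s) kl_at(500L, s), 0)
  kl_large <- vapply(1:10, function(s) kl_at(5000L, s), 0)
  expect_lt(mean(kl_large), mean(kl_small))
})
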