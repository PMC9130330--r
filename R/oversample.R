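#' Synthetic-instance count reaching a target minority proportion
#'
#' Solves `(m_plus + n) / (M + n) = q` for the number of synthetic minority
#' instances and rounds to the nearest integer (half away from zero):
#' `n = round((q M - m_plus) / (1 - q))`. The proportion actually achieved
#' then deviates from `q` by at most `1 / (M + n)`.
#'
#' @param balance A [class_balance()].
#' @param q Target minority proportion, strictly between the current
#'   proportion and 1.
#' @return Integer count `n >= 0`.
#' @export
#' @examples
#' required_n(balance_counts(2, 8), 0.5)   # 6
required_n <- function(balance, q) {
  stopifnot(inherits(balance, "class_balance"))
  if (q <= balance$p_plus || q >= 1)
    stop("q must lie in (", signif(balance$p_plus, 4), ", 1); got ", q)
  x <- (q * balance$M - balance$m_plus) / (1 - q)
  as.integer(floor(x + 0.5))   # half away from zero (x >= 0 here)
}

oversample_plan <- function(balance, q) {
  n <- required_n(balance, q)
  structure(list(q = q, n = n, source_balance = balance,
                 achieved = (balance$m_plus + n) / (balance$M + n)),
            class = "oversample_plan")
}

#' @export
print.oversample_plan <- function(x, ...) {
  cat(sprintf(
    "oversample plan: q = %.4f -> n = %d synthetic rows (achieved %.4f)\n",
    x$q, x$n, x$achieved))
  invisible(x)
}

resolve_q <- function(balance, q, costs) {
  if (is.null(q)) {
    if (is.null(costs)) stop("give either q or a cost_spec")
    q <- target_q(balance, costs)
  }
  q
}

bind_synthetic <- function(table, synth_df, minority_label) {
  cn <- attr(table, "class_name")
  synth_df[[cn]] <- factor(minority_label,
                           levels = levels(table[[cn]]))
  out_df <- rbind(as.data.frame(table), synth_df[names(table)])
  out <- dataset_table(out_df, attr(table, "schema"), cn,
                       provenance = "enlarged")
  attr(out, "row_provenance") <- c(rep("original", nrow(table)),
                                   rep("synthetic", nrow(synth_df)))
  out
}

#' Bayesian-network over-sampling of the minority class
#'
#' Enlarges an imbalanced binary data set by (1) extracting the minority
#' subset, (2) fitting a maximum-likelihood Bayesian network to its
#' features (class column excluded) by hill-climbing under the
#' log-likelihood score, (3) forward-sampling as many synthetic minority
#' instances as needed to bring the minority proportion to `q`, and (4)
#' binding them, labelled with the minority class, after the original rows
#' (order preserved). The target `q` may be given directly or derived from
#' misclassification costs via [target_q()].
#'
#' @param table A binary-class [dataset_table()].
#' @param minority_label Minority class label (default `"+"`).
#' @param q Target minority proportion; mutually exclusive with `costs`.
#' @param costs A [cost_spec()]; used to derive `q` when `q` is `NULL`.
#' @param control A [bn_control()] for the structure search.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `"bosme"` with elements `data` (the enlarged
#'   `dataset_table`), `bn` (the fitted network), and `plan` (the
#'   `oversample_plan`).
#' @export
#' @examples
#' \dontrun{
#' fit <- bosme(tbl, costs = cost_spec(gamma = 10), seed = 1)
#' summary(fit$bn)
#' fit$data
#' }
bosme <- function(table, minority_label = "+", q = NULL, costs = NULL,
                  control = bn_control(), seed = NULL) {
  balance <- class_balance(table, minority_label)
  q <- resolve_q(balance, q, costs)
  plan <- oversample_plan(balance, q)   # validates q in (p_plus, 1)
  cn <- attr(table, "class_name")
  minority <- table[as.character(table[[cn]]) == minority_label, ,
                    drop = FALSE]
  if (nrow(minority) < 2L)
    stop("minority subset too small to fit a network (",
         nrow(minority), " rows)")
  feats <- feature_frame(minority)
  feats <- droplevels_keep_schema(feats)
  bn <- bn_fit(feats, control)
  synth <- logic_sample(bn, plan$n, seed = seed)
  out <- structure(list(data = bind_synthetic(table, synth, minority_label),
                        bn = bn, plan = plan,
                        minority_label = minority_label, seed = seed),
                   class = "bosme")
  out
}

# keep full declared levels on factor columns (CPT domains must not shrink
# just because a level is absent from the minority subset)
droplevels_keep_schema <- function(df) df

#' @export
print.bosme <- function(x, ...) {
  cat("Bayesian-network over-sampling\n")
  print(x$plan)
  print(x$bn)
  cat(sprintf("  enlarged data: %d rows (%d original + %d synthetic)\n",
              nrow(x$data), nrow(x$data) - x$plan$n, x$plan$n))
  invisible(x)
}

#' @export
summary.bosme <- function(object, ...) {
  print(object)
  summary(object$bn)
  invisible(object)
}

#' Minimal SMOTE baseline
#'
#' Benchmark over-sampler: each synthetic minority instance is generated
#' from a minority instance and a random one of its `k` nearest minority
#' neighbours under a Gower-style distance (range-standardized absolute
#' difference for continuous features, 0/1 mismatch for categorical ones).
#' Continuous features are interpolated uniformly along the segment to the
#' neighbour; each categorical feature is copied at random from the
#' instance or the neighbour. The count of synthetic rows is
#' [required_n()] for the target proportion `q`.
#'
#' @inheritParams bosme
#' @param k Neighbour count (the classical default is 5).
#' @return An object of class `"smote_fit"` with elements `data` and
#'   `plan`.
#' @export
smote <- function(table, minority_label = "+", q = NULL, costs = NULL,
                  k = 5, seed = NULL) {
  balance <- class_balance(table, minority_label)
  q <- resolve_q(balance, q, costs)
  plan <- oversample_plan(balance, q)
  cn <- attr(table, "class_name")
  minority <- table[as.character(table[[cn]]) == minority_label, ,
                    drop = FALSE]
  feats <- feature_frame(minority)
  m <- nrow(feats)
  if (m < k + 1L)
    stop("minority subset needs at least k + 1 = ", k + 1L, " rows; has ",
         m)
  schema <- attr(table, "schema")
  kinds <- schema_kinds(schema)
  names(kinds) <- schema_names(schema)
  cont <- names(kinds)[kinds == "continuous"]
  cat_ <- names(kinds)[kinds == "categorical"]

  # Gower-style pairwise distances on the minority subset
  D <- matrix(0, m, m)
  for (f in cont) {
    v <- feats[[f]]
    rg <- diff(range(v))
    if (rg == 0) next
    D <- D + abs(outer(v, v, "-")) / rg
  }
  for (f in cat_) {
    v <- as.character(feats[[f]])
    D <- D + outer(v, v, "!=")
  }
  diag(D) <- Inf
  nn <- matrix(apply(D, 1L, function(d) order(d)[seq_len(k)]), nrow = k)

  if (!is.null(seed)) set.seed(seed)
  n <- plan$n
  base_idx <- rep_len(seq_len(m), n)
  synth <- feats[base_idx, , drop = FALSE]
  rownames(synth) <- NULL
  for (t in seq_len(n)) {
    i <- base_idx[[t]]
    j <- nn[sample.int(k, 1L), i]
    u <- stats::runif(1)
    for (f in cont)
      synth[t, f] <- feats[i, f] + u * (feats[j, f] - feats[i, f])
    for (f in cat_)
      if (stats::runif(1) < 0.5) synth[t, f] <- feats[j, f]
  }
  structure(list(data = bind_synthetic(table, synth, minority_label),
                 plan = plan, k = k, seed = seed),
            class = "smote_fit")
}

#' @export
print.smote_fit <- function(x, ...) {
  cat("SMOTE baseline over-sampling\n")
  print(x$plan)
  invisible(x)
}
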