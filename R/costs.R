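#' Misclassification cost specification
#'
#' Costs can be given as the pair `(c_plus, c_minus)` — the costs of a
#' false negative and a false positive — or as the cost ratio
#' `gamma = c_plus / c_minus` alone (then `c_minus = 1`). The working
#' assumption throughout is `gamma > 1`: missing a minority ("positive")
#' instance is the expensive error.
#'
#' @param c_plus Cost of a false negative.
#' @param c_minus Cost of a false positive.
#' @param gamma Cost ratio; mutually exclusive with the pair.
#' @return An object of class `"cost_spec"` with fields `c_plus`,
#'   `c_minus`, `gamma`.
#' @export
#' @examples
#' cost_spec(gamma = 10)
#' cost_spec(c_plus = 4, c_minus = 1)
cost_spec <- function(c_plus = NULL, c_minus = NULL, gamma = NULL) {
  if (!is.null(gamma)) {
    if (!is.null(c_plus) || !is.null(c_minus))
      stop("give either gamma or the (c_plus, c_minus) pair, not both")
    c_minus <- 1
    c_plus <- gamma
  }
  if (is.null(c_plus) || is.null(c_minus))
    stop("costs unspecified")
  if (c_plus <= 0 || c_minus <= 0) stop("costs must be positive")
  gamma <- c_plus / c_minus
  if (gamma <= 1)
    stop("cost ratio gamma = c_plus/c_minus must exceed 1 (got ",
         signif(gamma, 4), ")")
  structure(list(c_plus = c_plus, c_minus = c_minus, gamma = gamma),
            class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("costs: c+ = %g, c- = %g (gamma = %g)\n",
              x$c_plus, x$c_minus, x$gamma))
  invisible(x)
}

#' Target minority proportion implied by the costs
#'
#' The class-prior translation result: reweighting the class distribution
#' proportionally to the misclassification costs makes the
#' accuracy-optimal classifier under the new distribution coincide with
#' the expected-cost-optimal classifier under the original one. The
#' minority proportion of that reweighted distribution,
#' `q = m_plus * gamma / (m_plus * gamma + m_minus)`,
#' is therefore the proportion the minority class should represent in the
#' enlarged training set. For `gamma > 1`, `q` always lies strictly
#' between the original minority proportion and 1.
#'
#' @param balance A [class_balance()].
#' @param costs A [cost_spec()].
#' @return The proportion `q`.
#' @export
#' @examples
#' target_q(balance_counts(134, 1594), cost_spec(gamma = 10))  # 0.4567...
target_q <- function(balance, costs) {
  stopifnot(inherits(balance, "class_balance"), inherits(costs, "cost_spec"))
  g <- costs$gamma
  balance$m_plus * g / (balance$m_plus * g + balance$m_minus)
}

#' Cost-reweighted class distribution
#'
#' Multiplies each component of the class prior by its misclassification
#' cost and renormalizes:
#' `p~+ = C p+ c+`, `p~- = C p- c-` with
#' `C = 1 / (p+ c+ + p- c-)`. Reduces to the identity when the two costs
#' are equal.
#'
#' @param p_plus Original minority proportion, in (0, 1).
#' @param costs A [cost_spec()], or any list with `c_plus`/`c_minus`.
#' @return List with `p_tilde_plus`, `p_tilde_minus` and the normalizing
#'   constant `C`.
#' @export
reweighted_distribution <- function(p_plus, costs) {
  stopifnot(p_plus > 0, p_plus < 1)
  p_minus <- 1 - p_plus
  C <- 1 / (p_plus * costs$c_plus + p_minus * costs$c_minus)
  list(p_tilde_plus = C * p_plus * costs$c_plus,
       p_tilde_minus = C * p_minus * costs$c_minus,
       C = C)
}

#' Minimum-expected-cost label
#'
#' Given the (posterior) probability of the minority class and the costs,
#' assigning "+" incurs expected cost `c- p-` and assigning "-" incurs
#' `c+ p+`; the cheaper label wins. An exact tie returns "+"
#' (sensitivity-favoring).
#'
#' @param p_plus Probability of the minority class, in \[0, 1\].
#' @param costs A [cost_spec()] (or list with `c_plus`/`c_minus`).
#' @return `"+"` or `"-"`.
#' @export
min_cost_label <- function(p_plus, costs) {
  if (costs$c_minus * (1 - p_plus) <= costs$c_plus * p_plus) "+" else "-"
}

#' Expected misclassification cost of a confusion table
#'
#' @param confusion Named counts with components `TP`, `FP`, `TN`, `FN`.
#' @param costs A [cost_spec()].
#' @return `(FN * c_plus + FP * c_minus) / total`, the average cost per
#'   classified instance.
#' @export
#' @examples
#' expected_cost(c(TP = 3, FP = 3, TN = 2, FN = 2), cost_spec(gamma = 10))
expected_cost <- function(confusion, costs) {
  confusion <- as.list(confusion)
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(confusion)))
    stop("confusion must have components TP, FP, TN, FN")
  cnt <- vapply(need, function(k) as.numeric(confusion[[k]]), 0)
  if (any(cnt < 0)) stop("negative counts")
  total <- sum(cnt)
  if (total == 0) stop("empty confusion table")
  (cnt[["FN"]] * costs$c_plus + cnt[["FP"]] * costs$c_minus) / total
}

#' Confusion counts of predicted vs true binary labels
#'
#' @param truth,pred Vectors of `"+"`/`"-"` labels (anything coercible).
#' @param positive The minority label (default `"+"`).
#' @return Named numeric vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = "+") {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == positive & pred == positive),
    FP = sum(truth != positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FN = sum(truth == positive & pred != positive))
}
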