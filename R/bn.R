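#' Control parameters for Bayesian-network learning
#'
#' @param epsilon Minimum strict score improvement for a hill-climbing move
#'   to be applied. Pure log-likelihood scoring makes arc addition weakly
#'   beneficial on training data, so termination relies on this strict-gain
#'   threshold.
#' @param max_parents Cap on the parent-set size per node (`Inf` =
#'   unbounded).
#' @param max_iter Cap on the number of applied moves; exceeded searches
#'   return the best graph so far with a warning.
#' @param sigma_floor Absolute lower bound for any fitted Gaussian standard
#'   deviation. The effective floor per node is
#'   `max(sigma_floor, 1e-3 * sd(node))` so the sampler never emits NaN.
#' @return A list of class `"bn_control"`.
#' @export
bn_control <- function(epsilon = 1e-6, max_parents = Inf, max_iter = 500L,
                       sigma_floor = 1e-6) {
  stopifnot(epsilon > 0, max_iter > 0, max_parents >= 0, sigma_floor > 0)
  structure(list(epsilon = epsilon, max_parents = max_parents,
                 max_iter = max_iter, sigma_floor = sigma_floor),
            class = "bn_control")
}

# ---- internal helpers -------------------------------------------------

# linear config index over the categorical parents, first parent varying
# fastest (expand.grid convention); 1 when there are no categorical parents
config_index <- function(data, dparents) {
  idx <- rep(1L, nrow(data))
  mult <- 1L
  for (p in dparents) {
    f <- data[[p]]
    idx <- idx + (as.integer(f) - 1L) * mult
    mult <- mult * nlevels(f)
  }
  idx
}

n_configs <- function(data, dparents) {
  prod(vapply(dparents, function(p) nlevels(data[[p]]), 1L))
}

split_parents <- function(data, parents) {
  is_fac <- vapply(parents, function(p) is.factor(data[[p]]), FALSE)
  list(d = parents[is_fac], c = parents[!is_fac])
}

node_sigma_floor <- function(y, sigma_floor) {
  s <- stats::sd(y)
  if (!is.finite(s)) s <- 0
  max(sigma_floor, 1e-3 * s)
}

# MLE of a discrete family; returns prob matrix [config x level] + flags
fit_discrete_family <- function(child, parents, data) {
  y <- data[[child]]
  lev <- levels(y)
  ncfg <- n_configs(data, parents)
  cfg <- config_index(data, parents)
  counts <- matrix(0, ncfg, length(lev), dimnames = list(NULL, lev))
  tab <- table(factor(cfg, levels = seq_len(ncfg)), y)
  counts[] <- as.numeric(tab)
  tot <- rowSums(counts)
  fallback <- tot == 0
  prob <- counts
  prob[!fallback, ] <- counts[!fallback, , drop = FALSE] / tot[!fallback]
  prob[fallback, ] <- 1 / length(lev)
  list(kind = "discrete", child = child, parents = parents,
       levels = lev, prob = prob, fallback = fallback, counts = counts)
}

# least-squares per categorical-parent config with MLE (divide-by-n)
# variance; configs with < 2 rows or a singular design fall back to the
# pooled fit so the sampler is total
fit_gaussian_family <- function(child, parents, data, sigma_floor) {
  sp <- split_parents(data, parents)
  y <- data[[child]]
  floor_sd <- node_sigma_floor(y, sigma_floor)
  ncp <- length(sp$c)
  X <- if (ncp) as.matrix(data[sp$c]) else NULL
  ncfg <- n_configs(data, sp$d)
  cfg <- config_index(data, sp$d)

  ls_fit <- function(rows) {
    yy <- y[rows]
    if (ncp == 0L) {
      mu <- mean(yy)
      return(list(b0 = mu, coefs = numeric(0),
                  sd = max(floor_sd, sqrt(mean((yy - mu)^2))),
                  ok = TRUE))
    }
    Xd <- cbind(1, X[rows, , drop = FALSE])
    if (length(rows) < ncol(Xd)) return(list(ok = FALSE))
    qrX <- qr(Xd)
    if (qrX$rank < ncol(Xd)) return(list(ok = FALSE))
    b <- qr.coef(qrX, yy)
    res <- yy - drop(Xd %*% b)
    list(b0 = b[[1L]], coefs = stats::setNames(b[-1L], sp$c),
         sd = max(floor_sd, sqrt(mean(res^2))), ok = TRUE)
  }

  pooled <- ls_fit(seq_along(y))
  if (!pooled$ok) {
    # rank-deficient even pooled: zero out unidentifiable coefficients
    Xd <- cbind(1, X)
    b <- qr.coef(qr(Xd), y)
    b[is.na(b)] <- 0
    res <- y - drop(Xd %*% b)
    pooled <- list(b0 = b[[1L]], coefs = stats::setNames(b[-1L], sp$c),
                   sd = max(floor_sd, sqrt(mean(res^2))), ok = TRUE)
  }

  b0 <- numeric(ncfg); sds <- numeric(ncfg)
  coefs <- matrix(0, ncfg, ncp, dimnames = list(NULL, sp$c))
  pooled_flag <- logical(ncfg)
  for (g in seq_len(ncfg)) {
    rows <- which(cfg == g)
    f <- if (length(rows) >= 2L) ls_fit(rows) else list(ok = FALSE)
    if (!f$ok) { f <- pooled; pooled_flag[g] <- TRUE }
    b0[g] <- f$b0; sds[g] <- f$sd
    if (ncp) coefs[g, ] <- f$coefs
  }
  list(kind = "gaussian", child = child, parents = parents,
       dparents = sp$d, cparents = sp$c,
       b0 = b0, coefs = coefs, sd = sds, pooled = pooled_flag,
       sigma_floor = floor_sd)
}

# training log-likelihood of one family under its own MLE fit
family_loglik <- function(child, parents, data, sigma_floor) {
  if (is.factor(data[[child]])) {
    f <- fit_discrete_family(child, parents, data)
    n <- f$counts
    tot <- rowSums(n)
    p <- f$prob
    sum(n[n > 0] * log(p[n > 0]))
  } else {
    f <- fit_gaussian_family(child, parents, data, sigma_floor)
    sum(eval_gaussian_family(f, data, log = TRUE))
  }
}

eval_discrete_family <- function(f, data, log = FALSE) {
  cfg <- config_index(data, f$parents)
  li <- as.integer(data[[f$child]])
  p <- f$prob[cbind(cfg, li)]
  if (log) log(p) else p
}

eval_gaussian_family <- function(f, data, log = FALSE) {
  cfg <- config_index(data, f$dparents)
  mu <- f$b0[cfg]
  if (length(f$cparents))
    mu <- mu + rowSums(as.matrix(data[f$cparents]) *
                         f$coefs[cfg, , drop = FALSE])
  stats::dnorm(data[[f$child]], mu, f$sd[cfg], log = log)
}

eval_family <- function(f, data, log = FALSE) {
  if (f$kind == "discrete") eval_discrete_family(f, data, log)
  else eval_gaussian_family(f, data, log)
}

check_family_legal <- function(child, parents, data) {
  if (is.factor(data[[child]])) {
    bad <- parents[!vapply(parents, function(p) is.factor(data[[p]]), FALSE)]
    if (length(bad))
      stop("categorical node '", child,
           "' may not have continuous parent(s): ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- exported operations ---------------------------------------------

#' Maximum-likelihood parameter fit for a fixed DAG
#'
#' Discrete nodes get conditional probability tables of empirical
#' frequencies per categorical-parent configuration; parent configurations
#' unseen in the data get a uniform fallback row and are flagged.
#' Continuous nodes get, per categorical-parent configuration, a
#' least-squares linear model in the continuous parents with MLE
#' (divide-by-n) variance, floored at the node's sigma floor; degenerate
#' configurations (fewer than 2 rows, or a singular design) fall back to
#' the pooled fit over all rows.
#'
#' @param g A [dag()] whose nodes are exactly the columns of `data`.
#' @param data Data frame of factor (categorical) and numeric (continuous)
#'   columns; at least one row.
#' @param control A [bn_control()].
#' @return An object of class `"bn"` with elements `dag`, `cpds`, `variant`
#'   (`"discrete"`, `"gaussian"` or `"clg"`), and the training
#'   log-likelihood `loglik`.
#' @export
fit_mle <- function(g, data, control = bn_control()) {
  stopifnot(nrow(data) >= 1L)
  if (!setequal(g$nodes, names(data)))
    stop("dag nodes and data columns differ")
  is_fac <- vapply(g$nodes, function(n) is.factor(data[[n]]), FALSE)
  variant <- if (all(is_fac)) "discrete" else if (!any(is_fac)) "gaussian"
             else "clg"
  cpds <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (node in g$nodes) {
    pa <- g$parents[[node]]
    check_family_legal(node, pa, data)
    cpds[[node]] <- if (is_fac[[node]])
      fit_discrete_family(node, pa, data)
    else
      fit_gaussian_family(node, pa, data, control$sigma_floor)
  }
  levels_by_node <- lapply(data, function(v) if (is.factor(v)) levels(v))
  bn <- structure(list(dag = g, cpds = cpds, variant = variant,
                       nodes = g$nodes, levels = levels_by_node,
                       nobs = nrow(data), control = control),
                  class = "bn")
  bn$loglik <- sum(bn_loglik_terms(bn, data))
  bn
}

# per-node sums of log CPD values of `data` under a fitted bn
bn_loglik_terms <- function(bn, data) {
  vapply(bn$nodes,
         function(n) sum(eval_family(bn$cpds[[n]], data, log = TRUE)),
         0)
}

#' Decomposable log-likelihood score of a DAG
#'
#' The score of `g` is the log-likelihood of `data` under the
#' maximum-likelihood parameters fitted on that same data: a sum of
#' independent per-family terms, which is what makes single-arc
#' hill-climbing cheap (only the changed families are rescored).
#'
#' @inheritParams fit_mle
#' @return The score (natural log), with the per-node terms in the
#'   `"terms"` attribute.
#' @export
loglik_score <- function(g, data, control = bn_control()) {
  terms <- vapply(g$nodes, function(n) {
    check_family_legal(n, g$parents[[n]], data)
    family_loglik(n, g$parents[[n]], data, control$sigma_floor)
  }, 0)
  structure(sum(terms), terms = terms)
}

#' Hill-climbing structure search under the log-likelihood score
#'
#' Steepest-ascent greedy search from the empty graph over single-arc
#' additions, removals and reversals. A move must be legal (acyclic, the
#' categorical-parents-only rule for categorical children, the
#' `max_parents` cap) and is applied only if its score gain strictly
#' exceeds `control$epsilon`. Ties are broken deterministically: move type
#' (add, then remove, then reverse), then parent, then child, in node
#' declaration order. The returned graph is a local optimum: no legal
#' single-arc move gains more than `epsilon`.
#'
#' @inheritParams fit_mle
#' @return A [dag()].
#' @export
hill_climb <- function(data, control = bn_control()) {
  stopifnot(nrow(data) >= 2L)
  nodes <- names(data)
  g <- dag(nodes)
  is_fac <- vapply(data, is.factor, FALSE)

  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- family_loglik(child, parents, data, control$sigma_floor)
    cache[[key]] <- v
    v
  }
  legal_parent <- function(parent, child)
    !(is_fac[[child]] && !is_fac[[parent]])

  cur <- stats::setNames(vapply(nodes, function(n) fam(n, character()), 0),
                         nodes)
  for (iter in seq_len(control$max_iter)) {
    best <- list(gain = -Inf)
    for (u in nodes) for (v in nodes) {
      if (u == v) next
      if (!(u %in% g$parents[[v]])) {
        # addition u -> v
        if (!legal_parent(u, v)) next
        if (length(g$parents[[v]]) >= control$max_parents) next
        if (has_path(g, v, u)) next
        gain <- fam(v, c(g$parents[[v]], u)) - cur[[v]]
        if (gain > best$gain)
          best <- list(gain = gain, type = "add", u = u, v = v)
      }
    }
    a <- arcs(g)
    if (nrow(a)) for (i in seq_len(nrow(a))) {
      u <- a[i, 1L]; v <- a[i, 2L]
      gain <- fam(v, setdiff(g$parents[[v]], u)) - cur[[v]]
      if (gain > best$gain)
        best <- list(gain = gain, type = "remove", u = u, v = v)
    }
    if (nrow(a)) for (i in seq_len(nrow(a))) {
      u <- a[i, 1L]; v <- a[i, 2L]
      if (!legal_parent(v, u)) next
      if (length(g$parents[[u]]) >= control$max_parents) next
      g2 <- remove_arc(g, u, v)
      if (has_path(g2, u, v)) next   # another path u ~> v: reversal cycles
      gain <- (fam(v, g2$parents[[v]]) - cur[[v]]) +
              (fam(u, c(g2$parents[[u]], v)) - cur[[u]])
      if (gain > best$gain)
        best <- list(gain = gain, type = "reverse", u = u, v = v)
    }
    if (best$gain <= control$epsilon) return(g)
    if (best$type == "add") {
      g <- add_arc(g, best$u, best$v)
      cur[[best$v]] <- fam(best$v, g$parents[[best$v]])
    } else if (best$type == "remove") {
      g <- remove_arc(g, best$u, best$v)
      cur[[best$v]] <- fam(best$v, g$parents[[best$v]])
    } else {
      g <- remove_arc(g, best$u, best$v)
      g <- add_arc(g, best$v, best$u)
      cur[[best$v]] <- fam(best$v, g$parents[[best$v]])
      cur[[best$u]] <- fam(best$u, g$parents[[best$u]])
    }
  }
  warning("hill_climb: max_iter reached; returning best graph so far")
  g
}

#' Fit a Bayesian network: structure search plus maximum likelihood
#'
#' The one-call model fit: learns the DAG by [hill_climb()] under the
#' decomposable log-likelihood score, then the parameters by [fit_mle()].
#' Accepts either a plain feature data frame (factor and numeric columns)
#' or a [dataset_table()], whose class column is excluded — the network
#' models the features only.
#'
#' @param data Feature data frame or `dataset_table`.
#' @param control A [bn_control()].
#' @return An object of class `"bn"`; see [fit_mle()]. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `simulate`.
#' @export
#' @examples
#' df <- data.frame(a = factor(c(0, 0, 1, 1)), b = factor(c(0, 0, 1, 1)))
#' fit <- bn_fit(df)
#' arcs(fit$dag)
bn_fit <- function(data, control = bn_control()) {
  if (inherits(data, "dataset_table")) data <- feature_frame(data)
  g <- hill_climb(data, control)
  bn <- fit_mle(g, data, control)
  bn$call <- sys.call()
  bn
}

#' @export
print.bn <- function(x, ...) {
  cat(sprintf("Bayesian network (%s): %d nodes, %d arcs, fitted on %d rows\n",
              x$variant, length(x$nodes), nrow(arcs(x$dag)), x$nobs))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
summary.bn <- function(object, ...) {
  a <- arcs(object$dag)
  cat(sprintf("Bayesian network, variant '%s'\n", object$variant))
  cat(sprintf("  nodes: %s\n", paste(object$nodes, collapse = ", ")))
  if (nrow(a))
    cat("  arcs: ",
        paste(sprintf("%s -> %s", a[, 1L], a[, 2L]), collapse = "; "), "\n")
  else cat("  arcs: (none)\n")
  cat(sprintf("  training log-likelihood: %.4f on %d rows\n",
              object$loglik, object$nobs))
  fb <- vapply(object$cpds, function(f)
    if (f$kind == "discrete") sum(f$fallback) else sum(f$pooled), 0)
  if (any(fb > 0))
    cat("  fallback configs:",
        paste(sprintf("%s=%d", names(fb)[fb > 0], fb[fb > 0]),
              collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.bn <- function(object, ...) object$cpds

#' @export
logLik.bn <- function(object, ...) {
  df <- sum(vapply(object$cpds, function(f) {
    if (f$kind == "discrete")
      nrow(f$prob) * (ncol(f$prob) - 1L)
    else
      length(f$b0) * (2L + length(f$cparents))
  }, 0))
  structure(object$loglik, df = df, nobs = object$nobs, class = "logLik")
}

#' Forward (logic) sampling from a fitted network
#'
#' Generates complete instances by traversing the DAG in topological order:
#' each node is drawn from its conditional distribution given the values
#' already sampled for its parents (uniform over levels for flagged unseen
#' parent configurations; `Normal(mu(parents), sd)` for continuous nodes).
#'
#' @param bn A fitted `"bn"`.
#' @param n Number of instances (`n = 0` gives an empty frame).
#' @param seed Optional integer seed; a fixed seed gives identical output.
#' @return Data frame of `n` complete rows with the network's columns.
#' @export
logic_sample <- function(bn, n, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(bn$dag)
  out <- stats::setNames(vector("list", length(bn$nodes)), bn$nodes)
  cfg_of <- function(dparents) {
    idx <- rep(1L, n); mult <- 1L
    for (p in dparents) {
      f <- out[[p]]
      idx <- idx + (as.integer(f) - 1L) * mult
      mult <- mult * nlevels(f)
    }
    idx
  }
  for (node in ord) {
    f <- bn$cpds[[node]]
    if (f$kind == "discrete") {
      cfg <- cfg_of(f$parents)
      vals <- integer(n)
      for (g in sort(unique(cfg))) {
        rows <- which(cfg == g)
        vals[rows] <- sample.int(length(f$levels), length(rows),
                                 replace = TRUE, prob = f$prob[g, ])
      }
      out[[node]] <- factor(f$levels[vals], levels = f$levels)
    } else {
      cfg <- cfg_of(f$dparents)
      mu <- f$b0[cfg]
      if (length(f$cparents)) {
        X <- do.call(cbind, out[f$cparents])
        mu <- mu + rowSums(X * f$coefs[cfg, , drop = FALSE])
      }
      out[[node]] <- stats::rnorm(n, mu, f$sd[cfg])
    }
  }
  as.data.frame(out[bn$nodes])
}

#' @rdname logic_sample
#' @param object A fitted `"bn"`.
#' @param nsim Number of instances.
#' @param ... Unused.
#' @export
simulate.bn <- function(object, nsim = 1, seed = NULL, ...) {
  logic_sample(object, nsim, seed)
}

#' Chain-rule joint probability (or density) of a full assignment
#'
#' The joint value is the product over nodes of the conditional
#' distribution of the node at the instance, given the instance's values of
#' its parents. For discrete networks this is a probability; when
#' continuous nodes are present it is a density.
#'
#' @param bn A fitted `"bn"`.
#' @param instance Named list or one-row data frame assigning every node a
#'   value.
#' @param log Return the log value?
#' @return A single numeric value.
#' @export
joint_probability <- function(bn, instance, log = FALSE) {
  row <- as.data.frame(as.list(instance))[bn$nodes]
  for (node in bn$nodes) {
    lv <- bn$levels[[node]]
    if (!is.null(lv)) {
      val <- as.character(row[[node]])
      if (!val %in% lv)
        stop("value '", val, "' outside levels of node '", node, "'")
      row[[node]] <- factor(val, levels = lv)
    } else {
      row[[node]] <- as.numeric(row[[node]])
    }
  }
  ll <- sum(vapply(bn$nodes,
                   function(n) eval_family(bn$cpds[[n]], row, log = TRUE),
                   0))
  if (log) ll else exp(ll)
}

#' Log-likelihood of new data under a fitted network
#'
#' Rows that hit a flagged unseen parent configuration contribute the
#' uniform fallback's log-probability.
#'
#' @param bn A fitted `"bn"`.
#' @param data Data frame with the network's columns (factor levels must
#'   match the training levels).
#' @return Total log-likelihood, per-node terms in attribute `"terms"`.
#' @export
bn_loglik <- function(bn, data) {
  terms <- bn_loglik_terms(bn, data)
  structure(sum(terms), terms = terms)
}
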