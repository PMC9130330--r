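# Shared fixture builders: all data is generated in code at test time.

# hand-built discrete network; prob_list[[node]] is a [config x level]
# matrix with the first parent varying fastest
manual_discrete_bn <- function(levels_list, arc_mat = NULL,
                               prob_list = list()) {
  nodes <- names(levels_list)
  g <- dag(nodes, arc_mat)
  cpds <- lapply(nodes, function(node) {
    prob <- prob_list[[node]]
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
    list(kind = "discrete", child = node, parents = g$parents[[node]],
         levels = levels_list[[node]], prob = prob,
         fallback = rep(FALSE, nrow(prob)))
  })
  names(cpds) <- nodes
  structure(list(dag = g, cpds = cpds, variant = "discrete",
                 nodes = nodes, levels = levels_list, nobs = 0L,
                 control = bn_control(), loglik = NA_real_),
            class = "bn")
}

# every acyclic graph over the given nodes (25 for three nodes)
all_dags <- function(nodes) {
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1L)) {
    sel <- pairs[bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1L)) > 0L, ,
                 drop = FALSE]
    g <- tryCatch(dag(nodes, as.matrix(sel)), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# empirical joint table of a discrete sample, as a named probability vector
joint_empirical <- function(df) {
  key <- do.call(paste, c(lapply(df, as.character), sep = "\r"))
  tab <- table(key)
  tab / sum(tab)
}

# total-variation distance between a discrete bn's chain-rule joint and a
# sample's empirical joint
tv_to_joint <- function(bn, sample_df) {
  grid <- expand.grid(bn$levels, stringsAsFactors = FALSE)
  names(grid) <- bn$nodes
  p <- vapply(seq_len(nrow(grid)), function(i)
    joint_probability(bn, grid[i, , drop = FALSE]), 0)
  key <- do.call(paste, c(lapply(grid, as.character), sep = "\r"))
  emp <- joint_empirical(sample_df)
  q <- as.numeric(emp[key])
  q[is.na(q)] <- 0
  sum(abs(p - q)) / 2
}

# KL(true joint || learned joint) over all configurations of a small
# discrete network; learned probabilities clamped away from zero
kl_true_vs_learned <- function(bn_true, bn_learned, floor = 1e-12) {
  grid <- expand.grid(bn_true$levels, stringsAsFactors = FALSE)
  names(grid) <- bn_true$nodes
  kl <- 0
  for (i in seq_len(nrow(grid))) {
    inst <- grid[i, , drop = FALSE]
    p <- joint_probability(bn_true, inst)
    if (p == 0) next
    q <- max(joint_probability(bn_learned, inst), floor)
    kl <- kl + p * log(p / q)
  }
  kl
}

# small mixed table for data-model round trips
make_mixed_table <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  schema <- list(feature_schema("color", "categorical", c("red", "blue")),
                 feature_schema("size", "continuous"))
  df <- data.frame(color = sample(c("red", "blue"), n, replace = TRUE),
                   size = round(stats::rnorm(n), 6) + 1 / 3,
                   y = rep_len(c("+", "-"), n))
  dataset_table(df, schema, "y")
}

# imbalanced discrete ground-truth problem used across harness tests
make_gt_problem <- function(m_plus = 40L, m_minus = 360L, seed = 101L,
                            n_features = 4L, divergence = 1.5) {
  spec <- gt_spec(n_features = n_features, arc_density = 1,
                  m_plus = m_plus, m_minus = m_minus,
                  divergence = divergence, seed = seed)
  bn_pos <- random_ground_truth_bn(spec, "positive")
  bn_neg <- random_ground_truth_bn(spec, "negative")
  list(spec = spec, bn_pos = bn_pos, bn_neg = bn_neg,
       table = sample_imbalanced_dataset(bn_pos, bn_neg, m_plus, m_minus,
                                         seed = seed + 7L))
}
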