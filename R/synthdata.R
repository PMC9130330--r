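#' Ground-truth specification for synthetic imbalanced problems
#'
#' Describes a pair of class-conditional Bayesian networks over a common
#' feature schema, from which imbalanced data sets with a known
#' Bayes-optimal rule can be drawn. Generation is class-conditional (one
#' network per class) rather than a single joint network over features and
#' class: this makes the cost-optimal label exactly computable by
#' enumeration, which the cost-machinery tests rely on.
#'
#' @param n_features Number of features.
#' @param kinds Per-feature kind list: entries are either a character
#'   vector of levels (categorical) or the string `"continuous"`. Default:
#'   all binary categorical.
#' @param arc_density Expected number of parents per node.
#' @param dirichlet_alpha Concentration of the Dirichlet draw for CPT
#'   rows; 1 is uniform over the simplex.
#' @param clg_ranges Ranges for continuous-node parameters:
#'   `list(intercept = c(lo, hi), coef = c(lo, hi), sd = c(lo, hi))`.
#' @param m_plus,m_minus Minority and majority row counts.
#' @param divergence How far the negative-class network's parameters are
#'   pushed away from the positive-class network's (shift scale on CPT
#'   logits and CLG intercepts); 0 makes the classes indistinguishable.
#' @param seed Integer seed; the whole ground truth is a deterministic
#'   function of the spec.
#' @return A list of class `"gt_spec"`.
#' @export
gt_spec <- function(n_features = 3L,
                    kinds = NULL,
                    arc_density = 1,
                    dirichlet_alpha = 1,
                    clg_ranges = list(intercept = c(-2, 2),
                                      coef = c(-1, 1),
                                      sd = c(0.5, 1.5)),
                    m_plus = 100L, m_minus = 900L,
                    divergence = 1, seed = 1L) {
  if (is.null(kinds))
    kinds <- rep(list(c("0", "1")), n_features)
  stopifnot(length(kinds) == n_features, m_plus <= m_minus,
            arc_density >= 0, dirichlet_alpha > 0, divergence >= 0)
  structure(list(n_features = n_features, kinds = kinds,
                 arc_density = arc_density,
                 dirichlet_alpha = dirichlet_alpha,
                 clg_ranges = clg_ranges, m_plus = m_plus,
                 m_minus = m_minus, divergence = divergence,
                 seed = as.integer(seed)),
            class = "gt_spec")
}

gt_schema <- function(spec) {
  lapply(seq_len(spec$n_features), function(i) {
    k <- spec$kinds[[i]]
    nm <- sprintf("x%d", i)
    if (identical(k, "continuous")) feature_schema(nm, "continuous")
    else feature_schema(nm, "categorical", k)
  })
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

#' Random ground-truth Bayesian network
#'
#' Draws a DAG by sampling a node order and then arcs with probability set
#' by `arc_density` (the categorical-parents-only rule enforced), discrete
#' CPT rows from a Dirichlet, and continuous-node parameters uniformly in
#' `clg_ranges`. The negative-class network is the positive-class network
#' with its parameters perturbed: a fixed random direction (a function of
#' the seed) scaled by `divergence` is added to CPT logits and CLG
#' intercepts, so increasing the knob moves the classes monotonically
#' apart along the same direction.
#'
#' @param spec A [gt_spec()].
#' @param class_side `"positive"` or `"negative"`.
#' @return A `"bn"` object (same structure as [fit_mle()] output; usable
#'   with [logic_sample()] and [joint_probability()]).
#' @export
random_ground_truth_bn <- function(spec,
                                   class_side = c("positive", "negative")) {
  class_side <- match.arg(class_side)
  schema <- gt_schema(spec)
  nodes <- schema_names(schema)
  kinds <- stats::setNames(schema_kinds(schema), nodes)
  n <- length(nodes)

  set.seed(derive_seed(spec$seed, 1L))
  ord <- sample(nodes)
  g <- dag(nodes)
  p_arc <- if (n > 1) min(1, spec$arc_density / (n - 1)) else 0
  if (n > 1) for (j in 2:n) for (i in 1:(j - 1)) {
    u <- ord[[i]]; v <- ord[[j]]
    # categorical child may not have a continuous parent
    if (kinds[[which(nodes == v)]] == "categorical" &&
        kinds[[which(nodes == u)]] == "continuous") next
    if (stats::runif(1) < p_arc) g <- add_arc(g, u, v)
  }

  levels_by_node <- stats::setNames(
    lapply(schema, function(fs) fs$levels), nodes)
  nlev <- function(node) length(levels_by_node[[node]])
  ncfg_of <- function(parents) {
    dp <- parents[kinds[parents] == "categorical"]
    if (!length(dp)) 1L else prod(vapply(dp, nlev, 1L))
  }

  # positive-side parameters plus a fixed perturbation direction
  set.seed(derive_seed(spec$seed, 2L))
  cpds <- stats::setNames(vector("list", n), nodes)
  for (node in nodes) {
    pa <- g$parents[[node]]
    kindmap <- kinds[pa]
    dp <- pa[kindmap == "categorical"]
    cp <- pa[kindmap == "continuous"]
    ncfg <- ncfg_of(pa)
    if (kinds[[node]] == "categorical") {
      lev <- levels_by_node[[node]]
      prob <- t(vapply(seq_len(ncfg),
                       function(i) rdirichlet1(length(lev),
                                               spec$dirichlet_alpha),
                       numeric(length(lev))))
      shift <- matrix(stats::rnorm(ncfg * length(lev)), ncfg)
      if (class_side == "negative") {
        logit <- log(pmax(prob, 1e-12)) + spec$divergence * shift
        prob <- exp(logit) / rowSums(exp(logit))
      }
      cpds[[node]] <- list(kind = "discrete", child = node, parents = dp,
                           levels = lev, prob = prob,
                           fallback = rep(FALSE, ncfg))
    } else {
      r <- spec$clg_ranges
      b0 <- stats::runif(ncfg, r$intercept[1], r$intercept[2])
      coefs <- matrix(stats::runif(ncfg * length(cp), r$coef[1], r$coef[2]),
                      ncfg, length(cp), dimnames = list(NULL, cp))
      sds <- stats::runif(ncfg, r$sd[1], r$sd[2])
      shift <- stats::rnorm(ncfg)
      if (class_side == "negative") b0 <- b0 + spec$divergence * shift
      cpds[[node]] <- list(kind = "gaussian", child = node, parents = pa,
                           dparents = dp, cparents = cp, b0 = b0,
                           coefs = coefs, sd = sds,
                           pooled = rep(FALSE, ncfg),
                           sigma_floor = 1e-6)
    }
  }
  variant <- if (all(kinds == "categorical")) "discrete"
             else if (all(kinds == "continuous")) "gaussian" else "clg"
  lvls <- lapply(nodes, function(nd)
    if (kinds[[nd]] == "categorical") levels_by_node[[nd]] else NULL)
  names(lvls) <- nodes
  structure(list(dag = g, cpds = cpds, variant = variant, nodes = nodes,
                 levels = lvls, nobs = 0L, control = bn_control(),
                 loglik = NA_real_, schema = schema),
            class = "bn")
}

#' Sample an imbalanced data set from two class-conditional networks
#'
#' @param bn_pos,bn_neg Networks sharing a schema, for the minority and
#'   majority class respectively.
#' @param m_plus,m_minus Row counts per class (`m_plus <= m_minus`,
#'   `m_plus >= 1`).
#' @param seed Integer seed (drives both sampling and the final shuffle).
#' @return A [dataset_table()] with class column `"class"` and labels
#'   `"+"` / `"-"` in shuffled order.
#' @export
sample_imbalanced_dataset <- function(bn_pos, bn_neg, m_plus, m_minus,
                                      seed = 1L) {
  if (m_plus < 1L) stop("minority class needs at least one row")
  if (m_plus > m_minus) stop("m_plus must not exceed m_minus")
  if (!identical(bn_pos$nodes, bn_neg$nodes) ||
      !identical(bn_pos$levels, bn_neg$levels))
    stop("the two networks do not share a schema")
  pos <- logic_sample(bn_pos, m_plus, seed = derive_seed(seed, 1L))
  neg <- logic_sample(bn_neg, m_minus, seed = derive_seed(seed, 2L))
  pos$class <- "+"; neg$class <- "-"
  df <- rbind(pos, neg)
  set.seed(derive_seed(seed, 3L))
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  schema <- bn_schema(bn_pos)
  dataset_table(df, schema, "class", provenance = "synthetic")
}

# reconstruct a feature schema from a network's node kinds/levels
bn_schema <- function(bn) {
  if (!is.null(bn$schema)) return(bn$schema)
  lapply(bn$nodes, function(nd) {
    lv <- bn$levels[[nd]]
    if (is.null(lv)) feature_schema(nd, "continuous")
    else feature_schema(nd, "categorical", lv)
  })
}

#' Exact Bayes error of a discrete class-conditional problem
#'
#' Enumerates every feature configuration and accumulates the probability
#' mass lost by the Bayes-optimal (accuracy) rule under the prior
#' `(p_plus, 1 - p_plus)`. Only feasible for small all-categorical
#' networks.
#'
#' @param bn_pos,bn_neg Discrete networks sharing a schema.
#' @param p_plus Minority prior.
#' @return The Bayes error probability.
#' @export
bayes_error <- function(bn_pos, bn_neg, p_plus) {
  stopifnot(bn_pos$variant == "discrete")
  grid <- expand.grid(bn_pos$levels, stringsAsFactors = FALSE)
  names(grid) <- bn_pos$nodes
  err <- 0
  for (i in seq_len(nrow(grid))) {
    inst <- grid[i, , drop = FALSE]
    jp <- p_plus * joint_probability(bn_pos, inst)
    jn <- (1 - p_plus) * joint_probability(bn_neg, inst)
    err <- err + min(jp, jn)
  }
  err
}

#' Write the canonical fixture suite
#'
#' Generates three seeded benchmark-shaped fixtures — all-categorical
#' (1728 rows, 6 binary-to-quaternary features, 7.75% minority), mixed
#' (462 rows, 1 categorical + 8 continuous features, 34.6% minority), and
#' all-continuous (306 rows, 3 features, 26.5% minority) — as CSV files
#' with schema sidecars, plus a JSON manifest recording seeds, balances
#' and the generating networks' parameters. Regenerating from the same
#' master seed reproduces the files byte-identically.
#'
#' @param out_dir Writable directory (created if needed).
#' @param master_seed Integer master seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(out_dir, master_seed = 20220524L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  shapes <- list(
    list(name = "categorical_car_like",
         spec = gt_spec(n_features = 6,
                        kinds = list(c("a", "b", "c", "d"),
                                     c("a", "b", "c", "d"),
                                     c("2", "3", "4", "5more"),
                                     c("2", "4", "more"),
                                     c("small", "med", "big"),
                                     c("low", "med", "high")),
                        arc_density = 1.2, m_plus = 134L, m_minus = 1594L,
                        divergence = 1,
                        seed = derive_seed(master_seed, 1L))),
    list(name = "mixed_saheart_like",
         spec = gt_spec(n_features = 9,
                        kinds = c(list(c("absent", "present")),
                                  rep(list("continuous"), 8)),
                        arc_density = 1, m_plus = 160L, m_minus = 302L,
                        divergence = 1,
                        seed = derive_seed(master_seed, 2L))),
    list(name = "continuous_haberman_like",
         spec = gt_spec(n_features = 3,
                        kinds = rep(list("continuous"), 3),
                        arc_density = 1, m_plus = 81L, m_minus = 225L,
                        divergence = 1,
                        seed = derive_seed(master_seed, 3L))))
  manifest <- list(master_seed = master_seed, fixtures = list())
  for (sh in shapes) {
    spec <- sh$spec
    bn_pos <- random_ground_truth_bn(spec, "positive")
    bn_neg <- random_ground_truth_bn(spec, "negative")
    data_seed <- derive_seed(spec$seed, 99L)
    tbl <- sample_imbalanced_dataset(bn_pos, bn_neg, spec$m_plus,
                                     spec$m_minus, seed = data_seed)
    csv <- file.path(out_dir, paste0(sh$name, ".csv"))
    write_dataset(tbl, csv)
    bal <- class_balance(tbl, "+")
    dump <- file.path(out_dir, paste0(sh$name, "_bn.json"))
    jsonlite::write_json(list(positive = bn_dump(bn_pos),
                              negative = bn_dump(bn_neg)),
                         dump, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest$fixtures[[sh$name]] <- list(
      csv = basename(csv), bn_dump = basename(dump),
      gt_seed = spec$seed, data_seed = data_seed,
      M = bal$M, m_plus = bal$m_plus, m_minus = bal$m_minus,
      p_plus = bal$p_plus)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Dump a network's structure and parameters to plain lists (for JSON)
#' @param bn A `"bn"`.
#' @return A nested list mirroring the DAG and CPDs.
#' @export
bn_dump <- function(bn) {
  list(nodes = bn$nodes,
       arcs = apply(arcs(bn$dag), 1L, paste, collapse = "->"),
       cpds = lapply(bn$cpds, function(f) {
         if (f$kind == "discrete")
           list(kind = "discrete", parents = f$parents, levels = f$levels,
                prob = apply(f$prob, 1L, identity, simplify = FALSE))
         else
           list(kind = "gaussian", parents = f$parents,
                intercept = f$b0, coefs = f$coefs, sd = f$sd)
       }))
}
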