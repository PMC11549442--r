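#' Locally-equal self-weights
#'
#' The self-weight that puts equal weight on an agent's own opinion and
#' on each of its neighbors' opinions: `w_i = 1 / (deg_i + 1)`. With
#' these weights one naive-averaging step is the plain arithmetic mean
#' of the closed neighborhood.
#'
#' @param g An [igraph::igraph] graph.
#' @return Numeric vector of per-node self-weights.
#' @export
weights_lew <- function(g) {
  1 / (igraph::degree(g) + 1)
}

#' One synchronous naive-averaging (DeGroot) step
#'
#' Updates every opinion to
#' `x'_i = w_i * x_i + (1 - w_i)/deg_i * sum of neighbor opinions`,
#' i.e. `x' = A %*% x` with `A = build_static_adjacency(g, w)`. All
#' agents update simultaneously from the current state.
#'
#' @param x Numeric vector of current opinions.
#' @param g An [igraph::igraph] graph.
#' @param w Per-node self-weights in \[0, 1\] (scalar recycled).
#' @return Numeric vector of updated opinions.
#' @export
step_naive <- function(x, g, w) {
  a <- build_static_adjacency(g, w)
  as.vector(a %*% x)
}

# Sum of v over the closed neighborhood {i} U N_i of every node, given the
# unweighted dense adjacency of the graph.
closed_sums <- function(adj, v) {
  as.vector(adj %*% v) + v
}

#' One Bayesian fusion step assuming independent opinions
#'
#' Treats each neighbor's belief as an independent Gaussian measurement
#' and fuses the closed neighborhood by inverse-variance weighting (a
#' bank of one-dimensional Kalman updates run synchronously):
#' the new mean is the precision-weighted average of the neighborhood
#' means, and the new variance is the reciprocal of the summed
#' precisions. Because every neighbor adds positive precision, each
#' agent's variance strictly decreases at every step.
#'
#' @param b A [belief_state()].
#' @param g An [igraph::igraph] graph with as many nodes as `b` has
#'   agents.
#' @return The updated [belief_state()].
#' @export
step_bi_ai <- function(b, g) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  step_bi_ai_impl(b, adj)
}

step_bi_ai_impl <- function(b, adj) {
  prec <- 1 / b$sigma2
  s <- closed_sums(adj, prec)
  m <- closed_sums(adj, b$mu * prec)
  belief_state(m / s, 1 / s)
}

#' One Bayesian fusion step assuming unknown dependence
#'
#' Conservative variant for opinions whose correlation is unknown (they
#' are exchanged repeatedly, so they are certainly not independent). The
#' new mean is the same precision-weighted average as under the
#' independence assumption, but the new variance is the
#' precision-squared-weighted mean of the neighborhood variances
#' (one-dimensional fast covariance intersection):
#' `sigma2' = sum(1/sigma2) / sum(1/sigma2^2)`. The fused variance never
#' drops below the smallest variance in the closed neighborhood, so
#' certainty is only gained by initially uncertain agents.
#'
#' @inheritParams step_bi_ai
#' @return The updated [belief_state()].
#' @export
step_bi_ud <- function(b, g) {
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  step_bi_ud_impl(b, adj)
}

step_bi_ud_impl <- function(b, adj) {
  prec <- 1 / b$sigma2
  s <- closed_sums(adj, prec)
  m <- closed_sums(adj, b$mu * prec)
  s2 <- closed_sums(adj, prec^2)
  belief_state(m / s, s / s2)
}

#' Effective weighted adjacency of an update rule
#'
#' The row-stochastic matrix whose product with the opinion vector gives
#' one update. For the naive rules this is the static matrix defined by
#' the self-weights. For the Bayesian rules the weights are dynamic:
#' `a[i, j] = (1/sigma2_j) / sum of precisions over {i} U N_i`, so a
#' neighbor with lower uncertainty receives more weight, and the matrix
#' changes as uncertainties evolve. Its column sums are the dynamic
#' in-degree centralities.
#'
#' @param g An [igraph::igraph] graph.
#' @param rule One of `"bi-ai"`, `"bi-ud"`, `"na-lew"`, `"na"`.
#' @param beliefs A [belief_state()]; required for the Bayesian rules.
#' @param w_global Universal self-weight in \[0, 1\]; required for
#'   `rule = "na"`.
#' @return A dense row-stochastic matrix.
#' @export
effective_adjacency <- function(g, rule, beliefs = NULL, w_global = NULL) {
  rule <- match_rule(rule)
  n <- igraph::vcount(g)
  if (rule %in% c("bi-ai", "bi-ud")) {
    if (is.null(beliefs)) stop("Bayesian rules need `beliefs`", call. = FALSE)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    effective_adjacency_bi(beliefs, adj)
  } else if (rule == "na-lew") {
    build_static_adjacency(g, weights_lew(g))
  } else {
    if (is.null(w_global)) stop('rule "na" needs `w_global`', call. = FALSE)
    build_static_adjacency(g, rep(w_global, n))
  }
}

effective_adjacency_bi <- function(b, adj) {
  prec <- 1 / b$sigma2
  closed <- adj
  diag(closed) <- 1
  w <- closed * rep(prec, each = nrow(adj))   # w[i, j] = closed[i, j] * prec_j
  w / rowSums(w)
}

match_rule <- function(rule) {
  rule <- tolower(rule)
  match.arg(rule, c("bi-ai", "bi-ud", "na-lew", "na"))
}

#' Simulate synchronous opinion dynamics
#'
#' Applies `t_steps` synchronous updates of the chosen rule to an
#' initial belief state. All agents update simultaneously from the
#' time-`t` state, so the result is independent of agent order. Per-step
#' accuracy metrics and (optionally) the dynamic in-degree centralities
#' are recorded.
#'
#' @param g An [igraph::igraph] graph.
#' @param beliefs Initial [belief_state()]. Naive rules use only the
#'   means; the variances are carried along unchanged for logging.
#' @param rule One of `"bi-ai"`, `"bi-ud"`, `"na-lew"`, `"na"`.
#' @param w_global Universal self-weight, required for `rule = "na"`.
#' @param t_steps Number of update steps (default 10).
#' @param x_neutral Neutral opinion used in the error metrics.
#' @param record_in_degree If `TRUE`, store the in-degree vector of the
#'   weight matrix used at each step (row `t` corresponds to the update
#'   from `t - 1` to `t`).
#' @return An object of class `opinion_trajectory`: a list with matrices
#'   `mu` and `sigma2` of dimension `(t_steps + 1) x n` (row 1 is the
#'   initial state), a per-step `metrics` data frame with columns
#'   `step`, `x_col`, `E_P`, `E_T`, `E_A`, `E_P_norm`, and optionally
#'   `in_degree`.
#' @export
simulate_opinions <- function(g, beliefs, rule, w_global = NULL,
                              t_steps = 10, x_neutral = 0,
                              record_in_degree = FALSE) {
  rule <- match_rule(rule)
  stopifnot(inherits(beliefs, "belief_state"))
  n <- igraph::vcount(g)
  if (length(beliefs) != n) {
    stop("beliefs and graph disagree on the number of agents", call. = FALSE)
  }
  if (!is.numeric(t_steps) || t_steps < 1) {
    stop("`t_steps` must be a positive integer", call. = FALSE)
  }

  mu <- matrix(NA_real_, t_steps + 1L, n)
  sig <- matrix(NA_real_, t_steps + 1L, n)
  mu[1L, ] <- beliefs$mu
  sig[1L, ] <- beliefs$sigma2
  indeg <- if (record_in_degree) matrix(NA_real_, t_steps, n) else NULL

  bayesian <- rule %in% c("bi-ai", "bi-ud")
  if (bayesian) {
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    state <- beliefs
    for (t in seq_len(t_steps)) {
      if (record_in_degree) {
        indeg[t, ] <- colSums(effective_adjacency_bi(state, adj))
      }
      state <- if (rule == "bi-ai") step_bi_ai_impl(state, adj)
               else step_bi_ud_impl(state, adj)
      mu[t + 1L, ] <- state$mu
      sig[t + 1L, ] <- state$sigma2
    }
  } else {
    w <- if (rule == "na-lew") weights_lew(g) else {
      if (is.null(w_global)) stop('rule "na" needs `w_global`', call. = FALSE)
      rep(w_global, n)
    }
    a <- build_static_adjacency(g, w)
    x <- beliefs$mu
    for (t in seq_len(t_steps)) {
      if (record_in_degree) indeg[t, ] <- colSums(a)
      x <- as.vector(a %*% x)
      mu[t + 1L, ] <- x
      sig[t + 1L, ] <- beliefs$sigma2
    }
  }

  metrics <- do.call(rbind, lapply(seq_len(t_steps + 1L), function(i) {
    e <- error_decomposition(mu[i, ], x_neutral)
    data.frame(step = i - 1L, x_col = e$x_col,
               E_P = e$E_P, E_T = e$E_T, E_A = e$E_A)
  }))
  metrics$E_P_norm <- if (metrics$E_P[1L] > 0) metrics$E_P / metrics$E_P[1L]
                      else NA_real_

  structure(
    list(mu = mu, sigma2 = sig, metrics = metrics, in_degree = indeg,
         rule = rule, w_global = w_global, x_neutral = x_neutral,
         n_agents = n, t_steps = t_steps),
    class = "opinion_trajectory"
  )
}

#' @export
print.opinion_trajectory <- function(x, ...) {
  cat(sprintf("<opinion_trajectory> rule %s, %d agents, %d steps\n",
              x$rule, x$n_agents, x$t_steps))
  f <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  final: x_col = %.4g, E_P = %.4g, E_T = %.4g, E_A = %.4g\n",
              f$x_col, f$E_P, f$E_T, f$E_A))
  invisible(x)
}

#' Final-step metrics of a trajectory
#'
#' @param traj An `opinion_trajectory`.
#' @return One-row data frame with the final-step metrics.
#' @export
final_metrics <- function(traj) {
  stopifnot(inherits(traj, "opinion_trajectory"))
  traj$metrics[nrow(traj$metrics), , drop = FALSE]
}

#' Optimal universal self-weight for naive averaging
#'
#' Grid search for the universal self-weight that minimizes the
#' Monte-Carlo mean final accuracy error of naive averaging. Each
#' replicate draws a fresh graph and fresh initial beliefs; all grid
#' weights are evaluated on the *same* replicates (shared seeds) so the
#' comparison across weights is paired. The companion `grid_mean`
#' entries give the mean performance across the whole grid — the
#' behavior of naive averaging when the weight is not tuned.
#'
#' @param graph_fn Zero-argument function returning a fresh graph.
#' @param belief_fn One-argument function (the graph) returning fresh
#'   initial beliefs.
#' @param grid Candidate weights in \[0, 1\] (default `0, 0.1, ..., 1`).
#' @param reps Monte-Carlo replicates.
#' @param t_steps Steps per simulation.
#' @param x_neutral Neutral opinion for the metrics.
#' @param seed Integer seed for the replicate draws.
#' @return A list with `w_optimal`, `mean_E_A` (named vector over the
#'   grid), `grid_mean_E_A`, and the per-replicate final `E_A` matrix
#'   (`reps x length(grid)`).
#' @export
optimize_universal_weight <- function(graph_fn, belief_fn,
                                      grid = seq(0, 1, by = 0.1),
                                      reps = 20, t_steps = 10,
                                      x_neutral = 0, seed = NULL) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  if (any(grid < 0 | grid > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  e_a <- matrix(NA_real_, reps, length(grid))
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    g <- graph_fn()
    b <- belief_fn(g)
    for (j in seq_along(grid)) {
      traj <- simulate_opinions(g, b, "na", w_global = grid[j],
                                t_steps = t_steps, x_neutral = x_neutral)
      e_a[r, j] <- final_metrics(traj)$E_A
    }
  }
  mean_e_a <- colMeans(e_a)
  names(mean_e_a) <- format(grid)
  list(
    w_optimal = grid[which.min(mean_e_a)],
    mean_E_A = mean_e_a,
    grid_mean_E_A = mean(e_a),
    E_A = e_a
  )
}
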