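#' Belief state of a collective
#'
#' A belief state holds, per agent, a Gaussian belief over the continuous
#' opinion: a mean `mu` and a strictly positive variance `sigma2`. The
#' naive-averaging rules use only `mu`; the Bayesian rules update both.
#'
#' @param mu Numeric vector of opinion means.
#' @param sigma2 Numeric vector of opinion variances, same length as
#'   `mu`, all strictly positive.
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(mu, sigma2) {
  mu <- as.numeric(mu)
  sigma2 <- as.numeric(sigma2)
  if (length(mu) != length(sigma2)) {
    stop("`mu` and `sigma2` must have the same length", call. = FALSE)
  }
  if (length(mu) == 0L) stop("belief state needs at least one agent", call. = FALSE)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("all variances must be finite and strictly positive", call. = FALSE)
  }
  structure(list(mu = mu, sigma2 = sigma2), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  n <- length(x$mu)
  cat(sprintf("<belief_state> %d agents\n", n))
  cat(sprintf("  mu:     mean %.4g, range [%.4g, %.4g]\n",
              mean(x$mu), min(x$mu), max(x$mu)))
  cat(sprintf("  sigma2: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$sigma2), min(x$sigma2), max(x$sigma2)))
  invisible(x)
}

#' @export
length.belief_state <- function(x) length(x$mu)

#' Sample heterogeneous initial beliefs
#'
#' Each agent receives a noisy copy of the neutral collective opinion:
#' its noise standard deviation `sigma0` is drawn uniformly from
#' `(c_inf - p_inf/2, c_inf + p_inf/2)`, the opinion is
#' `x_neutral + Normal(0, sigma0^2)`, and the assigned variance is the
#' true `sigma0^2`. The width `p_inf` controls the *heterogeneity of
#' information quality*: `p_inf = 0` gives every agent the same variance,
#' while larger `p_inf` mixes well-informed (low variance) with poorly
#' informed agents.
#'
#' @param n Number of agents.
#' @param c_inf Center of the uniform distribution of `sigma0`
#'   (default 5).
#' @param p_inf Width of that distribution; requires
#'   `c_inf - p_inf/2 > 0` so every standard deviation is positive.
#' @param x_neutral Neutral (ground-truth) collective opinion, default 0.
#' @param seed Optional integer seed.
#' @return A [belief_state()].
#' @export
sample_initial_beliefs <- function(n, c_inf = 5, p_inf = 0, x_neutral = 0,
                                   seed = NULL) {
  check_sigma_window(c_inf, p_inf)
  if (!is.null(seed)) set.seed(seed)
  sigma0 <- stats::runif(n, c_inf - p_inf / 2, c_inf + p_inf / 2)
  mu <- x_neutral + stats::rnorm(n, 0, sigma0)
  belief_state(mu, sigma0^2)
}

#' Sample beliefs with uncorrelated uncertainty-assignment errors
#'
#' Models a collective that *misjudges* the quality of its information:
#' opinions are generated with the true noise parameters
#' `(c_true, p_true)`, but the variances the agents carry are drawn
#' independently from the uniform window `(c_model, p_model)`. With
#' `c_model < c_true` the collective is on average over-confident (it
#' believes its information is better than it is); with
#' `c_model > c_true`, under-confident.
#'
#' @param n Number of agents.
#' @param c_true,p_true Center/width of the true noise standard
#'   deviation (defaults 5 and 0: homogeneous information).
#' @param c_model,p_model Center/width of the *assigned* standard
#'   deviation.
#' @param x_neutral Neutral opinion, default 0.
#' @param seed Optional integer seed.
#' @return A [belief_state()] whose `sigma2` is the (mis)assigned
#'   variance.
#' @export
sample_mismatched_uncorrelated <- function(n, c_model, p_model = 0,
                                           c_true = 5, p_true = 0,
                                           x_neutral = 0, seed = NULL) {
  check_sigma_window(c_true, p_true)
  check_sigma_window(c_model, p_model)
  if (!is.null(seed)) set.seed(seed)
  sigma_true <- stats::runif(n, c_true - p_true / 2, c_true + p_true / 2)
  mu <- x_neutral + stats::rnorm(n, 0, sigma_true)
  sigma_model <- stats::runif(n, c_model - p_model / 2, c_model + p_model / 2)
  belief_state(mu, sigma_model^2)
}

#' Centrality-correlated uncertainty assignment
#'
#' Assigns each node a standard deviation that is an affine function of
#' its degree: `sigma0_i = K_model * (1 - rho_model * deg_i / n)`. For
#' `rho_model > 0` central (high-degree) nodes get *smaller* assigned
#' uncertainty (over-confident hubs at `rho_model` near 1); for
#' `rho_model < 0` central nodes are under-confident. `rho_model = 0`
#' assigns `K_model` everywhere.
#'
#' @param g An [igraph::igraph] graph.
#' @param K_model Positive scale of the assigned standard deviations
#'   (default 5, matching the default information scale).
#' @param rho_model Correlation coefficient in \[-1, 1\] between
#'   centrality and assigned certainty.
#' @return Numeric vector of per-node standard deviations `sigma0`.
#' @export
assign_centrality_correlated_sigma <- function(g, rho_model, K_model = 5) {
  if (!is.numeric(K_model) || K_model <= 0) {
    stop("`K_model` must be positive", call. = FALSE)
  }
  if (!is.numeric(rho_model) || rho_model < -1 || rho_model > 1) {
    stop("`rho_model` must lie in [-1, 1]", call. = FALSE)
  }
  n <- igraph::vcount(g)
  sigma0 <- K_model * (1 - rho_model * igraph::degree(g) / n)
  if (any(sigma0 <= 0)) {
    stop("centrality-correlated assignment produced non-positive sigma0",
         call. = FALSE)
  }
  sigma0
}

#' Sample beliefs with centrality-correlated uncertainty errors
#'
#' Opinions are distributed homogeneously with the true noise parameters
#' `(c_true, p_true)`, but assigned variances follow the degree-dependent
#' rule of [assign_centrality_correlated_sigma()].
#'
#' @inheritParams assign_centrality_correlated_sigma
#' @inheritParams sample_mismatched_uncorrelated
#' @return A [belief_state()].
#' @export
sample_centrality_correlated <- function(g, rho_model, K_model = 5,
                                         c_true = 5, p_true = 0,
                                         x_neutral = 0, seed = NULL) {
  check_sigma_window(c_true, p_true)
  sigma0 <- assign_centrality_correlated_sigma(g, rho_model, K_model)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  sigma_true <- stats::runif(n, c_true - p_true / 2, c_true + p_true / 2)
  mu <- x_neutral + stats::rnorm(n, 0, sigma_true)
  belief_state(mu, sigma0^2)
}

check_sigma_window <- function(c_inf, p_inf) {
  if (!is.numeric(c_inf) || !is.numeric(p_inf) || p_inf < 0 ||
      c_inf - p_inf / 2 <= 0) {
    stop("need c - p/2 > 0 so sampled standard deviations stay positive",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read/write belief tables
#'
#' Beliefs are exchanged as delimited text with columns
#' `agent_id`, `mu`, `sigma2` (`agent_id` is 1-based).
#'
#' @param b A [belief_state()].
#' @param path File path.
#' @return `write_beliefs` returns `path` invisibly; `read_beliefs`
#'   returns a [belief_state()].
#' @export
write_beliefs <- function(b, path) {
  stopifnot(inherits(b, "belief_state"))
  utils::write.csv(
    data.frame(agent_id = seq_along(b$mu), mu = b$mu, sigma2 = b$sigma2),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_beliefs
#' @export
read_beliefs <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mu", "sigma2") %in% names(df))) {
    stop("belief table needs columns `mu` and `sigma2`", call. = FALSE)
  }
  if ("agent_id" %in% names(df)) df <- df[order(df$agent_id), , drop = FALSE]
  belief_state(df$mu, df$sigma2)
}
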