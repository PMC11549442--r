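#' Accuracy, precision, and trueness error decomposition
#'
#' Decomposes the collective's total squared error about the neutral
#' opinion into a spread term and a bias term. With `x_col` the mean of
#' the expected opinions,
#' `E_P = mean((mu - x_col)^2)` (precision error: opinion variance about
#' the collective average, a proxy for distance from consensus),
#' `E_T = (x_col - x_neutral)^2` (trueness error: the collective bias),
#' and `E_A = mean((mu - x_neutral)^2)` (accuracy error). The
#' bias–variance identity `E_A = E_P + E_T` holds exactly.
#'
#' @param mu Numeric vector of expected opinions (belief means for the
#'   Bayesian rules, scalar opinions for naive averaging).
#' @param x_neutral Neutral (ground-truth) opinion, default 0.
#' @return A list with `x_col`, `E_P`, `E_T`, `E_A`.
#' @export
error_decomposition <- function(mu, x_neutral = 0) {
  mu <- as.numeric(mu)
  if (length(mu) == 0L) stop("need at least one agent", call. = FALSE)
  x_col <- mean(mu)
  list(
    x_col = x_col,
    E_P = mean((mu - x_col)^2),
    E_T = (x_col - x_neutral)^2,
    E_A = mean((mu - x_neutral)^2)
  )
}

#' In-degree centrality of a weighted network
#'
#' Column sums of a row-stochastic weight matrix: the total weight the
#' rest of the collective puts on each agent's opinion. Because every
#' row sums to one, the in-degrees sum to the number of agents. For the
#' Bayesian rules the weight matrix is dynamic (see
#' [effective_adjacency()]), so in-degree centrality evolves with the
#' uncertainties.
#'
#' @param a A row-stochastic weight matrix.
#' @return Numeric vector of per-node in-degrees.
#' @export
in_degree <- function(a) {
  a <- as.matrix(a)
  colSums(a)
}

#' Degree heterogeneity of a graph
#'
#' Population standard deviation of the unweighted degree distribution,
#' `sqrt(mean((d_i - mean(d))^2))`. Zero for regular graphs; maximal,
#' among connected graphs of the same mean degree, for the star.
#'
#' @param g An [igraph::igraph] graph.
#' @return Nonnegative scalar.
#' @export
degree_std <- function(g) {
  d <- igraph::degree(g)
  sqrt(mean((d - mean(d))^2))
}
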