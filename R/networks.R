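#' Star graph
#'
#' Builds the fully centralized extreme of the network spectrum: one hub
#' (node 1) connected to every other node. The star has the largest
#' degree-distribution standard deviation of any connected graph with
#' mean degree `2*(n-1)/n`.
#'
#' @param n Number of nodes (at least 2).
#' @return An undirected, connected [igraph::igraph] graph.
#' @examples
#' g <- make_star_graph(5)
#' igraph::degree(g) # 4 1 1 1 1
#' @export
make_star_graph <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  igraph::make_star(n, mode = "undirected", center = 1)
}

#' Random connected k-regular graph
#'
#' Samples a random graph in which every node has exactly `k` neighbors,
#' resampling until the draw is connected. Regular graphs are the
#' homogeneous-centrality reference: their degree standard deviation is
#' exactly zero.
#'
#' @param n Number of nodes.
#' @param k Degree of every node; `n * k` must be even and `k < n`.
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Resampling budget before giving up (connectivity is
#'   overwhelmingly likely for `k >= 3`, so the default is generous).
#' @return A connected `k`-regular [igraph::igraph] graph.
#' @export
make_k_regular <- function(n, k, seed = NULL, max_tries = 1000L) {
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(k) || k < 1 || k != round(k) || k >= n) {
    stop("`k` must be an integer in [1, n)", call. = FALSE)
  }
  if ((n * k) %% 2 != 0) {
    stop("infeasible degree sequence: n * k must be even", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_k_regular(n, k)
    if (igraph::is_connected(g)) return(g)
  }
  stop("failed to sample a connected k-regular graph within `max_tries`",
       call. = FALSE)
}

#' Heterogeneous networks by adding links to a star
#'
#' Starts from the star graph and adds each non-star node pair (i.e. each
#' pair of peripheral nodes) independently with wiring probability `p_w`.
#' At `p_w = 0` the output is the star itself; at `p_w = 1` it is the
#' complete (all-to-all) graph. The star backbone keeps every output
#' connected, while the degree standard deviation falls roughly linearly
#' in `p_w`. Note that the mean degree grows with `p_w`, so spectra of
#' graphs at different `p_w` differ; see [replace_links_model()] for the
#' constant-mean-degree alternative.
#'
#' @param n Number of nodes (at least 2).
#' @param p_w Wiring probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A connected [igraph::igraph] graph.
#' @export
add_links_model <- function(n, p_w, seed = NULL) {
  if (!is.numeric(p_w) || length(p_w) != 1L || p_w < 0 || p_w > 1) {
    stop("`p_w` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- make_star_graph(n)
  if (n > 2 && p_w > 0) {
    periph <- utils::combn(2:n, 2)              # pairs not already in the star
    keep <- stats::runif(ncol(periph)) < p_w
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(periph[, keep, drop = FALSE]))
    }
  }
  g
}

#' Heterogeneous networks by replacing links, at constant mean degree
#'
#' Three-step generator producing connected graphs whose mean degree stays
#' approximately that of the star while the degree heterogeneity is
#' controlled by `p_r`:
#' \enumerate{
#'   \item add links to the star with probability `p_r` per peripheral
#'     pair (as in [add_links_model()]); call the number of added links `m`;
#'   \item remove `m` links drawn uniformly from *all* current links
#'     (star links included), restoring the star's link count but
#'     possibly disconnecting the graph;
#'   \item while the graph is disconnected, pick two distinct components
#'     uniformly at random, one uniform node in each, and link them.
#' }
#' Reconnection adds a small surplus of links, so the mean degree is only
#' approximately conserved. The degree standard deviation decreases with
#' `p_r` and flattens out near `p_r = 0.3`.
#'
#' @param n Number of nodes (at least 2).
#' @param p_r Rewiring probability in \[0, 1\] (typical studies use
#'   \[0, 0.3\]).
#' @param seed Optional integer seed.
#' @return A connected [igraph::igraph] graph.
#' @export
replace_links_model <- function(n, p_r, seed = NULL) {
  if (!is.numeric(p_r) || length(p_r) != 1L || p_r < 0 || p_r > 1) {
    stop("`p_r` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- add_links_model(n, p_r)
  m <- igraph::ecount(g) - (n - 1L)
  if (m > 0) {
    drop <- sample.int(igraph::ecount(g), m)
    g <- igraph::delete_edges(g, drop)
    pick_one <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
    comp <- igraph::components(g)
    while (comp$no > 1L) {
      pick <- sample.int(comp$no, 2L)
      a <- pick_one(which(comp$membership == pick[1L]))
      b <- pick_one(which(comp$membership == pick[2L]))
      g <- igraph::add_edges(g, c(a, b))
      comp <- igraph::components(g)
    }
  }
  g
}

#' Is the graph connected?
#'
#' `TRUE` iff the graph has a single connected component, i.e. a path
#' exists between any two nodes. All generators in this package emit
#' connected graphs; this predicate is the contract check.
#'
#' @param g An [igraph::igraph] graph.
#' @return Logical scalar.
#' @export
is_connected_graph <- function(g) {
  igraph::is_connected(g, mode = "weak")
}

#' Row-stochastic weighted adjacency with static self-weights
#'
#' Builds the dense weight matrix of the naive-averaging update: agent `i`
#' keeps self-weight `w[i]` on its own opinion and spreads the remaining
#' `1 - w[i]` equally over its neighbors. Every row sums to one, so one
#' synchronous update is `x' = A %*% x`.
#'
#' @param g An [igraph::igraph] graph.
#' @param self_weights Numeric vector of per-node self-weights in
#'   \[0, 1\], one per node. A scalar is recycled.
#' @return A dense `n x n` row-stochastic matrix.
#' @export
build_static_adjacency <- function(g, self_weights) {
  n <- igraph::vcount(g)
  w <- rep_len(as.numeric(self_weights), n)
  if (length(self_weights) != 1L && length(self_weights) != n) {
    stop("`self_weights` must have length 1 or n", call. = FALSE)
  }
  if (any(w < 0 | w > 1)) {
    stop("self-weights must lie in [0, 1]", call. = FALSE)
  }
  deg <- igraph::degree(g)
  if (any(deg == 0 & w < 1)) {
    stop("node with no neighbors cannot distribute social weight 1 - w",
         call. = FALSE)
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  social <- ifelse(deg > 0, (1 - w) / pmax(deg, 1L), 0)
  a <- adj * social            # row i gets (1 - w_i)/deg_i on each neighbor
  diag(a) <- w
  a
}

#' Eigenvalue moduli of a row-stochastic adjacency
#'
#' Returns the moduli of the eigenvalues of a row-stochastic weight
#' matrix, sorted in decreasing order. For any weight matrix of a
#' connected network the leading modulus is exactly one; the
#' second-largest modulus governs the convergence rate of linear
#' averaging dynamics.
#'
#' @param a A row-stochastic square matrix (rows summing to one).
#' @param tol Tolerance for the row-sum contract check.
#' @return Numeric vector of eigenvalue moduli, decreasing.
#' @export
spectral_summary <- function(a, tol = 1e-8) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("`a` must be square", call. = FALSE)
  if (any(abs(rowSums(a) - 1) > tol)) {
    stop("`a` is not row-stochastic (rows must sum to 1)", call. = FALSE)
  }
  sort(Mod(eigen(a, only.values = TRUE)$values), decreasing = TRUE)
}
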