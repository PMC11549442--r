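# Independent per-replicate seeds derived from one master seed; kept below
# .Machine$integer.max so they are valid arguments to set.seed().
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Logarithmic parameter grid anchored at zero
#'
#' Heterogeneity parameters are swept on a log scale so that the region
#' near zero — where the transition away from homogeneity (or away from
#' the pure star) happens — is sampled densely. Returns `n` geometrically
#' spaced points on `(max_value * min_ratio, max_value]`, optionally
#' prefixed with an explicit 0.
#'
#' @param max_value Upper end of the grid (positive).
#' @param n Number of positive grid points.
#' @param min_ratio Ratio of the smallest positive point to `max_value`.
#' @param include_zero Prepend 0 (default `TRUE`).
#' @return Increasing numeric vector.
#' @export
log_grid <- function(max_value, n, min_ratio = 1e-3, include_zero = TRUE) {
  if (max_value <= 0 || n < 1) stop("need max_value > 0 and n >= 1", call. = FALSE)
  pts <- max_value * min_ratio^(rev(seq_len(n) - 1) / max(n - 1, 1))
  if (include_zero) pts <- c(0, pts)
  pts
}

generate_graph <- function(model, n, params, k = 6) {
  switch(model,
    star = make_star_graph(n),
    regular = make_k_regular(n, k),
    add = add_links_model(n, params$p_w %||% 0),
    replace = replace_links_model(n, params$p_r %||% 0),
    stop("unknown graph model: ", model, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

generate_beliefs <- function(g, params, x_neutral = 0) {
  n <- igraph::vcount(g)
  if (!is.null(params$rho_model)) {
    sample_centrality_correlated(
      g, rho_model = params$rho_model, K_model = params$K_model %||% 5,
      c_true = params$c_true %||% 5, p_true = params$p_true %||% 0,
      x_neutral = x_neutral)
  } else if (!is.null(params$c_model)) {
    sample_mismatched_uncorrelated(
      n, c_model = params$c_model, p_model = params$p_model %||% 0,
      c_true = params$c_true %||% 5, p_true = params$p_true %||% 0,
      x_neutral = x_neutral)
  } else {
    sample_initial_beliefs(
      n, c_inf = params$c_inf %||% 5, p_inf = params$p_inf %||% 0,
      x_neutral = x_neutral)
  }
}

#' Monte-Carlo parameter sweep over rules and conditions
#'
#' Runs the full pipeline — generate a connected graph, sample initial
#' beliefs, simulate `t_steps` synchronous updates, record final-step
#' errors — `n_reps` times for every row of a parameter grid and every
#' update rule, and aggregates per cell. Within one replicate all rules
#' consume the *same* graph and initial beliefs (shared derived seeds),
#' so rule comparisons are paired. A fresh graph and fresh beliefs are
#' drawn for every replicate. Results are bit-reproducible given
#' `master_seed`.
#'
#' @param grid Data frame of sweep cells. Recognized columns:
#'   `p_r` / `p_w` (network heterogeneity; selects the matching graph
#'   model column when `graph_model` is `"replace"` / `"add"`), `c_inf`,
#'   `p_inf` (matched information sampling), `c_model`, `p_model`
#'   (uncorrelated uncertainty-assignment errors), `rho_model`,
#'   `K_model` (centrality-correlated errors), `c_true`, `p_true`.
#'   Missing columns fall back to defaults (`c_inf = 5`, `p_inf = 0`,
#'   `p_r = 0`, `K_model = 5`).
#' @param rules Character vector from `"bi-ai"`, `"bi-ud"`, `"na-lew"`,
#'   `"na"` (mean over the universal-weight grid), `"na-ouw"` (best
#'   universal weight per cell).
#' @param n_reps Monte-Carlo replicates per cell.
#' @param n_agents Collective size (default 100).
#' @param t_steps Simulation horizon (default 10).
#' @param graph_model `"replace"`, `"add"`, `"regular"`, or `"star"`.
#' @param k Degree for `graph_model = "regular"`.
#' @param w_grid Universal-weight grid used by `"na"` and `"na-ouw"`.
#' @param x_neutral Neutral opinion.
#' @param master_seed Integer master seed.
#' @return A `sweep_result`: list with `runs` (one row per cell, rule,
#'   and replicate: final `E_P`, `E_T`, `E_A`, `E_P_norm`, plus
#'   `w_global` for the tuned rule), `cells` (per-cell, per-rule means
#'   and standard deviations), the `grid`, and the configuration.
#' @export
run_sweep <- function(grid, rules = c("bi-ai", "bi-ud", "na-lew"),
                      n_reps = 20, n_agents = 100, t_steps = 10,
                      graph_model = c("replace", "add", "regular", "star"),
                      k = 6, w_grid = seq(0, 1, by = 0.1),
                      x_neutral = 0, master_seed = 1) {
  graph_model <- match.arg(graph_model)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("`grid` must have at least one row", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  rules <- vapply(rules, function(r) {
    tolower(match.arg(tolower(r), c("bi-ai", "bi-ud", "na-lew", "na", "na-ouw")))
  }, character(1), USE.NAMES = FALSE)

  # Common random numbers: the same replicate seeds are reused in every
  # cell (and all rules within a replicate consume the same graph and
  # beliefs), so comparisons across cells and rules are paired. Cells
  # remain independent of one another: dropping a cell changes nothing
  # elsewhere.
  rep_seeds <- derive_seeds(master_seed, n_reps)
  needs_w_grid <- any(rules %in% c("na", "na-ouw"))
  base_rules <- setdiff(rules, c("na", "na-ouw"))

  runs <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    params <- as.list(grid[ci, , drop = FALSE])
    rows <- list()
    w_ea <- if (needs_w_grid) matrix(NA_real_, n_reps, length(w_grid))
    w_ep <- w_et <- w_epn <- w_ea
    base_fin <- array(NA_real_, c(n_reps, length(base_rules), 4L))

    for (r in seq_len(n_reps)) {
      set.seed(rep_seeds[r])
      g <- generate_graph(graph_model, n_agents, params, k)
      b <- generate_beliefs(g, params, x_neutral)
      for (bi in seq_along(base_rules)) {
        traj <- simulate_opinions(g, b, base_rules[bi], t_steps = t_steps,
                                  x_neutral = x_neutral)
        f <- final_metrics(traj)
        base_fin[r, bi, ] <- c(f$E_P, f$E_T, f$E_A, f$E_P_norm)
      }
      if (needs_w_grid) {
        for (j in seq_along(w_grid)) {
          traj <- simulate_opinions(g, b, "na", w_global = w_grid[j],
                                    t_steps = t_steps, x_neutral = x_neutral)
          f <- final_metrics(traj)
          w_ep[r, j] <- f$E_P; w_et[r, j] <- f$E_T
          w_ea[r, j] <- f$E_A; w_epn[r, j] <- f$E_P_norm
        }
      }
    }

    mk_rows <- function(rule, ep, et, ea, epn, w = NA_real_) {
      cbind(grid[rep(ci, n_reps), , drop = FALSE],
            data.frame(cell = ci, rule = rule, rep = seq_len(n_reps),
                       seed = rep_seeds, w_global = w,
                       E_P = ep, E_T = et, E_A = ea, E_P_norm = epn,
                       row.names = NULL))
    }
    for (bi in seq_along(base_rules)) {
      rows[[length(rows) + 1L]] <- mk_rows(
        base_rules[bi], base_fin[, bi, 1L], base_fin[, bi, 2L],
        base_fin[, bi, 3L], base_fin[, bi, 4L])
    }
    if ("na" %in% rules) {
      rows[[length(rows) + 1L]] <- mk_rows(
        "na", rowMeans(w_ep), rowMeans(w_et), rowMeans(w_ea), rowMeans(w_epn))
    }
    if ("na-ouw" %in% rules) {
      j_opt <- which.min(colMeans(w_ea))
      rows[[length(rows) + 1L]] <- mk_rows(
        "na-ouw", w_ep[, j_opt], w_et[, j_opt], w_ea[, j_opt],
        w_epn[, j_opt], w = w_grid[j_opt])
    }
    runs[[ci]] <- do.call(rbind, rows)
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL

  agg <- stats::aggregate(
    runs[, c("E_P", "E_T", "E_A", "E_P_norm")],
    by = list(cell = runs$cell, rule = runs$rule), FUN = mean)
  sds <- stats::aggregate(
    runs[, c("E_P", "E_T", "E_A", "E_P_norm")],
    by = list(cell = runs$cell, rule = runs$rule), FUN = stats::sd)
  names(sds)[-(1:2)] <- paste0(names(sds)[-(1:2)], "_sd")
  cells <- merge(cbind(grid, cell = seq_len(nrow(grid))),
                 merge(agg, sds, by = c("cell", "rule")), by = "cell")
  cells <- cells[order(cells$cell, cells$rule), ]
  rownames(cells) <- NULL

  structure(
    list(runs = runs, cells = cells, grid = grid,
         config = list(rules = rules, n_reps = n_reps, n_agents = n_agents,
                       t_steps = t_steps, graph_model = graph_model, k = k,
                       w_grid = w_grid, x_neutral = x_neutral,
                       master_seed = master_seed)),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells x %d rules x %d reps (N = %d, T = %d)\n",
              nrow(x$grid), length(x$config$rules), x$config$n_reps,
              x$config$n_agents, x$config$t_steps))
  print(utils::head(x$cells, 12L))
  invisible(x)
}

#' Sweep over uncertainty-quantification error models
#'
#' Convenience wrapper around [run_sweep()] for the two mismatch
#' studies. In `"uncorrelated"` mode the grid spans the assigned-window
#' center `c_model` (over-confident below the true 5, under-confident
#' above) against the assigned heterogeneity `p_model`. In
#' `"correlated"` mode it spans the centrality–certainty correlation
#' `rho_model` against the network heterogeneity `p_r`. Opinions are
#' always drawn from the homogeneous true noise (`c_true = 5`,
#' `p_true = 0`).
#'
#' @param mode `"uncorrelated"` or `"correlated"`.
#' @param grid Optional custom grid; defaults to a 5 x 5 grid over the
#'   studied ranges (`c_model` in \[2.5, 7.5\] x `p_model` in \[0, 5\],
#'   or `rho_model` in \[-1, 1\] x `p_r` in \[0, 0.3\]).
#' @param rules Rules to compare (default the two Bayesian rules).
#' @param K_model Scale of the correlated assignment (default 5).
#' @param ... Passed to [run_sweep()].
#' @return A `sweep_result`.
#' @export
run_error_model_study <- function(mode = c("uncorrelated", "correlated"),
                                  grid = NULL,
                                  rules = c("bi-ai", "bi-ud"),
                                  K_model = 5, ...) {
  mode <- match.arg(mode)
  if (is.null(grid)) {
    grid <- if (mode == "uncorrelated") {
      expand.grid(c_model = seq(2.5, 7.5, length.out = 5),
                  p_model = log_grid(5, 4))
    } else {
      expand.grid(rho_model = seq(-1, 1, length.out = 5),
                  p_r = log_grid(0.3, 4))
    }
  }
  if (mode == "correlated" && is.null(grid$K_model)) grid$K_model <- K_model
  if (mode == "uncorrelated" && is.null(grid$c_model)) {
    stop('uncorrelated mode needs a `c_model` column', call. = FALSE)
  }
  if (mode == "correlated" && is.null(grid$rho_model)) {
    stop('correlated mode needs a `rho_model` column', call. = FALSE)
  }
  run_sweep(grid, rules = rules, ...)
}

#' Centrality shift induced by a single highly certain agent
#'
#' Reproduces the qualitative uncertainty–centrality experiment: on a
#' random connected k-regular graph every agent starts with the same
#' variance except one seeded agent whose variance is
#' `certainty_factor` times smaller. Under inverse-variance fusion the
#' seeded agent initially dominates the dynamic in-degree centrality;
#' its direct neighbors, facing a far more certain peer, are initially
#' the *least* central; and as certainty propagates, the most central
#' node shifts away from the seeded agent toward the moving border
#' between certain and uncertain regions.
#'
#' @param n Number of agents (default 26).
#' @param k Degree (default 6).
#' @param sigma0 Common initial noise standard deviation (default 5).
#' @param certainty_factor Variance ratio between ordinary agents and
#'   the seeded agent (default 100).
#' @param seeded Index of the seeded agent (default 1).
#' @param t_steps Horizon (default 10).
#' @param seed Integer seed.
#' @return A list with the `graph`, the seeded index, its `neighbors`,
#'   the initial `beliefs`, the full `trajectory`, the per-step
#'   `in_degree` matrix (row `t` is the centrality of the update from
#'   `t - 1` to `t`), and `argmax` (most central node per step).
#' @export
reproduce_centrality_shift <- function(n = 26, k = 6, sigma0 = 5,
                                       certainty_factor = 100, seeded = 1,
                                       t_steps = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- make_k_regular(n, k)
  sigma2 <- rep(sigma0^2, n)
  sigma2[seeded] <- sigma0^2 / certainty_factor
  mu <- stats::rnorm(n, 0, sigma0)
  b <- belief_state(mu, sigma2)
  traj <- simulate_opinions(g, b, "bi-ai", t_steps = t_steps,
                            record_in_degree = TRUE)
  list(
    graph = g,
    seeded = seeded,
    neighbors = as.integer(igraph::neighbors(g, seeded)),
    beliefs = b,
    trajectory = traj,
    in_degree = traj$in_degree,
    argmax = apply(traj$in_degree, 1L, which.max)
  )
}
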