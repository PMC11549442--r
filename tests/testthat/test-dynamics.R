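test_that("locally-equal weights split mass evenly over closed neighborhoods", {
  g <- make_star_graph(5)
  expect_equal(weights_lew(g), c(1/5, rep(1/2, 4)), ignore_attr = TRUE)
  gr <- make_k_regular(26, 6, seed = 1)
  expect_equal(weights_lew(gr), rep(1/7, 26), ignore_attr = TRUE)
})

test_that("naive step matches hand-evaluated averaging", {
  # path 2 - 1 - 3 (node 1 is the hub), opinions (0, 3, 9)
  g <- make_star_graph(3)
  x <- c(0, 3, 9)
  out <- step_naive(x, g, c(1/3, 1/2, 1/2))
  expect_equal(out, c((0 + 3 + 9) / 3, (3 + 0) / 2, (9 + 0) / 2))

  # consensus is a fixed point; full self-weight is the identity
  expect_equal(step_naive(rep(2.5, 3), g, weights_lew(g)), rep(2.5, 3))
  expect_equal(step_naive(x, g, rep(1, 3)), x)

  # complete graph with LEW: one step is the global arithmetic mean
  gc <- add_links_model(7, 1)
  xc <- stats::rnorm(7)
  expect_equal(step_naive(xc, gc, weights_lew(gc)), rep(mean(xc), 7))
})

test_that("BI-AI equals closed-form inverse-variance fusion", {
  g <- make_star_graph(2)
  out <- step_bi_ai(belief_state(c(0, 2), c(1, 1)), g)
  expect_equal(out$mu[1], 1)
  expect_equal(out$sigma2[1], 0.5)

  g4 <- make_star_graph(4)
  out4 <- step_bi_ai(belief_state(rep(0, 4), rep(1, 4)), g4)
  expect_equal(out4$sigma2[1], 0.25)  # 1 / (1 + 3)
})

test_that("BI-AI matches the sequential Kalman oracle", {
  set.seed(11)
  for (i in 1:200) {
    nb <- random_neighborhood()
    out <- step_bi_ai(nb$b, nb$g)
    oracle <- kalman_fuse(nb$b$mu[1], nb$b$sigma2[1],
                          nb$b$mu[-1], nb$b$sigma2[-1])
    expect_lt(abs(out$mu[1] - oracle["mu"]) / max(1, abs(oracle["mu"])), 1e-12)
    expect_lt(abs(out$sigma2[1] - oracle["sigma2"]) /
                max(1, abs(oracle["sigma2"])), 1e-12)
  }
})

test_that("BI-UD is a conservative fusion bounded by neighborhood variances", {
  g <- make_star_graph(2)
  out <- step_bi_ud(belief_state(c(0, 4), c(1, 4)), g)
  expect_equal(out$mu[1], 0.8)
  expect_equal(out$sigma2[1], 1.25 / 1.0625)

  # equal variances are left unchanged
  g4 <- make_star_graph(4)
  same <- step_bi_ud(belief_state(stats::rnorm(4), rep(3.7, 4)), g4)
  expect_equal(same$sigma2, rep(3.7, 4), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:200) {
    nb <- random_neighborhood()
    out <- step_bi_ud(nb$b, nb$g)
    expect_gte(out$sigma2[1], min(nb$b$sigma2) - 1e-12)
    expect_lte(out$sigma2[1], max(nb$b$sigma2) + 1e-12)
    # mean agrees with the independence-assuming mean (same Eq-5 weights)
    expect_equal(out$mu[1], step_bi_ai(nb$b, nb$g)$mu[1], tolerance = 1e-12)
  }
})

test_that("homogeneous uncertainty reduces BI-AI means to LEW averaging", {
  set.seed(13)
  for (s in 1:10) {
    g <- replace_links_model(30, 0.2, seed = s)
    mu <- stats::rnorm(30, 0, 5)
    b <- belief_state(mu, rep(4, 30))
    expect_equal(step_bi_ai(b, g)$mu, step_naive(mu, g, weights_lew(g)),
                 tolerance = 1e-12)
  }
})

test_that("effective adjacency is row-stochastic and tracks precision", {
  gr <- make_k_regular(26, 6, seed = 2)
  b_hom <- belief_state(stats::rnorm(26), rep(25, 26))
  a_bi <- effective_adjacency(gr, "bi-ai", beliefs = b_hom)
  a_lew <- build_static_adjacency(gr, weights_lew(gr))
  expect_equal(a_bi, a_lew, tolerance = 1e-12)

  sig <- rep(25, 26); sig[4] <- 0.25
  a_het <- effective_adjacency(gr, "bi-ai", beliefs = belief_state(rep(0, 26), sig))
  expect_equal(rowSums(a_het), rep(1, 26), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(which.max(in_degree(a_het)), 4)

  expect_error(effective_adjacency(gr, "bi-ai"), "beliefs")
  expect_error(effective_adjacency(gr, "na"), "w_global")
  a_na <- effective_adjacency(gr, "na", w_global = 0.3)
  expect_equal(diag(a_na), rep(0.3, 26), ignore_attr = TRUE)
})

test_that("simulation is synchronous, convex, and order-independent", {
  g <- replace_links_model(40, 0.2, seed = 14)
  b <- sample_initial_beliefs(40, p_inf = 4, seed = 15)

  for (rule in c("bi-ai", "bi-ud", "na-lew")) {
    traj <- simulate_opinions(g, b, rule, t_steps = 8)
    rng <- apply(traj$mu, 1, function(r) diff(range(r)))
    expect_true(all(diff(rng) <= 1e-12))  # opinion range never expands
    expect_equal(traj$mu[1, ], b$mu)
  }

  # BI-AI variance strictly decreases every step for every agent
  traj_ai <- simulate_opinions(g, b, "bi-ai", t_steps = 8)
  expect_true(all(diff(traj_ai$sigma2) < 0))

  # frozen agents: w_global = 1 keeps the trajectory constant
  traj_frozen <- simulate_opinions(g, b, "na", w_global = 1, t_steps = 5)
  expect_true(all(traj_frozen$mu == rep(b$mu, each = 6)))

  # permutation equivariance: relabeling agents relabels the trajectory
  perm <- sample(40)
  gp <- igraph::permute(g, perm)                        # old i -> new perm[i]
  bp <- belief_state(b$mu[order(perm)], b$sigma2[order(perm)])
  tp <- simulate_opinions(gp, bp, "bi-ai", t_steps = 8)
  expect_equal(tp$mu[, perm], traj_ai$mu, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tp$sigma2[, perm], traj_ai$sigma2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("star hub pulls the collective mean under naive averaging", {
  set.seed(16)
  g <- make_star_graph(50)
  b <- sample_initial_beliefs(50, p_inf = 4, seed = 17)
  traj <- simulate_opinions(g, b, "na-lew", t_steps = 10)
  gap <- abs(traj$metrics$x_col - traj$mu[, 1])
  expect_lt(gap[11], gap[1])
})

test_that("trajectory metrics satisfy the error identity and normalization", {
  g <- replace_links_model(30, 0.1, seed = 18)
  b <- sample_initial_beliefs(30, p_inf = 3, seed = 19)
  traj <- simulate_opinions(g, b, "bi-ud")
  m <- traj$metrics
  expect_equal(m$E_A, m$E_P + m$E_T, tolerance = 1e-10)
  expect_equal(m$E_P_norm[1], 1)
  expect_equal(final_metrics(traj)$step, 10)
})

test_that("universal-weight search returns the grid argmin", {
  graph_fn <- function() add_links_model(15, 1)
  belief_fn <- function(g) sample_initial_beliefs(15, p_inf = 3)

  one <- optimize_universal_weight(graph_fn, belief_fn, grid = 0.4,
                                   reps = 3, seed = 20)
  expect_equal(one$w_optimal, 0.4)

  o <- optimize_universal_weight(graph_fn, belief_fn, reps = 15, seed = 21)
  # on a homogeneous complete graph fast averaging is optimal and frozen
  # agents (w = 1) are never selected
  expect_lt(o$w_optimal, 1)
  expect_equal(o$w_optimal, 0)
  expect_equal(unname(o$mean_E_A["1.0"]), max(o$mean_E_A))
  expect_gt(o$grid_mean_E_A, min(o$mean_E_A))

  expect_error(optimize_universal_weight(graph_fn, belief_fn,
                                         grid = numeric(0)), "grid")
})
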