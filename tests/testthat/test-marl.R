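test_that("agent grouping is contiguous and balanced", {
  expect_identical(strainrl:::agent_groups(4L, 2L), c(1L, 1L, 2L, 2L))
  expect_identical(strainrl:::agent_groups(4L, 1L), rep(1L, 4))
  expect_identical(strainrl:::agent_groups(4L, 4L), 1:4)
  expect_identical(strainrl:::agent_groups(5L, 2L), c(1L, 1L, 1L, 2L, 2L))
})

test_that("marl_config validates its fields", {
  cfg <- marl_config()
  expect_identical(cfg$n_agents, 4L)
  expect_identical(cfg$n_groups, 2L)
  expect_identical(cfg$tau, 5L)
  expect_identical(cfg$n_iterations, 40L)
  expect_equal(cfg$perturb_c, 0.8)
  expect_identical(cfg$replace_every_k, 5L)
  expect_equal(cfg$upper_quantile, 0.75)
  expect_identical(cfg$predict, "sum")
  expect_error(marl_config(n_groups = 5L), "n_groups")
  expect_error(marl_config(perturb_c = 1.5))
  expect_error(marl_config(predict = "magic"))
})

test_that("latin_hypercube respects bounds and degenerate input", {
  bounds <- rbind(lo = c(0, -2), hi = c(1, 2))
  set.seed(1)
  X <- latin_hypercube(10, bounds)
  expect_true(all(X[, 1] >= 0 & X[, 1] <= 1))
  expect_true(all(X[, 2] >= -2 & X[, 2] <= 2))
  expect_warning(latin_hypercube(3, rbind(c(1, 0), c(1, 1))), "degenerate")
})

test_that("warmup bookkeeping: tau rows per agent, reward chaining", {
  env <- make_surface_env(3, seed = 2)
  cfg <- marl_config(n_agents = 2L, tau = 1L)
  wd <- warmup(env, cfg)
  expect_identical(nrow(wd$designs), 2L) # members x 1 rows
  cfg2 <- marl_config(n_agents = 2L, tau = 4L)
  wd2 <- warmup(env, cfg2)
  expect_identical(nrow(wd2$designs), 8L)
  # first reward of each agent is measured against the wild-type baseline
  for (i in 1:2) {
    first <- which(wd2$agent == i & wd2$round == 1)
    expect_equal(wd2$rewards[first],
                 wd2$responses[first] - env$baseline_response)
    # subsequent rewards chain the agent's own responses
    rows <- which(wd2$agent == i)
    expect_equal(wd2$rewards[rows][-1], diff(wd2$responses[rows]))
  }
  # actions are the executed design deltas
  r1 <- which(wd2$agent == 1)[1]
  expect_equal(wd2$actions[r1, ], wd2$designs[r1, ] - env$baseline_design)
})

test_that("init_enzyme_levels seeds agent 1 from the upper quantile", {
  env <- make_surface_env(2, seed = 1)
  cfg <- marl_config(n_agents = 3L, tau = 2L, upper_quantile = 0.75)
  wd <- warmup(env, cfg)
  # hand oracle: top ceiling(0.25 * 6) = 2 designs, coordinate-wise median
  set.seed(cfg$seed) # starts 2..n are random LHS; only check agent 1
  top <- order(wd$responses, decreasing = TRUE)[1:2]
  expected <- apply(wd$designs[top, , drop = FALSE], 2, median)
  starts <- init_enzyme_levels(wd, env, cfg)
  expect_equal(starts[1, ], expected)
  expect_identical(dim(starts), c(3L, 2L))
  # single-element top set: quantile high enough that k = 1
  cfg2 <- marl_config(n_agents = 2L, tau = 2L, upper_quantile = 0.9)
  wd2 <- warmup(env, cfg2)
  s2 <- init_enzyme_levels(wd2, env, cfg2)
  expect_equal(s2[1, ], wd2$designs[which.max(wd2$responses), ])
})

test_that("gram_schmidt produces an orthonormal set and flags replacements", {
  set.seed(21)
  V <- matrix(rnorm(12), 3, 4)
  gs <- gram_schmidt(V)
  G <- tcrossprod(gs$vectors)
  expect_equal(G, diag(3), tolerance = 1e-10)
  expect_false(any(gs$replaced))
  # dependent vector gets replaced but output stays orthonormal
  V2 <- rbind(c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  gs2 <- gram_schmidt(V2)
  expect_true(gs2$replaced[2])
  expect_equal(tcrossprod(gs2$vectors), diag(3), tolerance = 1e-10)
  # more vectors than dimensions: the overflow is flagged
  V3 <- matrix(rnorm(6), 3, 2)
  gs3 <- gram_schmidt(V3)
  expect_true(gs3$replaced[3])
})

test_that("perturb_agents preserves norms and handles zero actions", {
  set.seed(31)
  A <- matrix(rnorm(8), 2, 4)
  P <- perturb_agents(A, 0.8)
  expect_equal(sqrt(rowSums(P^2)), sqrt(rowSums(A^2)), tolerance = 1e-9)
  # c = 0 keeps the first (Gram-Schmidt pivot) action unchanged
  P0 <- perturb_agents(A, 0)
  expect_equal(P0, A, tolerance = 1e-9)
  # zero action receives a small random direction of norm 1e-3
  Z <- rbind(c(1, 0), c(0, 0))
  PZ <- perturb_agents(Z, 0.8)
  expect_equal(sqrt(sum(PZ[2, ]^2)), 1e-3, tolerance = 1e-9)
})

test_that("replace_worst follows the median rule with deterministic ties", {
  designs <- diag(4)
  series <- list(c(3, 3), c(2, 2), c(4, 4), c(1, 1))
  set.seed(2)
  out <- replace_worst(designs, series)
  expect_identical(out$worst, 4L)
  expect_true(out$donor %in% 1:3)
  expect_equal(out$designs[4, ], designs[out$donor, ])
  # identical medians: lowest index replaced
  set.seed(2)
  out2 <- replace_worst(diag(2), list(c(1, 1), c(1, 1)))
  expect_identical(out2$worst, 1L)
  expect_identical(out2$donor, 2L)
})

test_that("run_marl: log shape, budget, monotone best-found, determinism", {
  env <- make_surface_env(3, seed = 5)
  cfg <- marl_config(n_agents = 4L, tau = 3L, n_iterations = 6L, seed = 11L)
  run <- run_marl(env, cfg)
  expect_s3_class(run, "strain_run")
  # log row count = n_agents x (tau + n_iterations)
  expect_identical(nrow(run$log), 4L * (3L + 6L))
  expect_identical(run$n_env_calls, 4L * (3L + 6L))
  expect_setequal(unique(run$log$phase), c("warmup", "optimize"))
  # best-found non-decreasing per agent and best_response consistent
  bf <- best_found(run)
  for (a in unique(bf$agent)) {
    expect_true(all(diff(bf$best_found[bf$agent == a]) >= 0))
  }
  expect_equal(max(run$log$response), run$best_response)
  # designs stay inside the box
  dcols <- as.matrix(run$log[, paste0("d", 1:3)])
  expect_true(all(dcols >= env$bounds[1, 1] - 1e-12 &
                  dcols <= env$bounds[2, 1] + 1e-12))
  # determinism
  run2 <- run_marl(env, cfg)
  expect_identical(run$log, run2$log)
  expect_equal(run$best_design, run2$best_design)
  # different seed gives a different trajectory
  cfg3 <- cfg; cfg3$seed <- 12L
  run3 <- run_marl(env, cfg3)
  expect_false(identical(run$log$response, run3$log$response))
})

test_that("run_marl accepts a shared precomputed warm-up", {
  env <- make_surface_env(3, seed = 5)
  cfg <- marl_config(tau = 3L, n_iterations = 4L, seed = 2L)
  wd <- warmup(env, cfg)
  r1 <- run_marl(env, cfg, warmup_data = wd)
  r2 <- run_marl(env, cfg)
  expect_identical(r1$log, r2$log) # same seed -> same warm-up -> same run
  bad <- marl_config(tau = 2L, n_iterations = 4L, seed = 2L)
  expect_error(run_marl(env, bad, warmup_data = wd))
})

test_that("plateau stop terminates early when enabled", {
  env <- make_surface_env(3, seed = 5)
  cfg <- marl_config(tau = 2L, n_iterations = 30L, seed = 1L,
                     plateau_patience = 3L)
  run <- run_marl(env, cfg)
  expect_lte(max(run$log$round), 2L + 30L)
  full <- marl_config(tau = 2L, n_iterations = 30L, seed = 1L)
  run_full <- run_marl(env, full)
  expect_identical(max(run_full$log$round), 32L)
})

test_that("the preimage prediction option runs and improves the surface result", {
  env <- make_surface_env(4, seed = 1)
  base <- marl_config(tau = 3L, n_iterations = 10L, seed = 1L)
  pre <- marl_config(tau = 3L, n_iterations = 10L, seed = 1L,
                     predict = "preimage")
  r_base <- run_marl(env, base)
  r_pre <- run_marl(env, pre)
  expect_identical(nrow(r_pre$log), nrow(r_base$log))
  # not asserted to dominate on one tiny run; both must stay valid runs
  expect_true(is.finite(r_pre$best_response))
})
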