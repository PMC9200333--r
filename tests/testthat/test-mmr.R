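test_that("margin transform matches the closed forms and clamps the domain", {
  expect_equal(margin_transform(c(0, 1, 3)), c(0, 1, 2))
  expect_equal(margin_transform(-1), log2(1e-6))
  expect_equal(margin_transform(-5), margin_transform(-1)) # clamped
  expect_error(margin_transform(NA_real_), "finite")
  expect_error(margin_transform(Inf), "finite")
  r <- seq(-0.99, 5, by = 0.07)
  expect_true(all(diff(margin_transform(r)) > 0)) # strictly increasing
})

test_that("gaussian kernel: analytic values, symmetry, errors", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 3), 1)
  x <- c(0, 0); x2 <- c(2, 0) # distance 2 = sigma
  expect_equal(gaussian_kernel(x, x2, 2), exp(-1))
  set.seed(1)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(gaussian_kernel(a, b, 2), exp(-sum((a - b)^2) / 4))
  expect_equal(gaussian_kernel(a, b, 2), gaussian_kernel(b, a, 2))
  expect_error(gaussian_kernel(1:2, 1:3, 1), "equal length")
  expect_error(gaussian_kernel(1:2, 2:3, -1), "positive")
})

test_that("joint kernel matrix is symmetric PSD with unit diagonal", {
  expect_error(joint_kernel_matrix(mmr_history(matrix(1, 1, 1)[0, , drop = FALSE],
                                               matrix(1, 1, 1)[0, , drop = FALSE],
                                               numeric(0)), 1, 1),
               "empty")
  h1 <- mmr_history(matrix(1:2, 1), matrix(3:4, 1), 0.5)
  expect_equal(joint_kernel_matrix(h1, 1, 1), matrix(1, 1, 1))
  h2 <- mmr_history(rbind(c(1, 2), c(1, 2)), rbind(c(0, 1), c(0, 1)), c(1, 1))
  expect_equal(joint_kernel_matrix(h2, 2, 2), matrix(1, 2, 2))
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    h <- mmr_history(matrix(rnorm(n * 3), n), matrix(rnorm(n * 2), n),
                     rnorm(n))
    K <- joint_kernel_matrix(h, runif(1, 0.5, 3), runif(1, 0.5, 3))
    expect_equal(K, t(K))
    expect_equal(unname(diag(K)), rep(1, n))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("median heuristic bandwidth matches brute force and guards zeros", {
  expect_equal(median_heuristic_bandwidth(rbind(c(0, 0), c(2, 0))), 2)
  X <- rbind(0, 1, 2) # collinear, distances 1, 1, 2
  expect_equal(median_heuristic_bandwidth(X), 1)
  set.seed(7)
  Y <- matrix(rnorm(40), 20)
  expect_equal(median_heuristic_bandwidth(Y),
               median(as.numeric(dist(Y))))
  expect_warning(out <- median_heuristic_bandwidth(rbind(c(1, 1), c(1, 1))),
                 "identical")
  expect_equal(out, 1.0)
})

test_that("box QP solver: closed forms and KKT certificates", {
  # scalar: min .5 b^2 - b on [0, 10] -> b = 1
  sol <- solve_box_qp(matrix(1), 1, 10)
  expect_equal(sol$beta, 1, tolerance = 1e-8)
  # non-positive linear term -> zero
  sol <- solve_box_qp(diag(3), c(0, -1, -5), 2)
  expect_equal(sol$beta, rep(0, 3))
  # 2x2 against a dense grid at resolution 1e-3
  K <- matrix(c(1, 0.6, 0.6, 1), 2)
  m <- c(1.2, 0.3)
  sol <- solve_box_qp(K, m, 1)
  g <- as.matrix(expand.grid(seq(0, 1, 1e-3), seq(0, 1, 1e-3)))
  vals <- 0.5 * rowSums((g %*% K) * g) - g %*% m
  expect_lte(sol$value, min(vals) + 1e-6)
  # KKT residual small on random PSD problems
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    A <- matrix(rnorm(n^2), n)
    K <- crossprod(A) / n + diag(1e-6, n)
    m <- rnorm(n)
    C <- runif(1, 0.5, 3)
    sol <- solve_box_qp(K, m, C)
    expect_true(sol$converged)
    expect_lt(strainrl:::box_qp_kkt_residual(K, m, C, sol$beta), 1e-6)
  }
})

test_that("box QP survives near-singular kernels (flat directions)", {
  # duplicated rows make K singular; objective-based stop must kick in
  K <- matrix(1, 4, 4)
  sol <- solve_box_qp(K, c(2, 2, 2, 2), 1)
  expect_true(sol$converged)
  expect_lt(strainrl:::box_qp_kkt_residual(K, c(2, 2, 2, 2), 1, sol$beta), 1e-6)
})

test_that("mmr fit: support at high reward, box feasibility, dual route check", {
  h <- mmr_history(states = rbind(c(0, 0), c(3, 3), c(-3, 2)),
                   actions = rbind(c(1, 0), c(0, 1), c(-1, 0)),
                   rewards = c(2.5, -0.9, -0.95))
  fit <- mmr(h, sigma_s = 1, sigma_a = 1, c_xi = 1)
  expect_s3_class(fit, "mmr")
  expect_gt(fit$beta[1], 0)  # the positive-reward triplet is a support vector
  expect_true(all(fit$beta >= 0 & fit$beta <= 1))
  # independent certified solver route (kernlab::ipop) agrees on the
  # objective, on a well-conditioned instance with interior solutions
  skip_if_not_installed("kernlab")
  h2 <- mmr_history(states = rbind(c(0, 0), c(2, 1), c(-1, 2)),
                    actions = rbind(c(1, 0), c(0, 1), c(-1, 1)),
                    rewards = c(1.5, 0.6, 0.2))
  fit2 <- mmr(h2, sigma_s = 1, sigma_a = 1, c_xi = 5)
  K <- joint_kernel_matrix(h2, 1, 1)
  M <- margin_transform(h2$rewards)
  ip <- kernlab::ipop(c = -M, H = K, A = t(rep(0, 3)), b = 0, r = 0,
                      l = rep(0, 3), u = rep(5, 3))
  b_ip <- kernlab::primal(ip)
  obj_ip <- 0.5 * sum(b_ip * (K %*% b_ip)) - sum(M * b_ip)
  expect_equal(fit2$objective, obj_ip, tolerance = 1e-6)
})

test_that("mmr validates inputs", {
  h <- mmr_history(matrix(0, 1, 2), matrix(1, 1, 2), 1)
  expect_error(mmr(h, c_xi = -1), "positive")
  expect_error(mmr(list()), "mmr_history")
  h2 <- h; h2$rewards <- NaN
  expect_error(mmr(h2), "finite")
})

test_that("predict.mmr: all-zero beta and single support vector cases", {
  h <- mmr_history(matrix(c(0, 0), 1), matrix(c(2, -1), 1), rewards = 1)
  fit <- mmr(h, sigma_s = 1, sigma_a = 1, c_xi = 10)
  # single support at its own state: K_S = 1, prediction = beta * action
  expect_equal(predict(fit, c(0, 0)), fit$beta[1] * c(2, -1))
  # all rewards <= 0 -> beta = 0 -> zero action for every type
  h0 <- mmr_history(matrix(rnorm(6), 3), matrix(rnorm(6), 3),
                    rewards = c(-0.2, -0.5, 0))
  f0 <- mmr(h0, sigma_s = 1, sigma_a = 1)
  expect_equal(max(abs(f0$beta)), 0)
  for (ty in c("sum", "normalized", "preimage")) {
    expect_equal(predict(f0, c(0, 0), type = ty), c(0, 0))
  }
  expect_error(predict(fit, c(1, 2, 3)), "length")
})

test_that("predict.mmr: weighted-sum formula matches independent evaluation", {
  set.seed(5)
  h <- mmr_history(matrix(rnorm(8), 4), matrix(rnorm(8), 4),
                   rewards = runif(4, 0.2, 2))
  fit <- mmr(h, sigma_s = 1.3, sigma_a = 0.9)
  s <- c(0.3, -0.2)
  ks <- apply(h$states, 1, function(si) gaussian_kernel(s, si, 1.3))
  expect_equal(predict(fit, s), as.numeric(crossprod(fit$beta * ks, h$actions)))
  # matrix input returns one action per row
  S <- rbind(s, c(1, 1))
  P <- predict(fit, S)
  expect_equal(dim(P), c(2L, 2L))
  expect_equal(P[1, ], predict(fit, s))
})

test_that("predict.mmr preimage maximizes the reward surrogate at least as well", {
  set.seed(9)
  h <- mmr_history(matrix(rnorm(12), 6), matrix(rnorm(12), 6),
                   rewards = runif(6, 0, 3))
  fit <- mmr(h, sigma_s = 1, sigma_a = 1)
  s <- rnorm(2)
  ks <- apply(h$states, 1, function(si) gaussian_kernel(s, si, 1))
  w <- fit$beta * ks
  g <- function(a) sum(w * apply(h$actions, 1,
                                 function(ai) gaussian_kernel(a, ai, 1)))
  expect_gte(g(predict(fit, s, type = "preimage")), g(predict(fit, s)) - 1e-12)
})

test_that("predict.mmr is Lipschitz-continuous in the state", {
  set.seed(13)
  h <- mmr_history(matrix(rnorm(10), 5), matrix(rnorm(10), 5),
                   rewards = runif(5, 0, 2))
  fit <- mmr(h, sigma_s = 1, sigma_a = 1)
  s <- c(0.1, 0.4)
  base <- predict(fit, s)
  for (eps in c(1e-4, 1e-5)) {
    d <- predict(fit, s + c(eps, 0)) - base
    expect_lt(sqrt(sum(d^2)), 10 * eps) # bounded difference quotient
  }
})

test_that("mmr JSON serialization round-trips", {
  set.seed(3)
  h <- mmr_history(matrix(rnorm(6), 3), matrix(rnorm(6), 3),
                   rewards = c(0.5, 1.5, -0.1))
  fit <- mmr(h, sigma_s = 1.1, sigma_a = 0.7, c_xi = 2)
  back <- mmr_from_json(mmr_to_json(fit))
  expect_equal(back$beta, fit$beta)
  expect_equal(back$history$states, fit$history$states)
  expect_equal(back$history$actions, fit$history$actions)
  expect_equal(back$sigma_s, fit$sigma_s)
  expect_equal(predict(back, c(0, 0)), predict(fit, c(0, 0)))
  p <- tempfile(fileext = ".json")
  mmr_to_json(fit, p)
  expect_equal(mmr_from_json(p)$objective, fit$objective)
  unlink(p)
})

test_that("print and summary methods run and report support counts", {
  h <- mmr_history(matrix(rnorm(6), 3), matrix(rnorm(6), 3),
                   rewards = c(1, 2, -0.5))
  fit <- mmr(h, sigma_s = 1, sigma_a = 1)
  expect_output(print(fit), "MMR policy")
  s <- summary(fit)
  expect_s3_class(s, "summary.mmr")
  expect_identical(s$n, 3L)
  expect_output(print(s), "support vectors")
  expect_equal(coef(fit), fit$beta)
})
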