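#' Random-search baseline
#'
#' After the shared Latin-hypercube warm-up, every round draws one design per
#' parallel slot uniformly in the design box — the standard strong baseline
#' for expensive black-box optimization. Consumes exactly the same
#' environment-call budget as [run_marl()] under the same configuration.
#'
#' @inheritParams run_marl
#' @return a `strain_run` with the same log schema as [run_marl()].
#' @export
random_search <- function(env, config = marl_config(), warmup_data = NULL) {
  stopifnot(inherits(env, "strain_env"), inherits(config, "marl_config"))
  if (is.null(warmup_data)) warmup_data <- warmup(env, config)
  n <- config$n_agents
  d <- env$n_design
  lo <- env$bounds[1L, ]; hi <- env$bounds[2L, ]
  set.seed(derive_seed(config$seed, "rand"))
  wl <- warmup_log(warmup_data, env, config, "rand")
  logs <- list(wl)
  prev_design <- do.call(rbind, lapply(warmup_data$last, `[[`, "design"))
  prev_y <- vapply(warmup_data$last, `[[`, numeric(1), "response")
  n_calls <- n * config$tau
  best_y <- max(warmup_data$responses)
  best_design <- warmup_data$designs[which.max(warmup_data$responses), ]
  grp <- agent_groups(n, config$n_groups)
  for (t in seq_len(config$n_iterations)) {
    designs <- matrix(stats::runif(n * d), n, d)
    designs <- sweep(sweep(designs, 2L, hi - lo, "*"), 2L, lo, "+")
    states <- matrix(NA_real_, n, env$n_state)
    ys <- numeric(n)
    for (i in seq_len(n)) {
      out <- env$step(designs[i, ], action = designs[i, ] - prev_design[i, ])
      n_calls <- n_calls + 1L
      states[i, ] <- out$state
      ys[i] <- out$response
      if (ys[i] > best_y) { best_y <- ys[i]; best_design <- designs[i, ] }
    }
    raws <- t(apply(designs, 1L, env$to_raw))
    if (d == 1L) raws <- t(raws)
    logs[[length(logs) + 1L]] <-
      log_block(round = config$tau + t, phase = "optimize", method = "rand",
                agent = seq_len(n), group = grp, designs = designs,
                raws = raws, states = states, responses = ys,
                rewards = ys - prev_y)
    prev_design <- designs
    prev_y <- ys
  }
  structure(list(log = do.call(rbind, logs), method = "rand",
                 env_name = env$name, config = config,
                 best_design = best_design, best_response = best_y,
                 n_env_calls = n_calls),
            class = "strain_run")
}

# ---- Gaussian-process surrogate (squared-exponential kernel) ----

#' Fit a Gaussian-process regression surrogate
#'
#' Zero-mean GP on centred targets with the squared-exponential kernel
#' `k(x, x') = exp(-||x - x'||^2 / (2 l^2))` and observation-noise variance
#' `noise_var`, fit by Cholesky factorization. A singular covariance is
#' retried once with jitter `1e-8` added to the diagonal.
#'
#' @param X design matrix (one input per row).
#' @param y numeric responses.
#' @param length_scale positive length scale, or `"median"` for the median
#'   heuristic over the pairwise input distances.
#' @param noise_var observation-noise variance (default `1e-6`, suited to
#'   noiseless simulators).
#' @return an object of class `gp_fit`.
#' @export
gp_fit <- function(X, y, length_scale = "median", noise_var = 1e-6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), noise_var >= 0)
  if (identical(length_scale, "median")) {
    length_scale <- if (nrow(X) < 2L) 1.0 else median_heuristic_bandwidth(X)
  }
  stopifnot(is.numeric(length_scale), length_scale > 0)
  mu <- mean(y)
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * length_scale^2))
  L <- tryCatch(chol(K + diag(noise_var, nrow(X))),
                error = function(e) chol(K + diag(noise_var + 1e-8, nrow(X))))
  alpha <- backsolve(L, forwardsolve(t(L), y - mu))
  structure(list(X = X, y = y, mu = mu, L = L, alpha = alpha,
                 length_scale = length_scale, noise_var = noise_var),
            class = "gp_fit")
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param object a [gp_fit()].
#' @param newdata matrix of query points (one per row) or a single vector.
#' @param ... unused.
#' @return a list with numeric vectors `mean` and `sd`.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  sq <- outer(rowSums(newdata^2), rowSums(object$X^2), "+") -
    2 * tcrossprod(newdata, object$X)
  sq[sq < 0] <- 0
  Ks <- exp(-sq / (2 * object$length_scale^2))
  mean <- object$mu + as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(1 - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Expected improvement acquisition
#'
#' Closed-form expected improvement of a Gaussian posterior over the current
#' best observation: `EI = imp * pnorm(z) + sd * dnorm(z)` with
#' `imp = mu - best - xi`, `z = imp / sd`; zero where the posterior is
#' (numerically) deterministic.
#'
#' @param mu,sd posterior mean(s) and standard deviation(s).
#' @param best current best observed response.
#' @param xi exploration offset (default 0).
#' @return numeric vector of EI values.
#' @export
expected_improvement <- function(mu, sd, best, xi = 0) {
  imp <- mu - best - xi
  ei <- numeric(length(mu))
  ok <- sd > 1e-12
  z <- imp[ok] / sd[ok]
  ei[ok] <- imp[ok] * stats::pnorm(z) + sd[ok] * stats::dnorm(z)
  pmax(ei, 0)
}

# maximize EI in the box: 64 seeded LHS starts, the 8 best polished by
# Nelder-Mead local search
maximize_ei <- function(fit, best, bounds, xi = 0, n_starts = 64L,
                        n_polish = 8L) {
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  starts <- latin_hypercube(n_starts, bounds)
  p <- predict(fit, starts)
  ei0 <- expected_improvement(p$mean, p$sd, best, xi)
  ord <- order(ei0, decreasing = TRUE)[seq_len(min(n_polish, n_starts))]
  obj <- function(x) {
    x <- pmin(pmax(x, lo), hi)
    p <- predict(fit, x)
    -expected_improvement(p$mean, p$sd, best, xi)
  }
  cand_x <- starts[ord[1L], ]
  cand_v <- ei0[ord[1L]]
  for (i in ord) {
    res <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 200L))
    x <- pmin(pmax(res$par, lo), hi)
    if (-res$value > cand_v) { cand_v <- -res$value; cand_x <- x }
  }
  cand_x
}

#' Bayesian-optimization baseline (GP surrogate, expected improvement)
#'
#' After the shared warm-up, fits a squared-exponential Gaussian process on
#' all (design, response) pairs each round and proposes a batch of
#' `n_agents` designs by maximizing expected improvement sequentially with
#' the constant-liar strategy: each accepted proposal is temporarily assigned
#' the current best observed response before the next proposal is optimized.
#' Consumes exactly the [run_marl()] budget.
#'
#' @inheritParams run_marl
#' @param gp list of GP settings: `length_scale` (positive or `"median"`),
#'   `noise_var`, `xi` (EI exploration offset).
#' @return a `strain_run` with the same log schema as [run_marl()].
#' @export
bo_gp <- function(env, config = marl_config(), warmup_data = NULL,
                  gp = list(length_scale = "median", noise_var = 1e-6, xi = 0)) {
  stopifnot(inherits(env, "strain_env"), inherits(config, "marl_config"))
  if (is.null(warmup_data)) warmup_data <- warmup(env, config)
  n <- config$n_agents
  d <- env$n_design
  set.seed(derive_seed(config$seed, "bogp"))
  logs <- list(warmup_log(warmup_data, env, config, "bogp"))
  X <- warmup_data$designs
  y <- warmup_data$responses
  prev_design <- do.call(rbind, lapply(warmup_data$last, `[[`, "design"))
  prev_y <- vapply(warmup_data$last, `[[`, numeric(1), "response")
  n_calls <- n * config$tau
  best_y <- max(y)
  best_design <- X[which.max(y), ]
  grp <- agent_groups(n, config$n_groups)
  for (t in seq_len(config$n_iterations)) {
    Xl <- X; yl <- y # constant-liar augmented copies
    proposals <- matrix(NA_real_, n, d)
    for (b in seq_len(n)) {
      fit <- gp_fit(Xl, yl, length_scale = gp$length_scale,
                    noise_var = gp$noise_var)
      proposals[b, ] <- maximize_ei(fit, max(yl), env$bounds, xi = gp$xi)
      Xl <- rbind(Xl, proposals[b, ])
      yl <- c(yl, max(y)) # the "lie": assume the current best
    }
    states <- matrix(NA_real_, n, env$n_state)
    ys <- numeric(n)
    for (i in seq_len(n)) {
      out <- env$step(proposals[i, ], action = proposals[i, ] - prev_design[i, ])
      n_calls <- n_calls + 1L
      states[i, ] <- out$state
      ys[i] <- out$response
      if (ys[i] > best_y) { best_y <- ys[i]; best_design <- proposals[i, ] }
    }
    X <- rbind(X, proposals)
    y <- c(y, ys)
    raws <- t(apply(proposals, 1L, env$to_raw))
    if (d == 1L) raws <- t(raws)
    logs[[length(logs) + 1L]] <-
      log_block(round = config$tau + t, phase = "optimize", method = "bogp",
                agent = seq_len(n), group = grp, designs = proposals,
                raws = raws, states = states, responses = ys,
                rewards = ys - prev_y)
    prev_design <- proposals
    prev_y <- ys
  }
  structure(list(log = do.call(rbind, logs), method = "bogp",
                 env_name = env$name, config = config,
                 best_design = best_design, best_response = best_y,
                 n_env_calls = n_calls),
            class = "strain_run")
}
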