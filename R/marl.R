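#' Configuration of a multi-agent optimization run
#'
#' Defaults follow the standard experimental setup: 4 parallel agents (e.g.
#' parallel cultivations) in 2 groups, a Latin-hypercube warm-up of 5 rounds
#' per agent, 40 optimization iterations, action perturbation coefficient
#' 0.8, worst-agent replacement every 5 iterations, and the 75th percentile
#' for seeding the first agent from the warm-up.
#'
#' @param n_agents number of parallel agents (default 4).
#' @param n_groups number of agent groups jointly learning one policy each
#'   (default 2); `1` is fully centralized, `n_agents` fully decentralized.
#' @param tau warm-up rounds per agent (default 5).
#' @param n_iterations optimization rounds after warm-up (default 40).
#' @param perturb_c perturbation coefficient in `[0, 1]` (default 0.8).
#' @param replace_every_k worst-agent replacement period (default 5).
#' @param upper_quantile response quantile whose exceeders seed agent 1
#'   (default 0.75).
#' @param seed integer root seed.
#' @param sigma_s,sigma_a,c_xi MMR hyper-parameters; `"median"` selects the
#'   median-heuristic bandwidth at each refit.
#' @param predict action-prediction rule handed to [predict.mmr()]: `"sum"`
#'   (the closed-form weighted sum, the default), `"normalized"`, or
#'   `"preimage"` (numeric pre-image by mean-shift — recommends larger,
#'   better-directed steps and empirically improves optimization markedly;
#'   kept opt-in to preserve the documented default behavior).
#' @param plateau_patience optional early stop: rounds without best-found
#'   improvement before stopping (`Inf` disables, the default).
#' @return an object of class `marl_config`.
#' @export
marl_config <- function(n_agents = 4L, n_groups = 2L, tau = 5L,
                        n_iterations = 40L, perturb_c = 0.8,
                        replace_every_k = 5L, upper_quantile = 0.75,
                        seed = 1L, sigma_s = "median", sigma_a = "median",
                        c_xi = 1, predict = c("sum", "normalized", "preimage"),
                        plateau_patience = Inf) {
  predict <- match.arg(predict)
  stopifnot(n_agents >= 1L, n_groups >= 1L, n_groups <= n_agents, tau >= 1L,
            n_iterations >= 0L, perturb_c >= 0, perturb_c <= 1,
            replace_every_k >= 1L, upper_quantile > 0, upper_quantile < 1,
            c_xi > 0)
  structure(list(n_agents = as.integer(n_agents), n_groups = as.integer(n_groups),
                 tau = as.integer(tau), n_iterations = as.integer(n_iterations),
                 perturb_c = perturb_c, replace_every_k = as.integer(replace_every_k),
                 upper_quantile = upper_quantile, seed = as.integer(seed),
                 sigma_s = sigma_s, sigma_a = sigma_a, c_xi = c_xi,
                 predict = predict, plateau_patience = plateau_patience),
            class = "marl_config")
}

# contiguous group assignment: 4 agents in 2 groups -> 1,1,2,2
agent_groups <- function(n_agents, n_groups) {
  sort(rep_len(seq_len(n_groups), n_agents))
}

#' Latin hypercube sample
#'
#' Stratified space-filling design: each dimension's range is divided into
#' `n` equiprobable intervals and every interval contains exactly one sample.
#' Draws from R's global RNG (seed before calling for reproducibility).
#'
#' @param n number of samples.
#' @param bounds 2 x d matrix, rows `lo` and `hi`.
#' @return an `n` x d matrix of samples inside the bounds.
#' @export
latin_hypercube <- function(n, bounds) {
  stopifnot(n >= 1L, nrow(bounds) == 2L, all(is.finite(bounds)))
  d <- ncol(bounds)
  u <- lhs::randomLHS(n, d)
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  if (any(lo == hi)) warning("degenerate bounds: constant dimension(s)")
  sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
}

#' Warm-up phase: seeded Latin-hypercube experiments
#'
#' Executes `tau` Latin-hypercube designs per agent to initialize the policy
#' memory. Rewards are response deltas within each agent's own sequence; the
#' first reward is the delta from the environment's wild-type baseline
#' response. Every method in a comparison shares the same warm-up data for a
#' given root seed.
#'
#' @param env a [strain_env()].
#' @param config a [marl_config()] (only `n_agents` and `tau` are used).
#' @param seed root seed; the warm-up draws from the `"warmup"` substream.
#' @return a list of class `marl_warmup`: `log` (one row per round x agent),
#'   `designs`/`responses`/`states` pooled matrices, and per-agent last
#'   design/state/response for the optimizer to continue from.
#' @export
warmup <- function(env, config, seed = config$seed) {
  stopifnot(inherits(env, "strain_env"), inherits(config, "marl_config"))
  n_agents <- config$n_agents; tau <- config$tau
  d <- env$n_design
  set.seed(derive_seed(seed, "warmup"))
  rows <- list(); ri <- 0L
  designs <- matrix(NA_real_, n_agents * tau, d)
  states_before <- matrix(NA_real_, n_agents * tau, env$n_state)
  states_obs <- matrix(NA_real_, n_agents * tau, env$n_state)
  actions <- matrix(NA_real_, n_agents * tau, d)
  rewards <- numeric(n_agents * tau)
  responses <- numeric(n_agents * tau)
  agent_of <- integer(n_agents * tau)
  round_of <- integer(n_agents * tau)
  last <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    plan <- latin_hypercube(tau, env$bounds)
    prev_design <- env$baseline_design
    prev_state <- env$baseline_state
    prev_y <- env$baseline_response
    for (t in seq_len(tau)) {
      dgn <- plan[t, ]
      act <- dgn - prev_design
      out <- env$step(dgn, action = act)
      ri <- ri + 1L
      designs[ri, ] <- dgn
      states_before[ri, ] <- prev_state
      states_obs[ri, ] <- out$state
      actions[ri, ] <- act
      rewards[ri] <- out$response - prev_y
      responses[ri] <- out$response
      agent_of[ri] <- i
      round_of[ri] <- t
      prev_design <- dgn; prev_state <- out$state; prev_y <- out$response
    }
    last[[i]] <- list(design = prev_design, state = prev_state, response = prev_y)
  }
  structure(list(designs = designs, states_before = states_before,
                 states_obs = states_obs,
                 actions = actions, rewards = rewards, responses = responses,
                 agent = agent_of, round = round_of, last = last,
                 n_agents = n_agents, tau = tau, seed = seed),
            class = "marl_warmup")
}

#' Choose the agents' starting designs from the warm-up
#'
#' Agent 1 starts at the coordinate-wise median of the warm-up designs whose
#' responses lie in the top `1 - upper_quantile` fraction (the single best
#' design if that fraction contains fewer than one); the remaining agents
#' start at fresh Latin-hypercube draws to keep exploring other subspaces.
#'
#' @param wdata a [warmup()] result.
#' @param env the environment (for the design bounds).
#' @param config a [marl_config()].
#' @return an `n_agents` x d matrix of starting designs.
#' @export
init_enzyme_levels <- function(wdata, env, config) {
  stopifnot(inherits(wdata, "marl_warmup"))
  n <- nrow(wdata$designs)
  k <- max(1L, ceiling((1 - config$upper_quantile) * n))
  top <- order(wdata$responses, decreasing = TRUE)[seq_len(k)]
  first <- apply(wdata$designs[top, , drop = FALSE], 2L, stats::median)
  starts <- matrix(NA_real_, config$n_agents, env$n_design)
  starts[1L, ] <- first
  if (config$n_agents > 1L) {
    starts[-1L, ] <- latin_hypercube(config$n_agents - 1L, env$bounds)
  }
  starts
}

#' Gram-Schmidt orthonormalization
#'
#' Orthonormalizes a set of vectors in input order. A vector that is
#' numerically dependent on its predecessors (residual norm below `1e-10`) —
#' including any vector beyond the space dimension — is replaced by a random
#' unit direction orthogonalized against the previous outputs; replacements
#' are flagged. Random draws use the global RNG.
#'
#' @param V matrix with one vector per row, or a list of vectors.
#' @return list with `vectors` (rows are pairwise orthogonal unit vectors)
#'   and `replaced` (logical flags).
#' @export
gram_schmidt <- function(V) {
  if (is.list(V)) V <- do.call(rbind, V)
  V <- as.matrix(V)
  d <- ncol(V)
  if (d == 0L) stop("zero-dimensional input")
  sz <- nrow(V)
  out <- matrix(0, sz, d)
  replaced <- logical(sz)
  ortho <- function(v, k) { # residual of v against the first k outputs
    if (k > 0L) {
      basis <- out[seq_len(k), , drop = FALSE]
      v <- v - as.numeric(crossprod(basis %*% v, basis))
    }
    v
  }
  for (i in seq_len(sz)) {
    if (i <= d) {
      v <- ortho(V[i, ], i - 1L)
      nv <- sqrt(sum(v^2))
      if (!(nv > 1e-10)) {
        replaced[i] <- TRUE
        repeat {
          v <- ortho(stats::rnorm(d), i - 1L)
          nv <- sqrt(sum(v^2))
          if (nv > 1e-10) break
        }
      }
    } else {
      # the basis is already complete: only a random re-draw is possible
      replaced[i] <- TRUE
      v <- stats::rnorm(d)
      nv <- sqrt(sum(v^2))
    }
    out[i, ] <- v / nv
  }
  list(vectors = out, replaced = replaced)
}

#' Diversify a group's actions by orthogonal perturbation
#'
#' Blends each agent's proposed action with its Gram-Schmidt direction,
#' `a~_i = (1 - c) a_i + c v_i`, then restores each action's original
#' Euclidean norm. This does not shrink — and generically grows — the
#' determinant of the actions' Gram matrix, i.e. the volume of the
#' parallelotope the group explores, while leaving each action's step size
#' unchanged. A zero action is first replaced by a small random vector of
#' norm `1e-3` so it, too, gets a direction.
#'
#' @param A matrix of actions, one per row (a group's proposals).
#' @param c perturbation coefficient in `[0, 1]` (default 0.8).
#' @return matrix of perturbed actions with the input norms.
#' @export
perturb_agents <- function(A, c = 0.8) {
  A <- as.matrix(A)
  stopifnot(nrow(A) >= 1L, c >= 0, c <= 1)
  norms <- sqrt(rowSums(A^2))
  for (i in which(norms == 0)) {
    v <- stats::rnorm(ncol(A))
    A[i, ] <- v / sqrt(sum(v^2)) * 1e-3
    norms[i] <- 1e-3
  }
  gs <- gram_schmidt(A)
  P <- (1 - c) * A + c * gs$vectors
  pn <- sqrt(rowSums(P^2))
  for (i in seq_len(nrow(A))) {
    if (pn[i] < 1e-12) {
      # degenerate cancellation: fall back to the orthogonal direction
      P[i, ] <- gs$vectors[i, ] * norms[i]
    } else {
      P[i, ] <- P[i, ] / pn[i] * norms[i]
    }
  }
  P
}

#' Replace the worst-performing agent
#'
#' The agent with the lowest median response over its recorded rounds has its
#' current design overwritten by a copy of a uniformly chosen other agent's
#' design; histories are not rewritten. Ties resolve to the lowest agent
#' index.
#'
#' @param designs `n_agents` x d matrix of current designs.
#' @param response_series list of numeric vectors, each agent's recorded
#'   responses.
#' @return list with the updated `designs`, the replaced index `worst` and
#'   the `donor` index.
#' @export
replace_worst <- function(designs, response_series) {
  n <- nrow(designs)
  stopifnot(n >= 2L, length(response_series) == n)
  med <- vapply(response_series, stats::median, numeric(1))
  worst <- which.min(med) # first minimum: lowest index on ties
  candidates <- setdiff(seq_len(n), worst)
  # sample() treats a scalar m as 1:m, so a single candidate must be kept as-is
  donor <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
  designs[worst, ] <- designs[donor, ]
  list(designs = designs, worst = worst, donor = donor)
}

# assemble one log row block for a round
log_block <- function(round, phase, method, agent, group, designs, raws,
                      states, responses, rewards) {
  df <- data.frame(round = round, agent = agent, group = group, phase = phase,
                   method = method)
  dcols <- as.data.frame(designs); names(dcols) <- paste0("d", seq_len(ncol(designs)))
  rcols <- as.data.frame(raws); names(rcols) <- paste0("raw", seq_len(ncol(raws)))
  scols <- as.data.frame(states); names(scols) <- paste0("s", seq_len(ncol(states)))
  cbind(df, dcols, rcols, scols,
        data.frame(response = responses, reward = rewards))
}

warmup_log <- function(wdata, env, config, method) {
  grp <- agent_groups(config$n_agents, config$n_groups)
  raws <- t(apply(wdata$designs, 1L, env$to_raw))
  if (env$n_design == 1L) raws <- t(raws)
  log_block(round = wdata$round, phase = "warmup", method = method,
            agent = wdata$agent, group = grp[wdata$agent],
            designs = wdata$designs, raws = raws,
            states = wdata$states_obs,
            responses = wdata$responses, rewards = wdata$rewards)
}

#' Run the multi-agent strain-design optimizer
#'
#' The full Design-Build-Test-Learn loop: Latin-hypercube warm-up, then
#' `n_iterations` rounds in which every agent executes its current design,
#' its group's history is extended with the (previous state, executed action,
#' response delta) triplet, the group policy is refit by [mmr()], actions are
#' predicted per agent, diversified by [perturb_agents()], and applied with
#' clipping to the design box. Every `replace_every_k` rounds the worst agent
#' (lowest median response) restarts from a copy of a random other agent.
#' Fully deterministic given `config$seed`.
#'
#' @param env a [strain_env()].
#' @param config a [marl_config()].
#' @param warmup_data optionally a precomputed [warmup()] result, so that
#'   competing methods can share the identical warm-up experiments.
#' @return an object of class `strain_run`: the tidy `log` (one row per
#'   round x agent), `best_design`/`best_response`, `n_env_calls`, the final
#'   per-group policies, and the config.
#' @export
run_marl <- function(env, config = marl_config(), warmup_data = NULL) {
  stopifnot(inherits(env, "strain_env"), inherits(config, "marl_config"))
  if (is.null(warmup_data)) warmup_data <- warmup(env, config)
  stopifnot(inherits(warmup_data, "marl_warmup"),
            warmup_data$n_agents == config$n_agents,
            warmup_data$tau == config$tau)
  n_agents <- config$n_agents
  grp <- agent_groups(n_agents, config$n_groups)
  d <- env$n_design
  lo <- env$bounds[1L, ]; hi <- env$bounds[2L, ]

  set.seed(derive_seed(config$seed, "marl"))
  logs <- list(warmup_log(warmup_data, env, config, "marl"))
  e <- init_enzyme_levels(warmup_data, env, config)

  # group histories seeded from the warm-up, member records in round order
  hist_g <- lapply(seq_len(config$n_groups), function(j) {
    idx <- order(warmup_data$round[grp[warmup_data$agent] == j])
    sel <- which(grp[warmup_data$agent] == j)[idx]
    mmr_history(warmup_data$states_before[sel, , drop = FALSE],
                warmup_data$actions[sel, , drop = FALSE],
                warmup_data$rewards[sel])
  })
  prev_design <- do.call(rbind, lapply(warmup_data$last, `[[`, "design"))
  prev_state <- do.call(rbind, lapply(warmup_data$last, `[[`, "state"))
  prev_y <- vapply(warmup_data$last, `[[`, numeric(1), "response")
  resp_series <- lapply(seq_len(n_agents), function(i)
    warmup_data$responses[warmup_data$agent == i])

  policies <- vector("list", config$n_groups)
  n_calls <- n_agents * config$tau
  best_y <- max(warmup_data$responses)
  best_design <- warmup_data$designs[which.max(warmup_data$responses), ]
  since_improved <- 0L

  for (t in seq_len(config$n_iterations)) {
    cur_state <- matrix(NA_real_, n_agents, env$n_state)
    cur_y <- numeric(n_agents)
    cur_reward <- numeric(n_agents)
    for (j in seq_len(config$n_groups)) {
      members <- which(grp == j)
      for (i in members) {
        act <- e[i, ] - prev_design[i, ]
        out <- env$step(e[i, ], action = act)
        n_calls <- n_calls + 1L
        cur_state[i, ] <- out$state
        cur_y[i] <- out$response
        cur_reward[i] <- out$response - prev_y[i]
        hist_g[[j]] <- history_append(hist_g[[j]], prev_state[i, ], act,
                                      cur_reward[i])
        resp_series[[i]] <- c(resp_series[[i]], out$response)
        if (out$response > best_y) {
          best_y <- out$response; best_design <- e[i, ]
        }
      }
      pol <- mmr(hist_g[[j]], sigma_s = config$sigma_s,
                 sigma_a = config$sigma_a, c_xi = config$c_xi)
      policies[[j]] <- pol
      A <- predict(pol, cur_state[members, , drop = FALSE],
                   type = config$predict)
      A <- perturb_agents(A, config$perturb_c)
      for (m in seq_along(members)) {
        i <- members[m]
        prev_design[i, ] <- e[i, ]
        prev_state[i, ] <- cur_state[i, ]
        prev_y[i] <- cur_y[i]
        e[i, ] <- pmin(pmax(e[i, ] + A[m, ], lo), hi)
      }
    }
    raws <- t(apply(prev_design, 1L, env$to_raw))
    if (d == 1L) raws <- t(raws)
    logs[[length(logs) + 1L]] <-
      log_block(round = config$tau + t, phase = "optimize", method = "marl",
                agent = seq_len(n_agents), group = grp,
                designs = prev_design, raws = raws, states = cur_state,
                responses = cur_y, rewards = cur_reward)
    if (t %% config$replace_every_k == 0L && n_agents >= 2L) {
      rep <- replace_worst(e, resp_series)
      e <- rep$designs
    }
    since_improved <- if (max(cur_y) >= best_y) 0L else since_improved + 1L
    if (is.finite(config$plateau_patience) &&
        since_improved >= config$plateau_patience) break
  }
  structure(list(log = do.call(rbind, logs), method = "marl",
                 env_name = env$name, config = config,
                 best_design = best_design, best_response = best_y,
                 n_env_calls = n_calls, policies = policies),
            class = "strain_run")
}
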