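#' Aggregate best-found trajectories across runs
#'
#' Pools, per round, the best-found responses of every (agent, run) pair and
#' returns the median, the 25th/75th percentiles (linear-interpolation
#' quantiles) and the mean — the summary used to compare optimizers across
#' repeated seeded runs.
#'
#' @param runs a list of `strain_run` objects sharing the same round count.
#' @return a data.frame with columns `round`, `median`, `q25`, `q75`, `mean`,
#'   `n` (pool size per round).
#' @export
aggregate_trajectories <- function(runs) {
  if (length(runs) == 0L) stop("no runs supplied")
  bf <- lapply(seq_along(runs), function(k) {
    x <- best_found(runs[[k]])
    x$run <- k
    x
  })
  rounds <- sort(unique(bf[[1L]]$round))
  for (x in bf) {
    if (!identical(sort(unique(x$round)), rounds)) {
      stop("runs must share the same round count")
    }
  }
  pooled <- do.call(rbind, bf)
  agg <- do.call(rbind, lapply(split(pooled$best_found, pooled$round), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(median = q[2L], q25 = q[1L], q75 = q[3L], mean = mean(v),
               n = length(v))
  }))
  out <- cbind(data.frame(round = as.numeric(rownames(agg))), agg)
  out <- out[order(out$round), ]
  rownames(out) <- NULL
  out
}

#' Stability (relative standard deviation) of a strain design
#'
#' Real constructs rarely hit designed enzyme levels exactly, so a good
#' design must keep its response under small perturbations. Each of
#' `n_neighbors` neighbors multiplies every raw enzyme level by an
#' independent factor uniform in `[1 - fold, 1 + fold]` (clipped to the raw
#' design range), the environment is queried at each neighbor, and the
#' relative standard deviation `RSD = sigma / mu` of the neighborhood
#' responses is returned (population sigma by default; lower is more stable).
#'
#' @param env a [strain_env()].
#' @param design_raw the design in raw space (e.g. normalized enzyme pools).
#' @param n_neighbors neighborhood size (default 10).
#' @param fold fold-change half-width in `(0, 1)` (default 0.5).
#' @param seed integer seed for the neighbor draws.
#' @param raw_bounds length-2 numeric clipping range of raw levels; defaults
#'   to the image of the design box under `env$to_raw`.
#' @param population logical; population (default) or sample standard
#'   deviation.
#' @return an object of class `rsd_stability`: `rsd`, the neighborhood
#'   `responses`, `mu`, `sigma`, and `undefined` (`TRUE` when the mean
#'   response is not positive, in which case `rsd` is `NA`).
#' @export
rsd_stability <- function(env, design_raw, n_neighbors = 10L, fold = 0.5,
                          seed = 1L, raw_bounds = NULL, population = TRUE) {
  stopifnot(inherits(env, "strain_env"), n_neighbors >= 2L, fold > 0, fold < 1)
  if (is.null(raw_bounds)) {
    raw_bounds <- range(env$to_raw(env$bounds[1L, ]), env$to_raw(env$bounds[2L, ]))
  }
  d <- length(design_raw)
  set.seed(derive_seed(seed, "rsd"))
  responses <- vapply(seq_len(n_neighbors), function(k) {
    fac <- stats::runif(d, 1 - fold, 1 + fold)
    raw <- pmin(pmax(design_raw * fac, raw_bounds[1L]), raw_bounds[2L])
    env$step(env$from_raw(raw), action = NULL)$response
  }, numeric(1))
  mu <- mean(responses)
  sigma <- if (population) {
    sqrt(mean((responses - mu)^2))
  } else {
    stats::sd(responses)
  }
  undefined <- mu <= 1e-12
  structure(list(rsd = if (undefined) NA_real_ else sigma / mu,
                 responses = responses, mu = mu, sigma = sigma,
                 undefined = undefined, n_neighbors = n_neighbors,
                 fold = fold),
            class = "rsd_stability")
}

#' @export
print.rsd_stability <- function(x, ...) {
  if (x$undefined) {
    cat("RSD: undefined (neighborhood mean response <= 0)\n")
  } else {
    cat(sprintf("RSD = %.4g (mu = %.4g, sigma = %.4g, %d neighbors, fold %.2g)\n",
                x$rsd, x$mu, x$sigma, x$n_neighbors, x$fold))
  }
  invisible(x)
}

#' Stability table across repeated runs
#'
#' Runs the optimizer over a seed set, takes each trajectory's best design,
#' and summarizes the [rsd_stability()] of those final designs (mean and sd
#' of the per-trajectory RSDs).
#'
#' @param env a [strain_env()].
#' @param config a [marl_config()].
#' @param seeds integer vector of root seeds (one run each).
#' @param method one of `"marl"`, `"rand"`, `"bogp"`.
#' @param ... passed to [rsd_stability()].
#' @return a data.frame with one row: `method`, `env`, `mean_rsd`, `sd_rsd`,
#'   `n_trajectories`, plus the per-run RSDs as attribute `"rsd"`.
#' @export
stability_table <- function(env, config, seeds, method = "marl", ...) {
  runner <- switch(method, marl = run_marl, rand = random_search, bogp = bo_gp,
                   stop("unknown method: ", method))
  rsds <- vapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run <- runner(env, cfg)
    raw <- env$to_raw(run$best_design)
    rsd_stability(env, raw, seed = derive_seed(s, "stability"), ...)$rsd
  }, numeric(1))
  out <- data.frame(method = method, env = env$name,
                    mean_rsd = mean(rsds, na.rm = TRUE),
                    sd_rsd = stats::sd(rsds),
                    n_trajectories = length(rsds))
  attr(out, "rsd") <- rsds
  out
}

#' Degradation of the final best-found response under noise
#'
#' Runs the optimizer over a seed set for each noise specification and
#' reports, per specification, the percentage decrement of the median final
#' best-found response relative to the noiseless baseline,
#' `100 (median_0 - median_m) / median_0`. Negative decrements
#' (improvements under noise) are reported as-is.
#'
#' @param env a noiseless [strain_env()].
#' @param config a [marl_config()].
#' @param noise_grid list of [noise_spec()]s; must include the all-zero spec.
#' @param seeds integer vector of root seeds.
#' @return a data.frame with columns `m_state`, `m_action`, `m_response`,
#'   `median_final`, `decrement_pct`.
#' @export
noise_degradation <- function(env, config, noise_grid, seeds) {
  zero <- vapply(noise_grid, function(s)
    s$m_state == 0 && s$m_action == 0 && s$m_response == 0, logical(1))
  if (!any(zero)) stop("noise_grid must include the zero (noiseless) spec")
  median_final <- vapply(noise_grid, function(spec) {
    runs <- lapply(seeds, function(s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      e <- with_noise(env, spec, seed = derive_seed(s, "noisewrap"))
      run_marl(e, cfg)
    })
    traj <- aggregate_trajectories(runs)
    traj$median[nrow(traj)]
  }, numeric(1))
  base <- median_final[which(zero)[1L]]
  data.frame(m_state = vapply(noise_grid, `[[`, numeric(1), "m_state"),
             m_action = vapply(noise_grid, `[[`, numeric(1), "m_action"),
             m_response = vapply(noise_grid, `[[`, numeric(1), "m_response"),
             median_final = median_final,
             decrement_pct = 100 * (base - median_final) / base)
}
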