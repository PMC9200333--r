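#' Best-found response trajectories of a run
#'
#' For each agent (or parallel experiment slot) the running maximum of its
#' observed responses by round — the quantity tracked when comparing
#' optimizers, since experiments already performed are never un-done.
#'
#' @param run a `strain_run` from [run_marl()], [random_search()] or
#'   [bo_gp()].
#' @return a data.frame with columns `round`, `agent`, `best_found`.
#' @export
best_found <- function(run) {
  stopifnot(inherits(run, "strain_run"))
  log <- run$log[order(run$log$agent, run$log$round), ]
  out <- do.call(rbind, lapply(split(log, log$agent), function(x) {
    data.frame(round = x$round, agent = x$agent[1L],
               best_found = cummax(x$response))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.strain_run <- function(x, ...) {
  cat(sprintf("<strain_run: method %s on %s>\n", x$method, x$env_name))
  cat(sprintf("  %d environment calls, best response %.6g\n",
              x$n_env_calls, x$best_response))
  invisible(x)
}

#' @export
summary.strain_run <- function(object, ...) {
  bf <- best_found(object)
  fin <- bf[bf$round == max(bf$round), ]
  out <- list(method = object$method, env = object$env_name,
              n_env_calls = object$n_env_calls,
              best_response = object$best_response,
              best_design = object$best_design,
              final_best_by_agent = stats::setNames(fin$best_found, fin$agent),
              rounds = max(bf$round))
  class(out) <- "summary.strain_run"
  out
}

#' @export
print.summary.strain_run <- function(x, ...) {
  cat(sprintf("Run summary: %s on %s\n", x$method, x$env))
  cat(sprintf("  rounds: %d  env calls: %d\n", x$rounds, x$n_env_calls))
  cat(sprintf("  best response: %.6g\n", x$best_response))
  cat("  best design:", paste(signif(x$best_design, 4), collapse = " "), "\n")
  cat("  final best-found per agent:",
      paste(signif(x$final_best_by_agent, 4), collapse = " "), "\n")
  invisible(x)
}

#' Plot best-found trajectories
#'
#' Median best-found response across agents per round, with the per-agent
#' trajectories in grey.
#'
#' @param x a `strain_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.strain_run <- function(x, ...) {
  bf <- best_found(x)
  med <- tapply(bf$best_found, bf$round, stats::median)
  rounds <- as.numeric(names(med))
  graphics::plot(rounds, med, type = "n",
                 xlab = "round", ylab = "best-found response",
                 main = sprintf("%s on %s", x$method, x$env_name), ...)
  for (a in unique(bf$agent)) {
    sub <- bf[bf$agent == a, ]
    graphics::lines(sub$round, sub$best_found, col = "grey70")
  }
  graphics::lines(rounds, med, lwd = 2)
  invisible(x)
}

#' Write a run log and summary to disk
#'
#' The log is a tidy CSV (one row per round x agent); the summary is a JSON
#' file echoing the configuration, the seed, and the best design/response.
#'
#' @param run a `strain_run`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix; defaults to the method name.
#' @return invisibly, the paths written.
#' @export
write_run_log <- function(run, dir, prefix = run$method) {
  stopifnot(inherits(run, "strain_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_path <- file.path(dir, paste0(prefix, "_log.csv"))
  sum_path <- file.path(dir, paste0(prefix, "_summary.json"))
  utils::write.csv(run$log, log_path, row.names = FALSE)
  cfg <- run$config
  cfg$plateau_patience <- NULL # may be Inf, not representable in JSON
  payload <- list(method = run$method, env = run$env_name,
                  config = unclass(cfg), seed = run$config$seed,
                  n_env_calls = run$n_env_calls,
                  best_design = run$best_design,
                  best_response = run$best_response)
  jsonlite::write_json(payload, sum_path, auto_unbox = TRUE, digits = NA)
  invisible(c(log = log_path, summary = sum_path))
}
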