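#' Log-margin transform of a reward
#'
#' Maps an observed reward (a response delta between consecutive rounds) to
#' the margin required of the learned reward surrogate,
#' `M(r) = log2(r + 1)`. Because rewards are deltas they can fall at or below
#' -1, outside the log domain; the input is clamped at `-1 + 1e-6` so the
#' transform stays defined while remaining strictly increasing on the
#' unclamped range.
#'
#' @param r numeric vector of finite rewards.
#' @return numeric vector of margins.
#' @export
#' @examples
#' margin_transform(c(0, 1, 3)) # 0, 1, 2
margin_transform <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) stop("rewards must be finite numbers")
  log2(pmax(r, -1 + 1e-6) + 1)
}

#' Gaussian kernel between two vectors
#'
#' `K(x, x') = exp(-||x - x'||^2 / sigma^2)`.
#'
#' @param x,x2 numeric vectors of equal length.
#' @param sigma positive bandwidth.
#' @return a number in `(0, 1]`.
#' @export
gaussian_kernel <- function(x, x2, sigma) {
  if (length(x) != length(x2)) stop("kernel arguments must have equal length")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  exp(-sum((x - x2)^2) / sigma^2)
}

# full Gaussian kernel matrix between the rows of two matrices
gaussian_kernel_matrix <- function(X, Y = X, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sq <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  sq[sq < 0] <- 0 # numerical round-off
  exp(-sq / sigma^2)
}

#' Joint state-action kernel matrix
#'
#' The Hadamard (element-wise) product of the Gaussian kernel matrices of the
#' states and the actions, `K_SA = K_S * K_A`; positive semidefinite by the
#' Schur product theorem, symmetric with unit diagonal.
#'
#' @param h an [mmr_history()] with at least one record.
#' @param sigma_s,sigma_a positive kernel bandwidths for states and actions.
#' @return a symmetric `length(h)` x `length(h)` matrix.
#' @export
joint_kernel_matrix <- function(h, sigma_s, sigma_a) {
  if (length(h) == 0L) stop("history is empty")
  Ks <- gaussian_kernel_matrix(h$states, sigma = sigma_s)
  Ka <- gaussian_kernel_matrix(h$actions, sigma = sigma_a)
  K <- Ks * Ka
  (K + t(K)) / 2
}

#' Median-heuristic kernel bandwidth
#'
#' The median of all pairwise Euclidean distances between the rows of `X`;
#' the default bandwidth for both the state and the action kernel.
#'
#' @param X numeric matrix (rows are vectors) or list of numeric vectors.
#' @return a strictly positive number. If the median distance is zero the
#'   median of the positive distances is used; if all vectors coincide the
#'   fallback 1.0 is returned with a warning.
#' @export
median_heuristic_bandwidth <- function(X) {
  if (is.list(X)) X <- do.call(rbind, X)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two vectors")
  d <- as.numeric(stats::dist(X))
  m <- stats::median(d)
  if (m <= 0) {
    pos <- d[d > 0]
    if (length(pos) == 0L) {
      warning("all vectors identical; falling back to bandwidth 1.0")
      return(1.0)
    }
    m <- stats::median(pos)
  }
  m
}

#' Solve a box-constrained convex quadratic program
#'
#' Minimizes `0.5 * b' K b - m' b` subject to `0 <= b <= C` by cyclic
#' coordinate descent with exact per-coordinate minimization, which converges
#' for positive semidefinite `K`. Deterministic: coordinates are visited in
#' index order, so degenerate problems resolve identically on every run.
#'
#' @param K symmetric positive semidefinite matrix.
#' @param m numeric vector (linear term).
#' @param C positive upper bound on every coordinate.
#' @param tol convergence tolerance on the largest coordinate update
#'   (default `1e-8`, part of the reproducibility contract). A sweep that no
#'   longer measurably decreases the objective (below machine precision
#'   relative to its magnitude) also counts as converged: on degenerate
#'   (near-singular) kernels coordinates can keep exchanging mass along flat
#'   directions without changing the objective.
#' @param max_sweeps maximum number of full coordinate sweeps.
#' @return list with `beta`, the objective `value`, number of `sweeps`,
#'   and `converged`.
#' @export
solve_box_qp <- function(K, m, C, tol = 1e-8, max_sweeps = 10000L) {
  n <- length(m)
  stopifnot(nrow(K) == n, ncol(K) == n, C > 0)
  beta <- pmin(pmax(m, 0), C) # feasible warm start
  g <- as.numeric(K %*% beta) # g_i = (K beta)_i
  objective <- function(b) 0.5 * sum(b * (K %*% b)) - sum(m * b)
  value <- objective(beta)
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    delta_max <- 0
    for (i in seq_len(n)) {
      kii <- K[i, i]
      if (kii <= 1e-12) {
        # flat direction: move to whichever bound the linear term favours
        target <- if (m[i] - g[i] > 0) C else 0
      } else {
        target <- beta[i] + (m[i] - g[i]) / kii
        target <- min(max(target, 0), C)
      }
      d <- target - beta[i]
      if (d != 0) {
        g <- g + K[, i] * d
        beta[i] <- target
        delta_max <- max(delta_max, abs(d))
      }
    }
    new_value <- objective(beta)
    decreased <- value - new_value
    value <- new_value
    if (delta_max < tol ||
        decreased < .Machine$double.eps * max(1, abs(value))) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, value = value, sweeps = sweeps, converged = converged)
}

# KKT residual of the box QP at beta: gradient K beta - m must be
# >= 0 where beta = 0, <= 0 where beta = C, and = 0 in the interior
box_qp_kkt_residual <- function(K, m, C, beta, bound_tol = 1e-9) {
  grad <- as.numeric(K %*% beta) - m
  at_lo <- beta <= bound_tol
  at_hi <- beta >= C - bound_tol
  interior <- !at_lo & !at_hi
  max(c(0,
        -grad[at_lo],        # must be >= 0 at the lower bound
        grad[at_hi],         # must be <= 0 at the upper bound
        abs(grad[interior])))
}

#' Fit a Maximum Margin Regression policy
#'
#' Learns the action-recommendation policy from a state-action-reward
#' history. The learner is an SVM-like kernel machine: each training triplet
#' demands that the predicted reward of its state-action pair exceed the
#' margin `log2(r + 1)`, slack violations being traded off against a
#' Frobenius-norm regularizer by `c_xi`. In the kernelized dual this is the
#' box-constrained quadratic program
#' `min 0.5 b' K_SA b - M' b, 0 <= b <= c_xi`, with `K_SA` the Hadamard
#' product of the Gaussian state and action kernel matrices. Triplets with
#' high rewards are thereby encouraged to become support vectors.
#'
#' @param h an [mmr_history()] with at least one record and finite rewards.
#' @param sigma_s,sigma_a state/action kernel bandwidths; `NULL` (default)
#'   selects the median heuristic over the history.
#' @param c_xi positive box bound (regularization/error trade-off), default 1.
#' @param tol QP solver tolerance.
#' @return an object of class `mmr`: dual coefficients `beta`, the training
#'   history, resolved bandwidths, `c_xi`, the dual `objective` and solver
#'   diagnostics.
#' @seealso [predict.mmr()]
#' @export
#' @examples
#' h <- mmr_history(states = matrix(rnorm(6), 3),
#'                  actions = matrix(rnorm(6), 3),
#'                  rewards = c(0.5, -0.2, 1.2))
#' fit <- mmr(h)
#' coef(fit)
mmr <- function(h, sigma_s = NULL, sigma_a = NULL, c_xi = 1, tol = 1e-8) {
  if (!inherits(h, "mmr_history")) stop("h must be an mmr_history")
  if (length(h) == 0L) stop("history is empty")
  if (!all(is.finite(h$rewards))) stop("rewards must be finite")
  if (!is.numeric(c_xi) || c_xi <= 0) stop("c_xi must be positive")

  resolve <- function(sig, X) {
    if (is.null(sig) || identical(sig, "median")) {
      if (nrow(X) < 2L) 1.0 else median_heuristic_bandwidth(X)
    } else {
      stopifnot(is.numeric(sig), sig > 0)
      sig
    }
  }
  sigma_s <- resolve(sigma_s, h$states)
  sigma_a <- resolve(sigma_a, h$actions)

  K <- joint_kernel_matrix(h, sigma_s, sigma_a)
  M <- margin_transform(h$rewards)
  sol <- solve_box_qp(K, M, c_xi, tol = tol)
  if (!sol$converged) {
    # retry once with a 10x looser tolerance before giving up
    sol <- solve_box_qp(K, M, c_xi, tol = tol * 10)
    if (!sol$converged) {
      stop(sprintf("MMR dual QP did not converge (%d sweeps, tol %g)",
                   sol$sweeps, tol * 10))
    }
  }
  structure(list(beta = sol$beta, history = h,
                 sigma_s = sigma_s, sigma_a = sigma_a, c_xi = c_xi,
                 objective = sol$value,
                 solver = list(sweeps = sol$sweeps, tol = tol)),
            class = "mmr")
}

#' @export
coef.mmr <- function(object, ...) object$beta

#' Predict actions from a fitted MMR policy
#'
#' Three pre-image solutions of the kernelized policy are offered. The
#' default, `type = "sum"`, is the approximate pre-image in closed form: for
#' a query state `s` the recommended action is the kernel-weighted
#' combination of the training actions, `sum_i beta_i a_i K_S(s, s_i)`;
#' actions of high-reward support vectors taken in similar states dominate.
#' `type = "normalized"` divides that sum by `sum_i beta_i K_S(s, s_i)` (a
#' convex re-weighting that keeps the action inside the hull of the training
#' actions). `type = "preimage"` solves the pre-image problem numerically:
#' it maximizes the learned reward surrogate over actions,
#' `g(a) = sum_i beta_i K_S(s, s_i) K_A(a, a_i)`, by fixed-point (mean-shift)
#' iteration from multiple starts (the weighted action mean and the
#' highest-weight support actions) and returns the best mode found. The
#' numeric pre-image typically recommends larger, better-directed steps than
#' the closed-form sum, whose terms can cancel; it costs
#' O(starts x iterations x history).
#'
#' @param object a fitted [mmr()] policy.
#' @param newstates numeric vector (one state) or matrix (one state per row).
#' @param type pre-image solution: `"sum"` (default), `"normalized"`, or
#'   `"preimage"`.
#' @param ... unused.
#' @return a numeric action vector, or a matrix with one action per row when
#'   `newstates` is a matrix. All types return the zero action where no
#'   support vector carries weight at the query state.
#' @export
predict.mmr <- function(object, newstates,
                        type = c("sum", "normalized", "preimage"), ...) {
  type <- match.arg(type)
  one <- is.vector(newstates)
  if (one) newstates <- matrix(newstates, nrow = 1L)
  newstates <- as.matrix(newstates)
  if (ncol(newstates) != ncol(object$history$states)) {
    stop(sprintf("state has length %d but the policy was trained on length %d",
                 ncol(newstates), ncol(object$history$states)))
  }
  Kq <- gaussian_kernel_matrix(newstates, object$history$states, object$sigma_s)
  out <- switch(type,
    sum = Kq %*% (object$beta * object$history$actions),
    normalized = {
      num <- Kq %*% (object$beta * object$history$actions)
      den <- as.numeric(Kq %*% object$beta)
      num[den > 1e-12, ] <- num[den > 1e-12, , drop = FALSE] / den[den > 1e-12]
      num
    },
    preimage = {
      A <- matrix(0, nrow(newstates), ncol(object$history$actions))
      for (m in seq_len(nrow(newstates))) {
        A[m, ] <- preimage_action(object$beta * Kq[m, ],
                                  object$history$actions, object$sigma_a)
      }
      A
    })
  if (one) as.numeric(out) else out
}

# numeric pre-image: argmax_a sum_i w_i K_A(a, a_i) by mean-shift iteration
# from the weighted action mean and the top-weight support actions
preimage_action <- function(w, actions, sigma_a, n_starts = 4L,
                            max_iter = 100L, tol = 1e-10) {
  if (sum(w) < 1e-12) return(rep(0, ncol(actions)))
  g <- function(a) {
    sum(w * exp(-rowSums(sweep(actions, 2L, a)^2) / sigma_a^2))
  }
  shift <- function(a) {
    for (it in seq_len(max_iter)) {
      ka <- w * exp(-rowSums(sweep(actions, 2L, a)^2) / sigma_a^2)
      if (sum(ka) < 1e-12) return(a)
      a2 <- colSums(ka * actions) / sum(ka)
      if (sqrt(sum((a2 - a)^2)) < tol) return(a2)
      a <- a2
    }
    a
  }
  starts <- list(colSums(w * actions) / sum(w))
  top <- order(w, decreasing = TRUE)[seq_len(min(n_starts - 1L, sum(w > 0)))]
  for (i in top) starts <- c(starts, list(actions[i, ]))
  cands <- lapply(starts, shift)
  cands[[which.max(vapply(cands, g, numeric(1)))]]
}

#' @export
print.mmr <- function(x, ...) {
  nsv <- sum(x$beta > 1e-9)
  cat(sprintf("MMR policy: %d training triplets, %d support vectors\n",
              length(x$history), nsv))
  cat(sprintf("  sigma_s = %.4g, sigma_a = %.4g, c_xi = %.4g, dual objective = %.6g\n",
              x$sigma_s, x$sigma_a, x$c_xi, x$objective))
  invisible(x)
}

#' @export
summary.mmr <- function(object, ...) {
  beta <- object$beta
  out <- list(n = length(beta),
              n_support = sum(beta > 1e-9),
              n_at_bound = sum(beta >= object$c_xi - 1e-9),
              objective = object$objective,
              sigma_s = object$sigma_s, sigma_a = object$sigma_a,
              c_xi = object$c_xi)
  class(out) <- "summary.mmr"
  out
}

#' @export
print.summary.mmr <- function(x, ...) {
  cat(sprintf(paste0("MMR policy summary\n  triplets: %d  support vectors: %d",
                     "  at box bound: %d\n  dual objective: %.6g",
                     "  sigma_s: %.4g  sigma_a: %.4g  c_xi: %.4g\n"),
              x$n, x$n_support, x$n_at_bound, x$objective,
              x$sigma_s, x$sigma_a, x$c_xi))
  invisible(x)
}

#' Serialize / restore an MMR policy as JSON
#'
#' The policy state (dual coefficients, training triplets and kernel
#' parameters) round-trips bit-exactly for the stored decimals.
#'
#' @param object a fitted [mmr()] policy.
#' @param path file path; `NULL` returns the JSON string.
#' @return `mmr_to_json`: the path (invisibly) or a JSON string;
#'   `mmr_from_json`: the restored `mmr` object.
#' @export
mmr_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "mmr"))
  payload <- list(beta = object$beta,
                  states = unname(apply(object$history$states, 1L, identity,
                                        simplify = FALSE)),
                  actions = unname(apply(object$history$actions, 1L, identity,
                                         simplify = FALSE)),
                  rewards = object$history$rewards,
                  sigma_s = object$sigma_s, sigma_a = object$sigma_a,
                  c_xi = object$c_xi, objective = object$objective)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname mmr_to_json
#' @param json a JSON string or file path produced by [mmr_to_json()].
#' @export
mmr_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  h <- mmr_history(as.matrix(x$states), as.matrix(x$actions), x$rewards)
  structure(list(beta = as.numeric(x$beta), history = h,
                 sigma_s = x$sigma_s, sigma_a = x$sigma_a, c_xi = x$c_xi,
                 objective = x$objective,
                 solver = list(sweeps = NA_integer_, tol = NA_real_)),
            class = "mmr")
}
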