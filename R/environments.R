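#' Enzyme-level transform and its inverse
#'
#' Normalized total enzyme pools live in `[0.1, 10]` (10-fold down- to
#' 10-fold up-regulation around the wild-type level 1). The optimizer works
#' in the transformed space `f(e) = (e - 1) / (e + 1)`, which maps the
#' wild-type to 0, knock-out (`e = 0`) to -1 and the up-regulation range
#' `(1, 10]` onto `(0, 0.82]`, nearly symmetric with the down-regulation
#' image `[-0.818, 0)`.
#'
#' @param e_hat numeric vector of non-negative normalized enzyme pools.
#' @return `transform_enzyme`: values in `[-1, 1)`; strictly increasing.
#' @export
#' @examples
#' transform_enzyme(c(0, 1, 10)) # -1, 0, 9/11
#' inverse_transform(transform_enzyme(2.5)) # 2.5
transform_enzyme <- function(e_hat) {
  if (!is.numeric(e_hat) || any(!is.finite(e_hat)) || any(e_hat < 0)) {
    stop("enzyme levels must be finite and non-negative")
  }
  (e_hat - 1) / (e_hat + 1)
}

#' @rdname transform_enzyme
#' @param y numeric vector in `(-1, 1)`, transformed enzyme levels.
#' @return `inverse_transform`: the raw enzyme levels `(1 + y) / (1 - y)`.
#' @export
inverse_transform <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(abs(y) >= 1)) {
    stop("transformed levels must lie strictly inside (-1, 1)")
  }
  (1 + y) / (1 - y)
}

# transformed bounds of the admissible enzyme range [0.1, 10]
enzyme_design_bounds <- function(n) {
  rbind(lo = rep(transform_enzyme(0.1), n),
        hi = rep(transform_enzyme(10), n))
}

#' Construct a strain-optimization environment
#'
#' An environment is the Test phase of the DBTL cycle behind a uniform step
#' contract: a design vector in the optimizer's working space goes in, an
#' observed state vector and a scalar response come out. External simulators
#' (e.g. genome-scale kinetic models run out of process) can be attached by
#' implementing this contract.
#'
#' @param name label of the environment.
#' @param n_design,n_state dimensions of the design and state vectors.
#' @param bounds 2 x `n_design` matrix (rows `lo`, `hi`): the box the
#'   optimizer searches, in the environment's working space.
#' @param step `function(design, action = NULL)` returning
#'   `list(state =, response =)`; must be deterministic given the design
#'   (and the environment's own seed). `action`, when supplied by the caller,
#'   is the executed design delta — only stochastic wrappers use it.
#' @param baseline_design design of the unmodified (wild-type) strain in the
#'   working space; defaults to the box centre.
#' @param to_raw,from_raw optional maps between the working space and the raw
#'   (untransformed) design space; identity by default.
#' @param ... extra fields stored on the environment (e.g. test oracles).
#' @return an object of class `strain_env`. `baseline_response` and
#'   `baseline_state` are filled by one call to `step(baseline_design)`.
#' @export
strain_env <- function(name, n_design, n_state, bounds, step,
                       baseline_design = NULL, to_raw = identity,
                       from_raw = identity, ...) {
  stopifnot(is.function(step), nrow(bounds) == 2L, ncol(bounds) == n_design,
            all(bounds[1L, ] <= bounds[2L, ]))
  if (is.null(baseline_design)) baseline_design <- colMeans(bounds)
  base <- step(baseline_design, action = NULL)
  env <- list(name = name, n_design = as.integer(n_design),
              n_state = as.integer(n_state),
              bounds = bounds, step = step,
              baseline_design = baseline_design,
              baseline_state = base$state,
              baseline_response = base$response,
              to_raw = to_raw, from_raw = from_raw, ...)
  class(env) <- "strain_env"
  env
}

#' @export
print.strain_env <- function(x, ...) {
  cat(sprintf("<strain_env '%s': %d design dims, %d state dims, baseline response %.4g>\n",
              x$name, x$n_design, x$n_state, x$baseline_response))
  invisible(x)
}

#' Smooth kinetic-model surrogate environment
#'
#' A deterministic synthetic environment standing in for a genome-scale
#' kinetic simulation: the response surface is a single smooth peak in the
#' transformed enzyme space,
#' `y(d) = y_max * exp(-(d - f*)' Q (d - f*))`, with a seeded optimum `f*`
#' drawn coordinate-wise uniform in `[-0.6, 0.6]`, a random symmetric
#' positive-definite `Q` (eigenvalues uniform in `[0.5, 2]`, scaled by
#' `1 / width^2`), and a state readout `s = tanh(B d)` through a random
#' linear map `B` (`n_state = 2 n_enzymes`, standard normal entries). The
#' optimum and `y_max` are exposed for verification.
#'
#' @param n_enzymes number of controllable enzymes (>= 2).
#' @param seed integer seed fixing `f*`, `Q` and `B`.
#' @param y_max peak response (default 10).
#' @param width widens (`> 1`) or narrows the peak; default 1.
#' @return a [strain_env()] whose working space is the transformed enzyme
#'   space clipped to `[f(0.1), f(10)]`, with fields `f_star`, `Q`, `y_max`.
#' @export
make_surface_env <- function(n_enzymes, seed, y_max = 10, width = 1) {
  stopifnot(n_enzymes >= 2L, width > 0)
  stream <- rng_stream(derive_seed(seed, "surface_env"))
  n_state <- 2L * n_enzymes
  params <- with_rng(stream, {
    f_star <- stats::runif(n_enzymes, -0.6, 0.6)
    A <- matrix(stats::rnorm(n_enzymes^2), n_enzymes)
    U <- qr.Q(qr(A))
    lambda <- stats::runif(n_enzymes, 0.5, 2)
    Q <- U %*% diag(lambda, n_enzymes) %*% t(U) / width^2
    B <- matrix(stats::rnorm(n_state * n_enzymes), n_state, n_enzymes)
    list(f_star = f_star, Q = (Q + t(Q)) / 2, B = B)
  })
  step <- function(design, action = NULL) {
    stopifnot(length(design) == n_enzymes)
    d <- as.numeric(design) - params$f_star
    list(state = tanh(as.numeric(params$B %*% as.numeric(design))),
         response = y_max * exp(-sum(d * (params$Q %*% d))))
  }
  strain_env(name = sprintf("surface-%d", n_enzymes),
             n_design = n_enzymes, n_state = n_state,
             bounds = enzyme_design_bounds(n_enzymes), step = step,
             baseline_design = rep(0, n_enzymes),
             to_raw = inverse_transform, from_raw = transform_enzyme,
             f_star = params$f_star, Q = params$Q, B = params$B,
             y_max = y_max)
}

#' Synthetic combinatorial promoter library
#'
#' Emulates a combinatorial yeast expression library: `n_genes` genes, each
#' at coded promoter strengths `{0, 0.2, ..., 1}`, with a scalar
#' biosensor-readout response. The full grid (6^5 = 7776 strains for the
#' defaults) is enumerated, a seeded `coverage` fraction of strains is
#' retained, and the response is a concave quadratic landscape with pairwise
#' gene-gene interaction terms and multiplicative log-normal measurement
#' noise (`sigma_log = 0.1`). Three seeded correlated covariates accompany
#' the design columns as the recorded strain state.
#'
#' @param n_genes number of tunable genes (default 5).
#' @param strengths coded strength levels (default `seq(0, 1, by = 0.2)`).
#' @param coverage fraction of the grid present in the library, in `(0, 1]`.
#' @param seed integer seed.
#' @param sigma_log log-normal noise sd on the log scale (default 0.1).
#' @return a `data.frame` with columns `gene_1..gene_n`, `state_1..state_3`
#'   and `response`, with attributes `optimum` (the row index of the maximal
#'   realized response), `optimum_response`, `argmax_design` (the noise-free
#'   quadratic's grid argmax) and `response_max_deterministic`.
#' @export
make_synthetic_library <- function(n_genes = 5L, strengths = seq(0, 1, by = 0.2),
                                   coverage = 1, seed = 1L, sigma_log = 0.1) {
  stopifnot(coverage > 0, coverage <= 1, n_genes >= 1L)
  grid <- as.matrix(expand.grid(rep(list(strengths), n_genes)))
  colnames(grid) <- paste0("gene_", seq_len(n_genes))
  stream <- rng_stream(derive_seed(seed, "synthetic_library"))
  out <- with_rng(stream, {
    keep <- sort(sample.int(nrow(grid), size = max(1L, round(coverage * nrow(grid)))))
    X <- grid[keep, , drop = FALSE]
    x_star <- strengths[sample.int(length(strengths), n_genes, replace = TRUE)]
    # mild random interactions keep the landscape non-separable but concave
    A <- diag(stats::runif(n_genes, 0.8, 1.2), n_genes)
    for (i in seq_len(n_genes - 1L)) {
      for (j in seq((i + 1L), n_genes)) {
        A[i, j] <- A[j, i] <- stats::runif(1, -0.15, 0.15)
      }
    }
    D <- sweep(X, 2L, x_star)
    quad <- rowSums((D %*% A) * D)
    y_det <- 10 * (1 - 0.9 * quad / max(quad))
    noise <- exp(stats::rnorm(length(y_det), 0, sigma_log))
    W <- matrix(stats::rnorm(n_genes * 3L), n_genes, 3L)
    S <- tanh(X %*% W) + matrix(stats::rnorm(nrow(X) * 3L, sd = 0.05), ncol = 3L)
    colnames(S) <- paste0("state_", 1:3)
    lib <- data.frame(X, S, response = y_det * noise, check.names = FALSE)
    attr(lib, "argmax_design") <- X[which.max(y_det), ]
    attr(lib, "response_max_deterministic") <- max(y_det)
    attr(lib, "optimum") <- which.max(lib$response)
    attr(lib, "optimum_response") <- max(lib$response)
    lib
  })
  out
}

#' Library-lookup environment
#'
#' Turns a combinatorial strain-library table into an environment: a proposed
#' design is matched to its nearest library strain, where a strain matches
#' when every coded gene strength differs by strictly less than `tolerance`
#' element-wise. Among multiple matches, the smallest Euclidean distance
#' wins, ties broken by the lowest row index. With no match the experiment is
#' scored zero (response 0, zero state) — the proposed strain simply does not
#' exist in the library.
#'
#' @param library a `data.frame` with `gene_*` design columns, optional
#'   `state_*` columns and a `response` column (see
#'   [make_synthetic_library()] and [read_library_csv()]).
#' @param tolerance strict element-wise matching threshold (default 0.2, the
#'   coded-strength grid spacing).
#' @return a [strain_env()] over the coded-strength box `[0, 1]^n`, with
#'   field `library`.
#' @export
make_library_env <- function(library, tolerance = 0.2) {
  gene_cols <- grep("^gene_", names(library), value = TRUE)
  state_cols <- grep("^state_", names(library), value = TRUE)
  if (length(gene_cols) == 0L || !"response" %in% names(library)) {
    stop("library must have gene_* columns and a response column")
  }
  X <- as.matrix(library[, gene_cols, drop = FALSE])
  S <- if (length(state_cols)) as.matrix(library[, state_cols, drop = FALSE]) else
    matrix(numeric(0), nrow(library), 0L)
  if (!is.numeric(X) || anyNA(X) || !is.numeric(library$response) || anyNA(library$response)) {
    stop("library design and response columns must be numeric and complete")
  }
  y <- as.numeric(library$response)
  n_genes <- ncol(X)
  n_state <- max(1L, ncol(S))
  step <- function(design, action = NULL) {
    stopifnot(length(design) == n_genes)
    dif <- abs(sweep(X, 2L, as.numeric(design)))
    hit <- which(apply(dif, 1L, max) < tolerance)
    if (length(hit) == 0L) {
      return(list(state = rep(0, n_state), response = 0))
    }
    d2 <- rowSums(dif[hit, , drop = FALSE]^2)
    row <- hit[which.min(d2)] # which.min takes the first minimum: lowest index
    st <- if (ncol(S)) as.numeric(S[row, ]) else 0
    list(state = st, response = y[row])
  }
  strain_env(name = sprintf("library-%d", nrow(library)),
             n_design = n_genes, n_state = n_state,
             bounds = rbind(lo = rep(0, n_genes), hi = rep(1, n_genes)),
             step = step, baseline_design = rep(0.5, n_genes),
             library = library, tolerance = tolerance)
}

#' Read / write a strain library CSV
#'
#' Columns: `gene_1..gene_n` coded strengths, optional `state_*` covariates,
#' and `response`; header required, UTF-8.
#'
#' @param path CSV file path.
#' @return `read_library_csv`: a validated `data.frame`.
#' @export
read_library_csv <- function(path) {
  lib <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  gene_cols <- grep("^gene_", names(lib), value = TRUE)
  if (length(gene_cols) == 0L || !"response" %in% names(lib)) {
    stop("malformed library: need gene_* columns and a response column")
  }
  num <- vapply(lib[c(gene_cols, "response")], is.numeric, logical(1))
  if (!all(num)) stop("malformed library: non-numeric design or response columns")
  lib
}

#' @rdname read_library_csv
#' @param library the library table.
#' @export
write_library_csv <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Noise specification for the three observation channels
#'
#' Percent noise levels on the state readout, the executed action, and the
#' response. A level `m` means a zero-mean Gaussian with standard deviation
#' `m`% of, respectively, the median state value, the minimum absolute action
#' coordinate, and the absolute response.
#'
#' @param m_state,m_action,m_response non-negative percentages.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(m_state = 0, m_action = 0, m_response = 0) {
  stopifnot(m_state >= 0, m_action >= 0, m_response >= 0)
  structure(list(m_state = m_state, m_action = m_action,
                 m_response = m_response), class = "noise_spec")
}

#' Wrap an environment with observation noise
#'
#' Emulates measurement error and imprecise genetic implementation around a
#' deterministic environment: (i) the executed design delta (action) is
#' perturbed before application by Gaussian noise with sd
#' `m_action`% of the minimum absolute action coordinate; (ii) the returned
#' state receives additive Gaussian noise with sd `m_state`% of the median of
#' the state values (the absolute-value median if that median is not
#' positive); (iii) the returned response receives additive Gaussian noise
#' with sd `m_response`% of its absolute value. A channel at 0% is disabled
#' exactly. When the action contains a zero coordinate the action-noise sd
#' would collapse to zero; it is floored at `1e-8 * ||a||`.
#'
#' @param env a [strain_env()].
#' @param spec a [noise_spec()].
#' @param seed integer seed of the wrapper's private noise stream.
#' @return a [strain_env()] with the same contract; deterministic given
#'   `seed` and the query sequence.
#' @export
with_noise <- function(env, spec, seed) {
  stopifnot(inherits(env, "strain_env"), inherits(spec, "noise_spec"))
  if (spec$m_state == 0 && spec$m_action == 0 && spec$m_response == 0) return(env)
  stream <- rng_stream(derive_seed(seed, "noise"))
  inner <- env$step
  lo <- env$bounds[1L, ]; hi <- env$bounds[2L, ]
  step <- function(design, action = NULL) {
    design <- as.numeric(design)
    if (spec$m_action > 0 && !is.null(action) && any(action != 0)) {
      sd_a <- (spec$m_action / 100) * min(abs(action))
      if (sd_a <= 0) sd_a <- 1e-8 * sqrt(sum(action^2))
      eps <- with_rng(stream, stats::rnorm(length(design), 0, sd_a))
      design <- pmin(pmax(design + eps, lo), hi)
    }
    out <- inner(design, action = action)
    if (spec$m_state > 0) {
      med <- stats::median(out$state)
      if (med <= 0) med <- stats::median(abs(out$state))
      if (med > 0) {
        out$state <- out$state +
          with_rng(stream, stats::rnorm(length(out$state), 0, (spec$m_state / 100) * med))
      }
    }
    if (spec$m_response > 0 && abs(out$response) > 0) {
      out$response <- out$response +
        with_rng(stream, stats::rnorm(1L, 0, (spec$m_response / 100) * abs(out$response)))
    }
    out
  }
  env2 <- env
  env2$step <- step
  env2$name <- sprintf("%s+noise(%g,%g,%g)", env$name, spec$m_state,
                       spec$m_action, spec$m_response)
  env2$noise <- spec
  # the baseline of the wrapped environment stays the noiseless one: it is a
  # fixed reference (wild-type response), not a measurement of this run
  env2
}
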