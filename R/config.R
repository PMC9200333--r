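#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON experiment specification, fills documented defaults
#' (warm-up 5 rounds, 40 iterations, 4 agents in 2 groups, perturbation
#' coefficient 0.8, replacement period 5, box bound `c_xi` 1, upper quantile
#' 0.75) and rejects unknown keys. Recognized keys: `method` (one of
#' `marl`, `bogp`, `rand`, or a list under `methods`), `env` (`surface`,
#' `library` or `custom`), `n_enzymes`, `library_csv`, `coverage`,
#' `tolerance`, `seed`, `seeds`, `noise` (`m_state`/`m_action`/`m_response`),
#' `out`, and all [marl_config()] fields.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return an object of class `experiment_spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_experiment_spec(raw)
}

#' @rdname load_config
#' @param x a named list of configuration values.
#' @export
as_experiment_spec <- function(x) {
  known <- c("method", "methods", "env", "n_enzymes", "library_csv",
             "coverage", "tolerance", "env_seed", "y_max", "width",
             "n_agents", "n_groups", "tau", "n_iterations", "perturb_c",
             "replace_every_k", "upper_quantile", "seed", "seeds",
             "sigma_s", "sigma_a", "c_xi", "predict", "plateau_patience",
             "noise", "out")
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  methods <- x$methods %||% x$method %||% "marl"
  if (!all(methods %in% c("marl", "bogp", "rand"))) {
    stop("method must be one of marl, bogp, rand")
  }
  env_name <- x$env %||% "surface"
  if (!env_name %in% c("surface", "library", "custom")) {
    stop("env must be one of surface, library, custom")
  }
  seeds <- x$seeds %||% x$seed %||% 1L
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  cfg <- marl_config(n_agents = x$n_agents %||% 4L,
                     n_groups = x$n_groups %||% 2L,
                     tau = x$tau %||% 5L,
                     n_iterations = x$n_iterations %||% 40L,
                     perturb_c = x$perturb_c %||% 0.8,
                     replace_every_k = x$replace_every_k %||% 5L,
                     upper_quantile = x$upper_quantile %||% 0.75,
                     seed = as.integer(seeds[[1L]]),
                     sigma_s = x$sigma_s %||% "median",
                     sigma_a = x$sigma_a %||% "median",
                     c_xi = x$c_xi %||% 1,
                     predict = x$predict %||% "sum",
                     plateau_patience = x$plateau_patience %||% Inf)
  ns <- x$noise %||% list()
  spec <- list(methods = unlist(methods), env = env_name,
               n_enzymes = as.integer(x$n_enzymes %||% 6L),
               library_csv = x$library_csv,
               coverage = x$coverage %||% 0.1,
               tolerance = x$tolerance %||% 0.2,
               env_seed = as.integer(x$env_seed %||% 1L),
               y_max = x$y_max %||% 10,
               width = x$width %||% 1,
               seeds = as.integer(unlist(seeds)),
               config = cfg,
               noise = noise_spec(m_state = ns$m_state %||% 0,
                                  m_action = ns$m_action %||% 0,
                                  m_response = ns$m_response %||% 0),
               out = x$out)
  class(spec) <- "experiment_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an experiment spec to YAML
#'
#' @param spec an `experiment_spec`.
#' @param path output file path.
#' @return the path, invisibly. `load_config(save_config(spec, p))`
#'   reproduces the spec.
#' @export
save_config <- function(spec, path) {
  stopifnot(inherits(spec, "experiment_spec"))
  cfg <- unclass(spec$config)
  cfg$seed <- NULL
  if (!is.finite(cfg$plateau_patience)) cfg$plateau_patience <- NULL
  payload <- c(list(methods = as.list(spec$methods), env = spec$env,
                    n_enzymes = spec$n_enzymes, coverage = spec$coverage,
                    tolerance = spec$tolerance, env_seed = spec$env_seed,
                    y_max = spec$y_max, width = spec$width,
                    seeds = as.list(spec$seeds)),
               cfg,
               list(noise = unclass(spec$noise)))
  if (!is.null(spec$library_csv)) payload$library_csv <- spec$library_csv
  if (!is.null(spec$out)) payload$out <- spec$out
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Instantiate the environment an experiment spec names
#'
#' @param spec an `experiment_spec`.
#' @return a [strain_env()].
#' @export
build_env <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  switch(spec$env,
         surface = make_surface_env(spec$n_enzymes, seed = spec$env_seed,
                                    y_max = spec$y_max, width = spec$width),
         library = {
           lib <- if (!is.null(spec$library_csv)) {
             read_library_csv(spec$library_csv)
           } else {
             make_synthetic_library(coverage = spec$coverage,
                                    seed = spec$env_seed)
           }
           make_library_env(lib, tolerance = spec$tolerance)
         },
         stop("a 'custom' environment must be constructed by the caller"))
}

#' Run several optimizers under a shared protocol
#'
#' For each seed one warm-up dataset is generated once and handed to every
#' method, so all methods start from byte-identical experiments and consume
#' the same environment-call budget; trajectories are then aggregated per
#' method.
#'
#' @param env a [strain_env()].
#' @param config a [marl_config()].
#' @param methods character vector from `c("marl", "bogp", "rand")`,
#'   length >= 2.
#' @param seeds integer vector of root seeds.
#' @return an object of class `method_comparison`: `trajectories` (the
#'   per-method [aggregate_trajectories()] tables, stacked with a `method`
#'   column), `final` (per-method final-round medians), and the raw `runs`.
#' @export
compare_methods <- function(env, config, methods = c("marl", "rand"),
                            seeds = 1:5) {
  if (length(methods) < 2L) stop("need at least two methods to compare")
  runners <- list(marl = run_marl, rand = random_search, bogp = bo_gp)
  if (!all(methods %in% names(runners))) stop("unknown method name")
  runs <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) runs[[m]] <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    wd <- warmup(env, cfg)
    for (m in methods) {
      runs[[m]][[k]] <- runners[[m]](env, cfg, warmup_data = wd)
    }
  }
  trajectories <- do.call(rbind, lapply(methods, function(m) {
    tr <- aggregate_trajectories(runs[[m]])
    tr$method <- m
    tr
  }))
  final <- vapply(methods, function(m) {
    tr <- trajectories[trajectories$method == m, ]
    tr$median[which.max(tr$round)]
  }, numeric(1))
  structure(list(trajectories = trajectories, final = final, runs = runs,
                 seeds = seeds, env_name = env$name),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison on %s, %d seeds>\n", x$env_name,
              length(x$seeds)))
  cat("final-round median best-found:\n")
  for (m in names(x$final)) cat(sprintf("  %-5s %.6g\n", m, x$final[[m]]))
  invisible(x)
}

#' Write bundled fixture files
#'
#' Writes (i) three surface-environment configurations named after commonly
#' engineered E. coli products, with the corresponding numbers of
#' controllable enzymes (succinic acid: 6; acetate: 13; ethanol: 13);
#' (ii) a synthetic combinatorial library CSV at coverage 0.1; (iii) a
#' worked-example JSON bundle with small hand-checkable MMR and perturbation
#' cases. All content is deterministic in `seed`.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  products <- list(
    list(name = "succinic-acid", n_enzymes = 6L,
         enzymes = c("ICL", "PPC", "ENO", "FUM", "ICDHyr", "SUCCt2_2pp_ex_H")),
    list(name = "acetate", n_enzymes = 13L,
         enzymes = c("RPI", "PFL", "GLCptspp_ex_exi", "HSK", "THRS", "IPPS",
                     "IPMD", "OMCDC", "IPPMIb", "IPPMIa", "HSDy", "ASPK",
                     "LDH_D")),
    list(name = "ethanol", n_enzymes = 13L,
         enzymes = c("PFL", "FRD2", "RPI", "GLCptspp_ex_exi", "HSK", "LDH_D",
                     "ASPK", "THRS", "IPPS", "IPMD", "OMCDC", "IPPMIb",
                     "IPPMIa")))
  paths <- character(0)
  for (p in products) {
    spec <- as_experiment_spec(list(method = "marl", env = "surface",
                                    n_enzymes = p$n_enzymes,
                                    env_seed = derive_seed(seed, p$name) %% 10000L,
                                    seeds = list(1L, 2L, 3L, 4L, 5L)))
    path <- file.path(out_dir, paste0(p$name, ".yaml"))
    save_config(spec, path)
    # append the enzyme labels as a comment block for traceability
    cat(paste0("# enzymes: ", paste(p$enzymes, collapse = ", "), "\n"),
        file = path, append = TRUE)
    paths <- c(paths, path)
  }
  lib <- make_synthetic_library(coverage = 0.1, seed = seed)
  # fixture serialization keeps 7 significant digits to stay compact; the
  # measurement noise floor (sigma_log = 0.1) is orders of magnitude larger
  for (cl in names(lib)) {
    if (is.numeric(lib[[cl]])) lib[[cl]] <- signif(lib[[cl]], 7)
  }
  lib_path <- file.path(out_dir, "synthetic_library.csv")
  write_library_csv(lib, lib_path)
  paths <- c(paths, lib_path)

  # worked examples: small exactly-checkable cases
  h <- mmr_history(states = rbind(c(0, 0), c(1, 0)),
                   actions = rbind(c(1, 0), c(0, 1)),
                   rewards = c(1, 3))
  fit <- mmr(h, sigma_s = 1, sigma_a = 1, c_xi = 10)
  set.seed(derive_seed(seed, "examples"))
  pert_in <- rbind(c(1, 0), c(sqrt(0.5), sqrt(0.5)))
  examples <- list(
    margin = list(r = c(0, 1, 3), M = margin_transform(c(0, 1, 3))),
    transform = list(e = c(0, 0.1, 1, 10),
                     f = transform_enzyme(c(0, 0.1, 1, 10))),
    mmr = jsonlite::fromJSON(mmr_to_json(fit)),
    perturbation = list(input = pert_in, c = 0.8,
                        output = perturb_agents(pert_in, 0.8)))
  ex_path <- file.path(out_dir, "worked_examples.json")
  jsonlite::write_json(examples, ex_path, digits = NA, auto_unbox = TRUE)
  paths <- c(paths, ex_path)
  invisible(paths)
}
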