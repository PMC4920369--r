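#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file into a validated `run_config`.
#' Unknown keys are rejected; omitted keys take the reference defaults
#' (`N = (20, 2)`, `W = 0.5`, `b = 3.0`, `c = 1.5`, equal capacities,
#' symmetric migration `m = 0.05`, `rho = 0`). Every stochastic mode
#' requires a seed.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_run_config(raw)
}

run_config_defaults <- function() {
  list(mode = NULL, N = c(20L, 2L), capacity = c(1, 1),
       W = c(0.5, 0.5), b = c(3, 3), c = c(1.5, 1.5),
       m = 0.05, rho = 0,
       m_values = NULL, rho_values = NULL, grid_step = 0.02,
       z1 = NULL, z2 = NULL, start = NULL,
       architecture = "A", pop_size = 4000, cycles = 5000,
       replicates = 1, record_every = 50,
       seed = NULL, out_dir = ".", verbose = TRUE)
}

#' Validate a configuration list
#'
#' @param x a named list of configuration values.
#' @return Object of class `"run_config"` with defaults resolved.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  modes <- c("gradient", "equilibrium", "region", "sweep", "simulate", "info")
  if (is.null(cfg$mode) || !cfg$mode %in% modes)
    stop("`mode` must be one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  # cue_model() performs the parameter validation (including rho <= 0.5)
  cfg$model <- cue_model(N = cfg$N, capacity = cfg$capacity, W = cfg$W,
                         b = cfg$b, c = cfg$c, m = cfg$m, rho = cfg$rho)
  if (cfg$mode == "simulate" && is.null(cfg$seed))
    stop("mode 'simulate' requires a seed", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Save a configuration
#'
#' @param config a `"run_config"`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$model <- NULL
  x <- Filter(Negate(is.null), x)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' Execute a configured run
#'
#' Dispatches a `run_config` to the corresponding analysis, writes its
#' tabular outputs (CSV for tables, TSV for grids) and a JSON manifest
#' (parameters, seed, package version, timings) into the configured output
#' directory, and returns the result object invisibly.
#'
#' Modes: `gradient` (selection gradient at a dimorphism), `equilibrium`
#' (gradient-path search), `region` (coexistence mask), `sweep`
#' (equilibria over `m_values` x `rho_values`), `simulate`
#' (individual-based run) and `info` (cue information of the analytic
#' equilibrium).
#'
#' @param config a `"run_config"` (or path to one).
#' @return The mode's result object, invisibly; artifacts on disk.
#' @export
run_command <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, msg)
    if (isTRUE(config$verbose)) message(msg)
  }
  model <- config$model
  if (!is.null(config$seed)) set.seed(config$seed)
  say("mode %s starting", config$mode)
  extra <- list()
  res <- switch(config$mode,
    gradient = {
      z <- c(config$z1, config$z2)
      stopifnot(length(z) == 2L)
      g <- selection_gradient(z, model)
      utils::write.csv(data.frame(z1 = z[1], z2 = z[2],
                                  g1 = g[1], g2 = g[2]),
                       file.path(config$out_dir, "gradient.csv"),
                       row.names = FALSE)
      g
    },
    equilibrium = {
      s0 <- if (!is.null(config$start)) config$start else auto_start(model)
      if (is.null(s0)) stop("no protected starting dimorphism", call. = FALSE)
      eqm <- ascend_to_equilibrium(s0, model)
      utils::write.csv(data.frame(z1 = eqm$z[1], z2 = eqm$z[2],
                                  status = eqm$status, steps = eqm$steps),
                       file.path(config$out_dir, "equilibrium.csv"),
                       row.names = FALSE)
      eqm
    },
    region = {
      reg <- coexistence_region(model, config$grid_step)
      utils::write.table(reg$mask,
                         file.path(config$out_dir, "region_mask.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      extra$region_empty <- !any(reg$mask)
      reg
    },
    sweep = {
      stopifnot(!is.null(config$m_values), !is.null(config$rho_values))
      sw <- sweep_equilibria(model, config$m_values, config$rho_values)
      out <- cbind(as.data.frame(sw), z_mono = attr(sw, "z_mono"))
      utils::write.csv(out, file.path(config$out_dir, "sweep.csv"),
                       row.names = FALSE)
      sw
    },
    simulate = {
      cfg <- sim_config(model, architecture = config$architecture,
                        pop_size = config$pop_size, cycles = config$cycles,
                        seed = config$seed,
                        record_every = config$record_every)
      sim <- run_simulation(cfg, replicates = config$replicates)
      utils::write.csv(sim$trajectory,
                       file.path(config$out_dir, "trajectory.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$summary,
                       file.path(config$out_dir, "simulation_summary.csv"),
                       row.names = FALSE)
      write_genomes(sim, file.path(config$out_dir, "final_genomes.tsv"))
      sim
    },
    info = {
      z <- c(config$z1, config$z2)
      stopifnot(length(z) == 2L)
      eq <- find_resident_equilibrium(z, model)
      info <- empirical_cue_information(eq)
      utils::write.csv(data.frame(q_11 = info$q_ik[1, 1],
                                  q_12 = info$q_ik[1, 2],
                                  mi_bits = info$mi),
                       file.path(config$out_dir, "info.csv"),
                       row.names = FALSE)
      info
    })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say("mode %s finished in %.2f s", config$mode, elapsed)
  manifest <- list(mode = config$mode, seed = config$seed,
                   parameters = {
                     x <- unclass(config); x$model <- NULL
                     Filter(Negate(is.null), x)
                   },
                   package_version = as.character(utils::packageVersion("gencue")),
                   r_version = R.version.string,
                   elapsed_seconds = elapsed)
  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(res)
}

# final genomes of every replicate as a tidy TSV
write_genomes <- function(sim, path) {
  rows <- list()
  for (r in seq_along(sim$final)) {
    for (h in 1:2) {
      fin <- sim$final[[r]][[h]]
      g <- t(fin$genome)
      colnames(g) <- paste0("locus", seq_len(ncol(g)))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, habitat = h, cue = fin$cue,
        liability = fin$liability, z = fin$z, g)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write deterministic miniature fixtures
#'
#' Generates a small reproducible test population (one short
#' individual-based run) and a pre-solved resident equilibrium, written as
#' plain-text TSV/CSV under `dir`. Used by the test suite and as worked
#' input for the information metrics.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(seed = 1, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mod <- cue_model(m = 0.05)
  cfg <- sim_config(mod, architecture = "A", pop_size = 200, cycles = 50,
                    seed = seed, record_every = 10)
  sim <- run_simulation(cfg)
  p_pop <- file.path(dir, "fixture_population.tsv")
  write_genomes(sim, p_pop)
  eq <- find_resident_equilibrium(c(0.0975, 0.75), mod)
  p_eq <- file.path(dir, "fixture_equilibrium.csv")
  utils::write.csv(
    data.frame(habitat = rep(1:2, 2), allele = rep(1:2, each = 2),
               n = as.vector(eq$n), p_ik = as.vector(eq$p_ik),
               q_ik = as.vector(eq$q_ik)),
    p_eq, row.names = FALSE)
  invisible(c(population = p_pop, equilibrium = p_eq))
}
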