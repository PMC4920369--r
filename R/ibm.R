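#' Modifier-locus genetic architectures
#'
#' Builds the locus table of one of the four genotype-phenotype
#' architectures used by the individual-based simulator. The phenotype is
#' always the sigmoid [liability_to_phenotype()] of `a0 + ag * x`; the
#' architectures differ in how `a0` and `ag` are genetically determined:
#'
#' * `"A"` -- `ag` encoded by a single locus (recombining with the cue
#'   locus at rate `rho`), `a0` held at a fixed value.
#' * `"B"` -- one locus each for `a0` and `ag`, both at recombination
#'   `rho` to the cue locus.
#' * `"C"` -- `a0` the difference between the summed (non-negative)
#'   expressions of 5 positive-effect and 5 negative-effect unlinked loci;
#'   `ag` the sum of 5 unlinked small-effect loci.
#' * `"D"` -- as `"C"`, plus two unlinked expression-threshold loci that
#'   cap the summed expression of the positive and negative sets:
#'   `a0 = min(S+, T+) - min(S-, T-)`.
#'
#' @param name architecture name, `"A"`, `"B"`, `"C"` or `"D"`.
#' @param rho cue-modifier recombination rate for the linked architectures
#'   (`"A"`, `"B"`); multilocus architectures are fully unlinked (0.5).
#' @param a0_fixed fixed baseline liability (architecture `"A"`) and the
#'   initial value of evolvable `a0` determinants elsewhere.
#' @param ag_init initial `ag` total.
#' @param mut_rate,mut_sd per-locus, per-gamete mutation probability and
#'   Gaussian kernel standard deviation for modifier alleles.
#' @return A list describing the loci: integer `role` codes, per-locus
#'   recombination rates `rec` to the cue locus, mutation parameters,
#'   initial allele values `init`, and the fixed baseline passed to the
#'   simulator.
#' @export
cue_architecture <- function(name = c("A", "B", "C", "D"), rho = 0,
                             a0_fixed = NULL, ag_init = 1.5,
                             mut_rate = 0.005, mut_sd = 0.2) {
  name <- match.arg(name)
  if (is.null(a0_fixed)) a0_fixed <- stats::qlogis(0.42375)
  arch <- switch(name,
    A = list(role = 0L, rec = rho, init = ag_init, fixed = a0_fixed),
    B = list(role = c(1L, 0L), rec = c(rho, rho),
             init = c(a0_fixed, ag_init), fixed = 0),
    C = list(role = c(rep(2L, 5), rep(3L, 5), rep(0L, 5)),
             rec = rep(0.5, 15),
             init = c(rep(0.25, 5), rep(0.25 - a0_fixed / 5, 5),
                      rep(ag_init / 5, 5)),
             fixed = 0),
    D = list(role = c(rep(2L, 5), rep(3L, 5), rep(0L, 5), 4L, 5L),
             rec = rep(0.5, 17),
             init = c(rep(0.25, 5), rep(0.25 - a0_fixed / 5, 5),
                      rep(ag_init / 5, 5), 2, 2),
             fixed = 0))
  nl <- length(arch$role)
  list(name = name, role = arch$role, rec = arch$rec,
       mut_rate = rep(mut_rate, nl), mut_sd = rep(mut_sd, nl),
       init = arch$init, a0_fixed = arch$fixed)
}

#' Configuration of an individual-based simulation
#'
#' Assembles and validates everything a forward-time run needs. The
#' per-habitat census sizes are `pop_size * capacity / sum(capacity)` and
#' must be divisible by the respective group sizes.
#'
#' @param model a [cue_model()]; its `rho` is the cue-modifier
#'   recombination rate of the linked architectures.
#' @param architecture an architecture name or a [cue_architecture()] list.
#' @param pop_size total census population size across both habitats.
#' @param cycles number of full life cycles to simulate.
#' @param seed mandatory integer seed.
#' @param record_every recording cadence in cycles.
#' @param cue_flip cue-locus mutation (allele flip) probability per gamete.
#' @param x allelic effect values of the two cue alleles.
#' @param final_fraction fraction of the recorded trajectory (from the
#'   end) averaged into the summary statistics.
#' @param ... passed to [cue_architecture()] when `architecture` is a name.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(model = cue_model(), architecture = "A",
                       pop_size = 4000, cycles = 5000, seed,
                       record_every = 50, cue_flip = 1e-4,
                       x = c(-1, 1), final_fraction = 0.2, ...) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer `seed` is mandatory", call. = FALSE)
  if (is.character(architecture))
    architecture <- cue_architecture(architecture, rho = model$rho, ...)
  cap <- round(pop_size * model$capacity / sum(model$capacity))
  if (any(cap %% model$N != 0))
    stop("per-habitat population sizes (", paste(cap, collapse = ", "),
         ") must be divisible by the group sizes", call. = FALSE)
  stopifnot(cycles >= 1, record_every >= 1, length(x) == 2L,
            final_fraction > 0, final_fraction <= 1)
  structure(list(model = model, architecture = architecture,
                 pop_size = pop_size, cap = as.integer(cap),
                 cycles = as.integer(cycles), seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 cue_flip = cue_flip, x = x,
                 final_fraction = final_fraction),
            class = "sim_config")
}

traj_cols <- c("cycle", "freq_x1_h1", "freq_x1_h2",
               "mean_z_h1_x1", "mean_z_h1_x2", "mean_z_h2_x1", "mean_z_h2_x2",
               "mean_z_x1", "mean_z_x2",
               "mean_a0", "sd_a0", "mean_ag", "sd_ag", "mean_z", "sd_z")

#' Initialise a population deterministically
#'
#' Cue alleles are seeded alternately (frequency exactly 0.5 in each
#' habitat) and all modifier loci start at the architecture's initial
#' allele values, so initial populations are identical across seeds.
#'
#' @param config a [sim_config()].
#' @return List with per-habitat `cue` (0/1 integer vectors) and `genome`
#'   (loci x individuals matrices).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$architecture
  lapply(1:2, function(h) {
    n <- config$cap[h]
    list(cue = rep(c(0L, 1L), length.out = n),
         genome = matrix(a$init, nrow = length(a$role), ncol = n))
  })
}

#' Advance a population by one full stochastic life cycle
#'
#' Applies a single cycle of the individual-based dynamics -- game,
#' fecundity-proportional offspring production, migration, mating with
#' recombination and mutation, founding, one asexual generation -- to a
#' population in census state. Uses R's RNG stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @param population per-habitat list as returned by [init_population()]
#'   or a previous call: elements with `cue` (0/1 integers) and `genome`
#'   (loci x individuals).
#' @param config a [sim_config()].
#' @return The next census population, same shape, plus the phenotypes
#'   and liabilities of the new census as extra elements.
#' @export
life_cycle_step <- function(population, config) {
  stopifnot(inherits(config, "sim_config"))
  mod <- config$model
  a <- config$architecture
  res <- .ibm_run(mod$N, config$cap, mod$W, mod$b, mod$c, mod$m,
                  1L, 1L, a$role, a$rec, a$mut_rate, a$mut_sd,
                  a$a0_fixed, config$cue_flip, config$x,
                  population[[1]]$cue, population[[2]]$cue,
                  population[[1]]$genome, population[[2]]$genome)
  lapply(res$final, function(h)
    list(cue = h$cue, genome = h$genome, z = h$z, liability = h$liability))
}

#' Run the forward-time individual-based simulation
#'
#' Simulates the full life cycle -- public-goods game with
#' fecundity-proportional offspring production, within- and between-habitat
#' migration, random mating with cue-modifier recombination in the
#' dispersal pool, group founding to capacity, and one asexual generation
#' -- with mutation at gamete formation. Replicate `r` uses seed
#' `seed + r - 1`; identical seeds give bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @param replicates number of independent replicate runs.
#' @return Object of class `"cue_sim"`: list with `trajectory` (long data
#'   frame over replicates; columns include per-habitat cue-allele
#'   frequencies and per-class mean phenotypes), `final` (per-replicate
#'   final populations with cue, genome, liability, `a0`, `ag` and `z`),
#'   `summary` (per-replicate final-epoch statistics, see Details) and the
#'   config.
#'
#' @details The summary averages the last `final_fraction` of recorded
#'   trajectory rows: per-cue-allele mean phenotypes (`NA` when the allele's
#'   mean frequency is below 2%), cue minor-allele frequency, mean `ag` and
#'   the mean and standard deviation of `a0`.
#' @export
run_simulation <- function(config, replicates = 1) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  mod <- config$model
  a <- config$architecture
  init <- init_population(config)
  trajs <- vector("list", replicates)
  finals <- vector("list", replicates)
  sums <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(config$seed + r - 1L)
    res <- .ibm_run(mod$N, config$cap, mod$W, mod$b, mod$c, mod$m,
                    config$cycles, config$record_every,
                    a$role, a$rec, a$mut_rate, a$mut_sd,
                    a$a0_fixed, config$cue_flip, config$x,
                    init[[1]]$cue, init[[2]]$cue,
                    init[[1]]$genome, init[[2]]$genome)
    tr <- as.data.frame(res$trajectory)
    names(tr) <- traj_cols
    tr$replicate <- r
    trajs[[r]] <- tr
    finals[[r]] <- res$final
    sums[[r]] <- summarise_run(tr, res$final, config, r)
  }
  structure(list(trajectory = do.call(rbind, trajs),
                 final = finals,
                 summary = do.call(rbind, sums),
                 config = config),
            class = "cue_sim")
}

summarise_run <- function(tr, final, config, r) {
  nrec <- nrow(tr)
  keep <- tr$cycle >= (1 - config$final_fraction) * config$cycles
  ep <- tr[keep, , drop = FALSE]
  w <- config$cap / sum(config$cap)
  f1 <- mean(ep$freq_x1_h1 * w[1] + ep$freq_x1_h2 * w[2])
  mz <- function(col, freq) if (freq < 0.02) NA_real_ else
    mean(col, na.rm = TRUE)
  data.frame(replicate = r,
             freq_x1 = f1, minor_freq = min(f1, 1 - f1),
             mean_z_x1 = mz(ep$mean_z_x1, f1),
             mean_z_x2 = mz(ep$mean_z_x2, 1 - f1),
             mean_z = mean(ep$mean_z),
             mean_ag = mean(ep$mean_ag), sd_ag = mean(ep$sd_ag),
             mean_a0 = mean(ep$mean_a0), sd_a0 = mean(ep$sd_a0))
}

#' @export
print.cue_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Individual-based run: architecture %s, %d individuals, %d cycles, %d replicate(s)\n",
              cfg$architecture$name, cfg$pop_size, cfg$cycles,
              max(x$trajectory$replicate)))
  cat(sprintf("  model m = %g, rho = %g, seed = %d\n",
              cfg$model$m[2, 1], cfg$model$rho, cfg$seed))
  cat("Final-epoch summary (averaged over the last ",
      round(100 * cfg$final_fraction), "% of records):\n", sep = "")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cue_sim <- function(x, replicate = 1, ...) {
  tr <- x$trajectory[x$trajectory$replicate == replicate, ]
  graphics::matplot(tr$cycle, tr[, c("mean_z_x1", "mean_z_x2")],
                    type = "l", lty = 1, col = c("blue", "red"),
                    xlab = "cycle", ylab = "mean phenotype",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", c("cue allele x1", "cue allele x2"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Kernel density of the phenotype distribution
#'
#' Gaussian kernel density of investment phenotypes on `[0, 1]`,
#' renormalised to integrate to one over the unit interval. Degenerate
#' samples (a single phenotype value) fall back to a minimum bandwidth.
#'
#' @param z phenotype values in `[0, 1]`, or a `"cue_sim"` (pooled final
#'   phenotypes of one replicate).
#' @param bw bandwidth; default `stats::bw.nrd0` with a floor of 0.005.
#' @param n grid size.
#' @param replicate replicate to use when `z` is a simulation.
#' @return A list with grid `x`, density `y` (integrates to 1 on
#'   `[0, 1]`) and `modes`, the number of interior local maxima.
#' @export
phenotype_distribution <- function(z, bw = NULL, n = 512, replicate = 1) {
  if (inherits(z, "cue_sim"))
    z <- unlist(lapply(z$final[[replicate]], function(h) h$z))
  stopifnot(length(z) > 0)
  if (is.null(bw)) {
    # bw.nrd0 falls back to |x| on zero-spread data; use the floor instead
    bw <- if (stats::sd(z) < 1e-12) 0.005 else
      tryCatch(stats::bw.nrd0(z), error = function(e) 0.005)
    if (!is.finite(bw) || bw < 0.005) bw <- 0.005
  }
  d <- stats::density(z, bw = bw, from = 0, to = 1, n = n)
  area <- sum(diff(d$x) * (d$y[-1] + d$y[-n]) / 2)
  y <- d$y / area
  dy <- diff(y)
  modes <- sum(dy[-length(dy)] > 0 & dy[-1] <= 0 &
                 y[2:(n - 1)] > 0.05 * max(y))
  list(x = d$x, y = y, bw = bw, modes = modes)
}

#' Detect the polymorphism-transfer signature
#'
#' Classifies the end state of a run with an evolvable `a0` against the
#' transfer outcome in which the adaptive polymorphism moves from the cue
#' locus to the `a0` determinant: (i) the `a0` values are polymorphic (a
#' 2-means split of individual `a0` with both clusters above
#' `min_cluster` weight and centres separated by more than `a0_gap`),
#' (ii) the cue-locus polymorphism has collapsed (minor allele frequency
#' below `cue_tol`), (iii) the cue-effect weight `ag` has lost its role:
#' the share of liability variance attributable to the cue locus is below
#' `cue_r2_tol`, and (iv) the phenotype distribution is multimodal.
#'
#' Check (iii) is the finite-population observable of "`ag` evolves toward
#' zero": once the cue locus fixes, only the sum `a0 + ag*x` is visible to
#' selection, so the numerical value of `ag` performs a neutral random walk
#' along that ridge and is not a meaningful end-state statistic at small
#' population sizes; what is meaningful is that the cue locus no longer
#' explains the liability variation. The decay of the mean `ag` toward
#' zero during the transfer itself is visible in the recorded trajectory.
#'
#' @param sim a `"cue_sim"`.
#' @param replicate replicate index.
#' @param a0_gap,min_cluster,cue_r2_tol,cue_tol detection thresholds.
#' @return Logical; attribute `"checks"` holds the four components.
#' @export
transfer_signature <- function(sim, replicate = 1, a0_gap = 1,
                               min_cluster = 0.15, cue_r2_tol = 0.05,
                               cue_tol = 0.1) {
  stopifnot(inherits(sim, "cue_sim"))
  fin <- sim$final[[replicate]]
  a0 <- unlist(lapply(fin, function(h) h$a0))
  liab <- unlist(lapply(fin, function(h) h$liability))
  cue <- unlist(lapply(fin, function(h) h$cue))
  a0_poly <- FALSE
  if (stats::sd(a0) > 1e-6) {
    km <- suppressWarnings(stats::kmeans(a0, centers = 2, nstart = 5))
    wts <- km$size / length(a0)
    a0_poly <- min(wts) > min_cluster &&
      abs(diff(km$centers[, 1])) > a0_gap
  }
  minor <- min(mean(cue), 1 - mean(cue))
  cue_collapsed <- minor < cue_tol
  # share of liability variance explained by the cue allele; only meaningful
  # while the locus is actually polymorphic -- at mutation-boundary
  # frequencies the few fresh mutant carriers are outliers (their liability
  # is offset by the neutrally drifted 2*ag), not population structure
  v <- stats::var(liab)
  r2 <- if (v > 0 && minor >= 0.01)
    summary(stats::lm(liab ~ factor(cue)))$r.squared else 0
  cue_irrelevant <- r2 < cue_r2_tol
  bimodal <- phenotype_distribution(unlist(lapply(fin, function(h) h$z)))$modes >= 2
  out <- a0_poly && cue_collapsed && cue_irrelevant && bimodal
  attr(out, "checks") <- c(a0_polymorphic = a0_poly,
                           cue_collapsed = cue_collapsed,
                           cue_explains_no_liability = cue_irrelevant,
                           z_bimodal = bimodal)
  out
}
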