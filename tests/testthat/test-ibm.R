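test_that("populations initialise at capacity with a balanced cue locus", {
  cfg <- sim_config(ref_model(), "A", pop_size = 400, cycles = 10, seed = 1)
  pop <- init_population(cfg)
  expect_equal(vapply(pop, function(h) length(h$cue), integer(1)), c(200L, 200L))
  expect_equal(vapply(pop, function(h) mean(h$cue), numeric(1)), c(0.5, 0.5))
  # deterministic: identical across calls
  expect_identical(pop, init_population(cfg))
  expect_error(sim_config(ref_model(), "A", pop_size = 415, cycles = 10, seed = 1),
               "divisible")
  expect_error(sim_config(ref_model(), "A", pop_size = 400, cycles = 10),
               "seed")
})

test_that("seeded runs are reproducible and conserve capacity", {
  cfg <- sim_config(ref_model(m = 0.1), "B", pop_size = 400, cycles = 60,
                    seed = 99, record_every = 10)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$final, s2$final)
  # census size invariant over the whole run
  for (h in 1:2)
    expect_length(s1$final[[1]][[h]]$cue, cfg$cap[h])
  # genome lengths fixed by the architecture
  expect_equal(nrow(s1$final[[1]][[1]]$genome),
               length(cfg$architecture$role))
})

test_that("a flat game drifts without directional allele-frequency change", {
  # equal phenotypes (ag = 0, no mutation) make all payoffs identical, so the
  # cue locus evolves by pure drift: replicate-averaged change is ~ 0
  mod <- ref_model(m = 0.05)
  cfg <- sim_config(mod, cue_architecture("A", ag_init = 0, mut_rate = 0),
                    pop_size = 200, cycles = 20, seed = 500,
                    cue_flip = 0, record_every = 20)
  sims <- run_simulation(cfg, replicates = 200)
  dp <- sims$summary$freq_x1 - 0.5
  se <- sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp)), 2 * se + 1e-12)
})

test_that("a stochastic cycle matches the deterministic class dynamics", {
  # large population, fixed phenotypes: the realised cue-allele frequency
  # change over a cycle agrees with resident_step to within sampling error.
  # The first cycle is burn-in: the deterministic class payoffs presuppose
  # the census group structure created by random founding plus asexual
  # copying, which the deterministic initial population does not yet have.
  mod <- ref_model(m = 0.1)
  ag <- 1.2; a0 <- -0.3
  z <- liability_to_phenotype(a0, ag, c(-1, 1))
  cfg <- sim_config(mod, cue_architecture("A", ag_init = ag, a0_fixed = a0,
                                          mut_rate = 0),
                    pop_size = 40000, cycles = 2, seed = 7, cue_flip = 0,
                    record_every = 1)
  sim <- run_simulation(cfg)
  tr <- sim$trajectory
  p1 <- unlist(tr[tr$cycle == 1, c("freq_x1_h1", "freq_x1_h2")])
  p2 <- unlist(tr[tr$cycle == 2, c("freq_x1_h1", "freq_x1_h2")])
  det <- resident_step(cbind(p1, 1 - p1) * mod$capacity, z, mod)
  p_det <- det$n[, 1] / mod$capacity
  se <- sqrt(0.5 * 0.5 / cfg$cap)          # generous binomial scale
  expect_lt(max(abs(p2 - p_det)), 5 * max(se))
})

test_that("full linkage without mutation preserves cue-modifier haplotypes", {
  # architecture A at rho = 0: the ag allele carried with each cue allele can
  # never change, so per-cue-allele phenotypes stay exactly at their initial
  # values even as frequencies drift
  mod <- ref_model(m = 0.05, rho = 0)
  cfg <- sim_config(mod, cue_architecture("A", rho = 0, ag_init = 1,
                                          mut_rate = 0),
                    pop_size = 400, cycles = 40, seed = 123, cue_flip = 0,
                    record_every = 10)
  sim <- run_simulation(cfg)
  z_expect <- liability_to_phenotype(stats::qlogis(0.42375), 1, c(-1, 1))
  tr <- sim$trajectory
  expect_lt(max(abs(tr$mean_z_x1 - z_expect[1]), na.rm = TRUE), 1e-12)
  expect_lt(max(abs(tr$mean_z_x2 - z_expect[2]), na.rm = TRUE), 1e-12)
})

test_that("single life-cycle steps compose into a run", {
  cfg <- sim_config(ref_model(m = 0.1), "A", pop_size = 200, cycles = 3,
                    seed = 55, record_every = 1)
  pop <- init_population(cfg)
  set.seed(cfg$seed)
  for (i in 1:3) pop <- life_cycle_step(pop, cfg)
  # capacity conserved and phenotypes in range
  expect_equal(vapply(pop, function(h) length(h$cue), integer(1)), cfg$cap)
  expect_true(all(unlist(lapply(pop, function(h) h$z)) > 0))
  expect_true(all(unlist(lapply(pop, function(h) h$z)) < 1))
  # stepping three times with the same RNG stream reproduces a 3-cycle run
  sim <- run_simulation(cfg)
  expect_equal(pop[[1]]$cue, sim$final[[1]][[1]]$cue)
  expect_equal(pop[[2]]$genome, sim$final[[1]][[2]]$genome)
})

test_that("phenotype densities integrate to one and flag multimodality", {
  set.seed(77)
  d1 <- phenotype_distribution(runif(500))
  expect_equal(sum(diff(d1$x) * (d1$y[-1] + d1$y[-length(d1$y)]) / 2), 1,
               tolerance = 1e-6)
  d2 <- phenotype_distribution(c(rnorm(400, 0.2, 0.03), rnorm(400, 0.75, 0.03)))
  expect_gte(d2$modes, 2)
  # degenerate single-value population falls back to the minimum bandwidth
  d3 <- phenotype_distribution(rep(0.4, 100))
  expect_equal(d3$bw, 0.005)
  expect_equal(d3$modes, 1)
})

test_that("architectures expose the documented locus structure", {
  a <- cue_architecture("A", rho = 0.3)
  expect_equal(a$role, 0L)
  expect_equal(a$rec, 0.3)
  b <- cue_architecture("B", rho = 0.1)
  expect_equal(b$role, c(1L, 0L))
  cc <- cue_architecture("C")
  expect_equal(table(factor(cc$role, levels = 0:5)),
               table(factor(c(rep(2, 5), rep(3, 5), rep(0, 5)), levels = 0:5)))
  expect_true(all(cc$rec == 0.5))
  d <- cue_architecture("D")
  expect_setequal(unique(d$role), c(0L, 2L, 3L, 4L, 5L))
  # thresholded a0: initial thresholds are non-binding, so initial a0 equals
  # the plain additive sum
  cfgC <- sim_config(ref_model(), "C", pop_size = 80, cycles = 1, seed = 2)
  cfgD <- sim_config(ref_model(), "D", pop_size = 80, cycles = 1, seed = 2)
  sC <- run_simulation(cfgC); sD <- run_simulation(cfgD)
  expect_equal(sC$final[[1]][[1]]$a0[1], sD$final[[1]][[1]]$a0[1] )
})
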