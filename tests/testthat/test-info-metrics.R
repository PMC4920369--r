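test_that("mutual information of the cue-habitat table", {
  # independent counts carry no information
  expect_equal(empirical_cue_information(outer(c(30, 70), c(40, 60)))$mi, 0)
  # perfect association at equal habitat sizes is exactly one bit
  expect_equal(empirical_cue_information(diag(c(500, 500)))$mi, 1)
  # worked example: q11 = 0.9, MI ~ 0.531 bits
  info <- empirical_cue_information(matrix(c(900, 100, 100, 900), 2))
  expect_equal(info$q_ik[1, 1], 0.9)
  expect_equal(info$mi, 0.531004, tolerance = 1e-6)
  # bounds: 0 <= MI <= min of the marginal entropies
  set.seed(431)
  for (rep in 1:10) {
    n <- matrix(rpois(4, 200) + 1, 2)
    s <- empirical_cue_information(n)
    expect_gte(s$mi, -1e-12)
    expect_lte(s$mi, min(s$H_habitat, s$H_cue) + 1e-12)
    expect_lte(s$mi, 1)
  }
})

test_that("analytic conditional probabilities match a large stochastic census", {
  mod <- ref_model(m = 0.05)
  z <- c(0.0975, 0.75)
  eq <- find_resident_equilibrium(z, mod)
  a0 <- (stats::qlogis(z[1]) + stats::qlogis(z[2])) / 2
  ag <- (stats::qlogis(z[2]) - stats::qlogis(z[1])) / 2
  cfg <- sim_config(mod, cue_architecture("A", ag_init = ag, a0_fixed = a0,
                                          mut_rate = 0),
                    pop_size = 20000, cycles = 150, seed = 13, cue_flip = 0,
                    record_every = 150)
  sim <- run_simulation(cfg)
  emp <- empirical_cue_information(sim)
  counts <- emp$counts
  se <- sqrt(0.25 / colSums(counts))
  expect_lt(max(abs(emp$q_ik - eq$q_ik)), 6 * max(se))
})

test_that("logistic regression of habitat on liability recovers known laws", {
  set.seed(432)
  # null data: no association, slope within 2 SE of zero
  liab <- rnorm(2000)
  hab <- sample(1:2, 2000, replace = TRUE)
  fit0 <- habitat_logistic_regression(liab, hab)
  expect_false(fit0$separated)
  expect_lt(abs(fit0$slope), 2 * fit0$se[2])
  # parameter recovery from a known logistic law
  liab <- rnorm(10000)
  p <- stats::plogis(-1 + 2 * liab)
  hab <- ifelse(runif(10000) < p, 1L, 2L)
  fit <- habitat_logistic_regression(liab, hab)
  expect_lt(abs(fit$intercept - (-1)), 3 * fit$se[1])
  expect_lt(abs(fit$slope - 2), 3 * fit$se[2])
  # symmetric two-point liabilities put probability one half at the midpoint
  liab2 <- rep(c(-1, 1), each = 500)
  hab2 <- rep(rep(1:2, each = 250), 2)
  fit2 <- habitat_logistic_regression(liab2, hab2)
  expect_equal(stats::plogis(fit2$intercept), 0.5, tolerance = 1e-6)
  expect_error(habitat_logistic_regression(liab2, rep(1, 1000)), "both")
})

test_that("complete separation is detected and capped", {
  liab <- c(rnorm(200, -3, 0.3), rnorm(200, 3, 0.3))
  hab <- rep(2:1, each = 200)
  expect_warning(fit <- habitat_logistic_regression(liab, hab), "separation")
  expect_true(fit$separated)
  expect_equal(abs(fit$slope), 50)
  # predicted curve still respects the direction of the data
  expect_gt(fit$slope, 0)
})

test_that("runs are ranked by the information in their genotypes", {
  set.seed(433)
  mod <- ref_model(m = 0.05)
  mk <- function(ag) {
    cfg <- sim_config(mod, cue_architecture("A", ag_init = ag, mut_rate = 0),
                      pop_size = 400, cycles = 30, seed = 5, cue_flip = 0,
                      record_every = 30)
    run_simulation(cfg, replicates = 3)
  }
  informative <- mk(2)     # strongly divergent phenotypes track habitat
  flat <- mk(0)            # no divergence: liability carries no information
  ord <- information_ordering(list(divergent = informative, flat = flat))
  expect_equal(ord$run[1], "divergent")
  expect_gt(ord$mi_mean[1], ord$mi_mean[2])
  expect_true(all(ord$mi_mean <= 1))
  # duplicate runs tie within replicate noise
  ord2 <- information_ordering(list(a = informative, b = informative))
  expect_equal(ord2$mi_mean[1], ord2$mi_mean[2])
})
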