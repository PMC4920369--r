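test_that("relatedness is the reciprocal of the founder number", {
  expect_identical(relatedness(1), 1)
  expect_equal(relatedness(20), 0.05)
  expect_equal(relatedness(2), 0.5)
  expect_error(relatedness(0))
  expect_error(relatedness(2.5))
  expect_error(relatedness(-3))
})

test_that("payoff follows the public-goods form and clamps as a fecundity", {
  mod <- ref_model()
  expect_equal(payoff(0, 0, 1, mod), 0.5)
  expect_equal(payoff(0.75, 0.75, 1, mod), 0.5 + 3 * 0.75 - 1.5 * 0.75^2)
  expect_equal(payoff(0.75, 0.75, 1, mod), 1.90625)
  expect_equal(payoff(1, 0, 1, mod), -1)          # raw payoff can be negative
  expect_equal(fecundity(payoff(1, 0, 1, mod)), 0)
  expect_warning(fecundity(-1, warn = TRUE), "clamped")
  expect_error(payoff(0.5, 0.5, 3, mod))
})

test_that("expected mutant payoff: closed-form examples", {
  mod <- ref_model()
  # neutral mutant in a monomorphic population recovers the monomorphic payoff
  for (z in c(0.2, 0.5, 0.9)) {
    expect_equal(expected_mutant_payoff(z, z, 1, mod), payoff(z, z, 1, mod))
    expect_equal(expected_mutant_payoff(z, z, 2, mod), payoff(z, z, 2, mod))
  }
  # hand evaluation at N = 2: W + (b/2)*(1.5 z' + 0.5 ztilde) - c z'^2
  expect_equal(expected_mutant_payoff(0, 0.75, 2, mod), 1.0625)
})

test_that("resident class payoff: coefficients sum to one and match examples", {
  mod <- ref_model()
  # monomorphic population: class payoff reduces to the plain payoff
  for (h in 1:2)
    expect_equal(resident_class_payoff(1, c(0.6, 0.6), 0.5, h, mod),
                 payoff(0.6, 0.6, h, mod))
  # hand evaluation, N = 2, z_k = 0.75, ztilde = 0.5
  expect_equal(resident_class_payoff(1, c(0.75, 0.25), 0.5, 2, mod), 1.71875)
  # coefficient identity: (2N-1)/N^2 + (N-1)^2/N^2 = 1 exactly
  for (N in 1:8) {
    sw <- (2 * N - 1) / N
    expect_identical(sw / N + (N - sw) / N, 1)
  }
})

test_that("closed forms equal the enumeration oracle for N in 1..6", {
  set.seed(401)
  for (N in 1:6) {
    for (rep in 1:3) {
      mod <- random_small_model(N)
      z <- sort(runif(2))
      p1 <- runif(1, 0.1, 0.9)
      zp <- runif(1)
      ztil <- p1 * z[1] + (1 - p1) * z[2]
      for (h in 1:2) {
        expect_equal(expected_mutant_payoff(zp, ztil, h, mod),
                     enumerate_mutant_payoff(zp, z, p1, h, mod),
                     tolerance = 1e-12)
        for (k in 1:2)
          expect_equal(resident_class_payoff(k, z, p1, h, mod),
                       enumerate_class_payoff(k, z, p1, h, mod),
                       tolerance = 1e-12)
      }
    }
  }
  expect_error(enumerate_mutant_payoff(0.5, c(0.2, 0.8), 0.5, 1, ref_model()),
               "N <= 8")
})

test_that("size-biased mutant copy number equals 1 + (N-1) r", {
  # E[K^2]/E[K] for K ~ Binomial(N, 1/N): the self-weight of the focal mutant
  for (N in c(2, 5, 20)) {
    k <- 0:N
    pk <- dbinom(k, N, 1 / N)
    expect_equal(sum(k^2 * pk) / sum(k * pk), 1 + (N - 1) / N)
  }
  expect_equal(1 + (20 - 1) * relatedness(20), 1.95)
})

test_that("payoff derivative matches its closed form and the numerical slope", {
  mod <- ref_model()
  expect_equal(payoff_derivative(0.75, 2, mod), 0)     # z* = 0.75 at N = 2
  expect_equal(payoff_derivative(0, 1, mod), 0.2925)   # (3/20)(1 + 19 * 0.05)
  expect_equal(payoff_derivative(0.0975, 1, mod), 0)   # z* = 0.0975 at N = 20
  # central differences of the expected mutant payoff in z'
  set.seed(402)
  h <- 1e-5
  for (rep in 1:5) {
    mod2 <- random_small_model(sample(2:6, 1))
    zk <- runif(1); ztil <- runif(1)
    for (hab in 1:2) {
      num <- (expected_mutant_payoff(zk + h, ztil, hab, mod2) -
                expected_mutant_payoff(zk - h, ztil, hab, mod2)) / (2 * h)
      expect_equal(num, payoff_derivative(zk, hab, mod2), tolerance = 1e-8)
    }
  }
})

test_that("liability map is the logistic with saturating asymptotes", {
  expect_equal(liability_to_phenotype(0, 5, 0), 0.5)
  expect_equal(liability_to_phenotype(2, 0, 0.3), 1 / (1 + exp(-2)))
  expect_equal(liability_to_phenotype(2, 0, 0.3), 0.88079708, tolerance = 1e-8)
  expect_equal(liability_to_phenotype(1e4), 1)
  expect_equal(liability_to_phenotype(-1e4), 0)
  # strict monotonicity in the liability
  a <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(liability_to_phenotype(a)) > 0))
  expect_true(all(diff(liability_to_phenotype(0, a, 1)) > 0))
})

test_that("model constructor validates its invariants", {
  expect_error(cue_model(N = c(0, 2)), "N")
  expect_error(cue_model(b = c(-1, 3)), "b")
  expect_error(cue_model(c = c(0, 1.5)), "c")
  expect_error(cue_model(rho = 0.7), "rho")
  expect_error(cue_model(m = 0.8), "migration")
  expect_error(cue_model(m = matrix(c(0.9, 0.2, 0.1, 0.8), 2)), "sum")
  mod <- cue_model(m = matrix(c(0.9, 0.1, 0.2, 0.8), 2))
  expect_equal(mod$m[2, 1], 0.1)
  expect_equal(ref_model()$r, c(0.05, 0.5))
})
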