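test_that("cue inheritance mixes faithful transmission with the pool", {
  pool <- matrix(c(0.8, 0.3, 0.2, 0.7), 2)
  h0 <- cue_inheritance(0, pool)
  for (j in 1:2) expect_equal(h0[j, , ], diag(2))      # full linkage
  h <- cue_inheritance(0.5, pool)
  expect_equal(h[1, 1, 1], 0.9)                        # 0.5 + 0.5 * 0.8
  expect_equal(h[1, 2, 1], 0.1)
  for (j in 1:2) for (k in 1:2)
    expect_equal(sum(h[j, , k]), 1)
  expect_error(cue_inheritance(0.2, matrix(c(0.5, 0.5, 0.2, 0.2), 2)),
               "normalised")
})

test_that("the resident is neutral: leading eigenvalue 1 at every equilibrium", {
  set.seed(421)
  for (rep in 1:8) {
    case <- random_protected_case()
    A <- mutant_projection_matrix(case$z, case$eq)
    lam <- max(Re(eigen(A, only.values = TRUE)$values))
    expect_equal(lam, 1, tolerance = 1e-8)
    expect_true(all(A >= 0))
    # right eigenvector of the resident matrix is the class structure
    expect_equal(as.vector(A %*% as.vector(t(case$eq$n))),
                 as.vector(t(case$eq$n)), tolerance = 1e-8)
  }
})

test_that("full linkage decouples the cue-allele lineages", {
  mod <- ref_model(m = 0.05, rho = 0)
  eq <- find_resident_equilibrium(c(0.1, 0.72), mod)
  A <- mutant_projection_matrix(c(0.15, 0.6), eq, rho = 0)
  # off-allele blocks vanish: no transitions between lineages
  idx1 <- c(1, 3); idx2 <- c(2, 4)
  expect_true(all(A[idx1, idx2] == 0))
  expect_true(all(A[idx2, idx1] == 0))
  # per-allele invasion fitness equals the 2x2 habitat sub-matrix fitness
  lamA <- max(Re(eigen(A, only.values = TRUE)$values))
  lam_blocks <- sapply(list(idx1, idx2), function(ii)
    max(Re(eigen(A[ii, ii], only.values = TRUE)$values)))
  expect_equal(lamA, max(lam_blocks), tolerance = 1e-12)
})

test_that("no dispersal and full linkage factorise into scalars", {
  mod <- cue_model(m = 0, rho = 0)
  eq <- find_resident_equilibrium(c(0.0975, 0.75), mod, p0 = c(0.999, 0.001))
  zp <- c(0.2, 0.6)
  A <- mutant_projection_matrix(zp, eq, rho = 0)
  offdiag <- A[row(A) != col(A)]
  expect_true(all(offdiag == 0))
  # diagonal entries are phi_i * expected mutant payoff
  ztil <- eq$p_ik[, 1] * eq$z[1] + eq$p_ik[, 2] * eq$z[2]
  for (i in 1:2) for (k in 1:2)
    expect_equal(A[(i - 1) * 2 + k, (i - 1) * 2 + k],
                 eq$phi[i] * expected_mutant_payoff(zp[k], ztil[i], i, mod))
})

test_that("invasion fitness is zero for the resident and symmetric under relabeling", {
  mod <- ref_model(m = 0.06, rho = 0.3)
  z <- c(0.12, 0.7)
  inv <- invasion_fitness(z, z, mod)
  expect_equal(inv$F, 0, tolerance = 1e-8)
  # swapping habitat labels and allele labels together leaves F unchanged
  mod_swap <- cue_model(N = rev(mod$N), m = 0.06, rho = 0.3)
  zp <- c(0.2, 0.55)
  F1 <- invasion_fitness(zp, z, mod)$F
  F2 <- invasion_fitness(rev(zp), rev(z), mod_swap)$F
  expect_equal(F1, F2, tolerance = 1e-8)
})

test_that("reproductive values are normalised and weight the gradient correctly", {
  set.seed(422)
  case <- random_protected_case()
  rv <- reproductive_values(case$eq)
  expect_equal(sum(rv$v * rv$u), 1, tolerance = 1e-10)
  # symmetric model with equal phenotypes: all reproductive values equal
  mods <- cue_model(N = c(4, 4), m = 0.1, rho = 0.3)
  eqs <- find_resident_equilibrium(c(0.5, 0.5), mods, p0 = c(0.6, 0.4))
  rvs <- reproductive_values(eqs)
  expect_equal(max(rvs$v) - min(rvs$v), 0, tolerance = 1e-8)
})

test_that("the selection gradient equals the eigenvalue sensitivity", {
  set.seed(423)
  h <- 1e-5
  for (rep in 1:6) {
    case <- random_protected_case()
    g <- selection_gradient(eq = case$eq)
    fd <- vapply(1:2, function(k) {
      zp <- case$z; zm <- case$z
      zp[k] <- zp[k] + h; zm[k] <- zm[k] - h
      (invasion_fitness(zp, eq = case$eq)$F -
         invasion_fitness(zm, eq = case$eq)$F) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("at full linkage the gradient matches the per-block sensitivity", {
  mod <- ref_model(m = 0.05, rho = 0)
  eq <- find_resident_equilibrium(c(0.1, 0.72), mod)
  g <- selection_gradient(eq = eq, rho = 0)
  h <- 1e-5
  for (k in 1:2) {
    blk <- function(zk) {
      ztil <- eq$p_ik[, 1] * eq$z[1] + eq$p_ik[, 2] * eq$z[2]
      wm <- vapply(1:2, function(i)
        fecundity(expected_mutant_payoff(zk, ztil[i], i, mod)), numeric(1))
      B <- outer(eq$phi, wm) * mod$m
      log(max(Re(eigen(B, only.values = TRUE)$values)))
    }
    fd <- (blk(eq$z[k] + h) - blk(eq$z[k] - h)) / (2 * h)
    # block fitness sensitivity carries the dilution factor p_k in Eq-7 form
    expect_equal(g[k], eq$p_k[k] * fd, tolerance = 1e-6)
  }
})

test_that("gradient components vanish where the payoff derivatives do", {
  # with m -> 0 the gradient at the pair of habitat optima is ~ 0
  mod <- ref_model(m = 0.001, rho = 0.2)
  g <- selection_gradient(c(0.0975, 0.75), mod)
  # the residual gradient is of the order of the migration coupling
  expect_lt(max(abs(g)), 5e-3)
})
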