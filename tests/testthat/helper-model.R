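# reference parameter set used throughout the suite: two habitats differing
# only in group size (N1 = 20, N2 = 2), shared game parameters
ref_model <- function(m = 0.05, rho = 0, ...) {
  cue_model(m = m, rho = rho, ...)
}

# random model with both group sizes equal to N (for enumeration oracles)
random_small_model <- function(N) {
  cue_model(N = rep(N, 2),
            W = runif(2, 0.2, 1),
            b = runif(2, 0.5, 4),
            c = runif(2, 0.5, 3),
            m = runif(1, 0.01, 0.3))
}

# draw a protected dimorphism with an interior resident equilibrium,
# under a model with random migration/recombination
random_protected_case <- function() {
  repeat {
    m <- runif(1, 0.02, 0.12)
    rho <- runif(1, 0.05, 0.5)
    mod <- ref_model(m = m, rho = rho)
    z <- c(runif(1, 0.05, 0.35), runif(1, 0.55, 0.9))
    if (!isTRUE(coexistence_test(z[1], z[2], mod))) next
    eq <- find_resident_equilibrium(z, mod)
    if (eq$monomorphic || !eq$converged) next
    if (any(eq$p_k < 0.05) || any(eq$p_k > 0.95)) next
    return(list(model = mod, z = z, eq = eq))
  }
}
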