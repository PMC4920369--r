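#' Brute-force expected rare-mutant payoff
#'
#' Exact expectation of the mutant payoff by full enumeration, used as the
#' independent oracle for the closed form in [expected_mutant_payoff()].
#' A mutant group is founded by one mutant and `N - 1` residents drawn
#' i.i.d. from the habitat pool (allele 1 with probability `p1`); each of
#' the `N` offspring copies a uniformly chosen founder; the focal mutant is
#' a random mutant individual, i.e. groups are weighted by their mutant
#' offspring count (size-biased sampling, normalised by `E[K] = 1`).
#'
#' Enumeration is over the resident founder composition and the multinomial
#' offspring counts, so cost grows quickly with `N`; it is capped at
#' `N <= 8`.
#'
#' @inheritParams resident_class_payoff
#' @param zprime mutant investment.
#' @return Exact expected mutant payoff.
#' @export
enumerate_mutant_payoff <- function(zprime, z, p1, habitat, model) {
  check_habitat(habitat)
  N <- model$N[habitat]
  if (N > 8) stop("enumeration oracle limited to N <= 8", call. = FALSE)
  W <- model$W[habitat]; b <- model$b[habitat]; cc <- model$c[habitat]
  total <- 0
  for (j in 0:(N - 1)) {                     # type-1 residents among founders
    pj <- stats::dbinom(j, N - 1, p1)
    if (pj == 0) next
    probs <- c(1, j, N - 1 - j) / N          # founder copy probabilities
    for (K in 0:N) for (A1 in 0:(N - K)) {   # offspring counts (K, A1, A2)
      A2 <- N - K - A1
      pm <- stats::dmultinom(c(K, A1, A2), prob = probs)
      if (pm == 0 || K == 0) next
      zbar <- (K * zprime + A1 * z[1] + A2 * z[2]) / N
      total <- total + pj * pm * K * (W + b * zbar - cc * zprime^2)
    }
  }
  total                                      # E[K] = 1, so no renormalisation
}

#' Brute-force expected resident class payoff
#'
#' Exact expectation of the payoff to a random resident carrying cue allele
#' `k`, by enumeration over founder compositions (all `N` founders i.i.d.
#' from the pool) and multinomial offspring counts, with the focal class
#' size-biased by its offspring count and normalised by `E[O_k] = N p_k`.
#' Oracle for [resident_class_payoff()]; capped at `N <= 8`.
#'
#' @inheritParams resident_class_payoff
#' @return Exact expected class payoff.
#' @export
enumerate_class_payoff <- function(k, z, p1, habitat, model) {
  check_habitat(habitat)
  stopifnot(k %in% 1:2)
  N <- model$N[habitat]
  if (N > 8) stop("enumeration oracle limited to N <= 8", call. = FALSE)
  W <- model$W[habitat]; b <- model$b[habitat]; cc <- model$c[habitat]
  pk <- if (k == 1) p1 else 1 - p1
  if (pk == 0) stop("focal allele absent from the pool", call. = FALSE)
  total <- 0
  for (f1 in 0:N) {                          # type-1 founders
    pf <- stats::dbinom(f1, N, p1)
    if (pf == 0) next
    for (o1 in 0:N) {                        # type-1 offspring
      po <- stats::dbinom(o1, N, f1 / N)
      if (po == 0) next
      ok <- if (k == 1) o1 else N - o1
      if (ok == 0) next
      zbar <- (o1 * z[1] + (N - o1) * z[2]) / N
      total <- total + pf * po * ok * (W + b * zbar - cc * z[k]^2)
    }
  }
  total / (N * pk)
}
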