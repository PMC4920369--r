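#' Pairwise relatedness among offspring group members
#'
#' Probability that two members of an offspring group are identical by
#' descent since the founding of the group. Under the founding model --
#' `N` founders, each of the `N` offspring a copy of a uniformly chosen
#' founder -- two offspring share a founder with probability `1/N`.
#'
#' @param N integer (vectorised) number of founders per group, `>= 1`.
#' @return `1/N`.
#' @examples
#' relatedness(c(20, 2))
#' @seealso [simulate_founding_ibd()] for a Monte-Carlo check.
#' @export
relatedness <- function(N) {
  if (any(!is.finite(N)) || any(N < 1) || any(N != round(N)))
    stop("`N` must be positive integers", call. = FALSE)
  1 / N
}

#' Monte-Carlo estimate of identity by descent since founding
#'
#' Simulates the group-formation process (`N` founders, `N` offspring each
#' copying a uniformly chosen founder) and estimates the probability that two
#' distinct random offspring group members descend from the same founder.
#' Serves as an independent check of [relatedness()].
#'
#' @param N founders per group.
#' @param groups number of simulated groups.
#' @return A list with the estimate `r_hat`, its standard error `se` and the
#'   number of groups.
#' @examples
#' set.seed(1)
#' simulate_founding_ibd(2, groups = 1e4)
#' @export
simulate_founding_ibd <- function(N, groups = 1e5) {
  stopifnot(N >= 1, N == round(N), groups >= 1)
  # founder labels of two distinct offspring drawn per group; offspring pick
  # founders independently and uniformly, so a pair is IBD iff labels match
  f1 <- sample.int(N, groups, replace = TRUE)
  f2 <- sample.int(N, groups, replace = TRUE)
  ibd <- f1 == f2
  p <- mean(ibd)
  list(r_hat = p, se = sqrt(p * (1 - p) / groups), groups = groups)
}

#' Public-goods payoff
#'
#' Payoff `W_i + b_i*zbar - c_i*z^2` to an individual investing `z` in a
#' group with mean investment `zbar` in habitat `habitat`. The raw value can
#' be negative for extreme `(z, zbar)`; users of the payoff as a fecundity
#' clamp it at zero (see [fecundity()]).
#'
#' @param z individual investment in `[0, 1]` (vectorised).
#' @param zbar group mean investment in `[0, 1]`.
#' @param habitat habitat index, 1 or 2.
#' @param model a [cue_model()].
#' @return Numeric payoff (possibly negative).
#' @export
payoff <- function(z, zbar, habitat, model) {
  check_habitat(habitat)
  model$W[habitat] + model$b[habitat] * zbar - model$c[habitat] * z^2
}

#' Payoff clamped at zero for use as a fecundity
#'
#' Offspring production cannot be negative, so everywhere a payoff enters the
#' life cycle as a fecundity it is truncated at zero. A warning is emitted
#' when clamping is active, since the reference equilibria sit in
#' positive-payoff regions and active clamping usually signals extreme
#' phenotype pairs.
#'
#' @param w raw payoff values.
#' @param warn emit a warning when any value is clamped?
#' @return `pmax(w, 0)`.
#' @export
fecundity <- function(w, warn = FALSE) {
  if (warn && any(w < 0))
    warning("negative payoff clamped to zero fecundity", call. = FALSE)
  pmax(w, 0)
}

#' Expected payoff of a randomly chosen rare mutant
#'
#' A rare mutant modifier lineage founds groups with exactly one mutant
#' founder among `N_i` founders. Each of the `N_i` offspring copies a
#' uniformly chosen founder, so the number of mutant offspring `K` is
#' binomial(`N_i`, `1/N_i`), and a randomly chosen mutant individual sits in
#' a group size-biased by `K`. Because the benefit is linear in the group
#' mean, the expectation has the closed form
#' \deqn{W + (b/N)\left[\frac{2N-1}{N} z' +
#'       \left(N - \frac{2N-1}{N}\right)\tilde z\right] - c z'^2,}
#' where `ztilde` is the mean resident phenotype in the habitat. The
#' self-weight `(2N-1)/N` is `E[K^2]/E[K] / N * N = 1 + (N-1)/N`, i.e.
#' `1 + (N-1) r` of the payoff derivative.
#'
#' @param zprime mutant investment in `[0, 1]`.
#' @param ztilde mean resident phenotype `p_i1*z1 + p_i2*z2` in the habitat.
#' @param habitat habitat index.
#' @param model a [cue_model()].
#' @return Expected mutant payoff (raw, unclamped).
#' @seealso [enumerate_mutant_payoff()] for the brute-force oracle.
#' @export
expected_mutant_payoff <- function(zprime, ztilde, habitat, model) {
  check_habitat(habitat)
  N <- model$N[habitat]
  sw <- (2 * N - 1) / N                       # size-biased self weight
  model$W[habitat] +
    (model$b[habitat] / N) * (sw * zprime + (N - sw) * ztilde) -
    model$c[habitat] * zprime^2
}

#' Expected payoff of a random resident of a given cue class
#'
#' Expected payoff of a randomly chosen resident individual carrying cue
#' allele `k` (phenotype `z[k]`) in habitat `habitat`, averaging over group
#' compositions with founders drawn i.i.d. from the habitat's pool. The same
#' size-biasing logic as in [expected_mutant_payoff()] applies to the focal
#' individual's own type, and in fact the two closed forms coincide when the
#' mutant expresses the resident phenotype:
#' `W + b*((2N-1)/N^2 * z_k + (N-1)^2/N^2 * ztilde) - c*z_k^2`.
#'
#' @param k cue-allele index (1 or 2).
#' @param z length-2 vector of resident phenotypes `(z1, z2)`.
#' @param p1 resident frequency of allele 1 in the habitat.
#' @param habitat habitat index.
#' @param model a [cue_model()].
#' @return Expected class payoff (raw, unclamped).
#' @export
resident_class_payoff <- function(k, z, p1, habitat, model) {
  stopifnot(k %in% 1:2, p1 >= 0, p1 <= 1)
  ztilde <- p1 * z[1] + (1 - p1) * z[2]
  expected_mutant_payoff(z[k], ztilde, habitat, model)
}

#' Derivative of the expected mutant payoff
#'
#' The payoff derivative `d_ik` evaluated at the resident phenotype:
#' `(b_i/N_i) * (1 + (N_i - 1) * r_i) - 2 * c_i * z_k` with `r_i = 1/N_i`.
#' This is the per-habitat ingredient of the selection gradient.
#'
#' @param zk resident phenotype at which to evaluate.
#' @param habitat habitat index.
#' @param model a [cue_model()].
#' @return The derivative `d_ik`.
#' @export
payoff_derivative <- function(zk, habitat, model) {
  check_habitat(habitat)
  N <- model$N[habitat]
  (model$b[habitat] / N) * (1 + (N - 1) / N) - 2 * model$c[habitat] * zk
}

#' Sigmoid liability-to-phenotype map
#'
#' Maps the liability `a0 + ag*x` of a genotype to an investment phenotype
#' through the logistic function `1/(1 + exp(-a0 - ag*x))`. `x` is the
#' allelic effect of the cue allele carried (by convention `-1` for allele 1
#' and `+1` for allele 2) and `a0`, `ag` are determined by modifier loci.
#' The result is strictly inside `(0, 1)` for finite liabilities and is
#' monotone increasing in the liability; overflow saturates cleanly at the
#' asymptotes.
#'
#' @param a0 baseline liability.
#' @param ag cue-effect weight.
#' @param x allelic effect value of the cue allele.
#' @return Investment phenotype in `(0, 1)`.
#' @examples
#' liability_to_phenotype(0, 1.5, c(-1, 1))
#' @export
liability_to_phenotype <- function(a0, ag = 0, x = 0) {
  stats::plogis(a0 + ag * x)
}

check_habitat <- function(habitat) {
  if (!all(habitat %in% 1:2))
    stop("habitat index must be 1 or 2", call. = FALSE)
  invisible(TRUE)
}
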