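#' One life-cycle step of the deterministic resident dynamics
#'
#' Advances the large-population resident dynamics over the four classes
#' (habitat `i`, cue allele `k`) by one full life cycle: expected class
#' fecundity from [resident_class_payoff()] (clamped at zero), migration
#' mixing of offspring into per-habitat dispersal pools, random mating
#' (which leaves resident cue-allele frequencies unchanged because residents
#' carry no modifier variation), founding that regulates each habitat back
#' to its capacity, and one asexual generation (which preserves expected
#' class frequencies). The census point is after group formation, just
#' before the game.
#'
#' @param n 2x2 matrix of class abundances, `n[i, k]` = number of
#'   individuals in habitat `i` carrying cue allele `k`. Habitat totals must
#'   equal the model capacities.
#' @param z length-2 vector of resident phenotypes `(z1, z2)` induced by the
#'   two cue alleles.
#' @param model a [cue_model()].
#' @return A list: `n` (next census abundances, habitats again at capacity),
#'   `phi` (founding probability per habitat dispersal pool),
#'   `pool_freq` (2x2 post-migration pool composition, rows habitats) and
#'   `w` (2x2 clamped class fecundities).
#' @export
resident_step <- function(n, z, model) {
  stopifnot(is.matrix(n), all(dim(n) == 2L), all(n >= 0))
  cap <- model$capacity
  if (any(abs(rowSums(n) - cap) > 1e-8 * max(cap)))
    stop("habitat totals must equal the configured capacities", call. = FALSE)
  p1 <- n[, 1] / cap
  w <- sapply(1:2, function(k)
    sapply(1:2, function(i) resident_class_payoff(k, z, p1[i], i, model)))
  w <- fecundity(w)                                   # 2x2, [i, k]
  pool <- model$m %*% (n * w)                         # pool[j, k]
  pool_tot <- rowSums(pool)
  if (any(pool_tot <= 0))
    stop("dispersal pool extinct in habitat ", which(pool_tot <= 0)[1],
         call. = FALSE)
  pool_freq <- pool / pool_tot
  list(n = cap * pool_freq, phi = cap / pool_tot, pool_freq = pool_freq, w = w)
}

# fast inlined one-step map on the per-habitat allele-1 frequencies
# (equivalent to resident_step() restricted to frequencies; used by the
# equilibrium solver, which calls it thousands of times)
freq_step <- function(p, z, model) {
  N <- model$N
  sw <- (2 * N - 1) / N
  ztil <- p * z[1] + (1 - p) * z[2]
  base <- model$W + (model$b / N) * (N - sw) * ztil
  w1 <- pmax(base + (model$b / N) * sw * z[1] - model$c * z[1]^2, 0)
  w2 <- pmax(base + (model$b / N) * sw * z[2] - model$c * z[2]^2, 0)
  cap <- model$capacity
  pool1 <- model$m %*% (cap * p * w1)
  tot <- pool1 + model$m %*% (cap * (1 - p) * w2)
  if (any(tot <= 0))
    stop("dispersal pool extinct in habitat ", which(tot <= 0)[1], call. = FALSE)
  as.vector(pool1 / tot)
}

#' Resident population-dynamical equilibrium
#'
#' Iterates [resident_step()] to its fixed point, giving the equilibrium
#' class structure on which all invasion analyses are built. Convergence is
#' accelerated with a damped Newton iteration on the per-habitat allele-1
#' frequencies (the state reduces to two frequencies because habitats are
#' regulated to capacity); plain fixed-point iteration is the fallback, and
#' the neutral case `z1 = z2` (a line of fixed points in the overall allele
#' frequency) is handled by plain iteration alone.
#'
#' @param z length-2 vector of resident phenotypes `(z1, z2)`.
#' @param model a [cue_model()].
#' @param p0 starting allele-1 frequencies per habitat.
#' @param tol convergence tolerance on the maximum frequency change per
#'   step.
#' @param max_iter iteration cap.
#' @param extinct_tol frequency below which an allele is declared extinct
#'   and the equilibrium flagged monomorphic.
#' @return An object of class `"resident_equilibrium"`: a list with the
#'   phenotypes `z`, abundances `n` (2x2), within-habitat frequencies `p_ik`
#'   (2x2), habitat priors `q_i`, conditional habitat probabilities `q_ik`
#'   (`q_ik[i, k]` = P(habitat `i` | cue allele `k`)), overall allele
#'   frequencies (dilution factors) `p_k`, founding probabilities `phi`,
#'   pool composition `pool_freq`, clamped class fecundities `w`, and the
#'   flags `monomorphic`, `converged` plus iteration diagnostics.
#' @examples
#' mod <- cue_model(m = 0.05)
#' eq <- find_resident_equilibrium(c(0.0975, 0.75), mod)
#' eq
#' @export
find_resident_equilibrium <- function(z, model, p0 = c(0.9, 0.1),
                                      tol = 1e-12, max_iter = 1e6,
                                      extinct_tol = 1e-10) {
  stopifnot(length(z) == 2L, all(z >= 0), all(z <= 1))
  cap <- model$capacity
  stepf <- function(p) freq_step(p, z, model)
  resf <- function(p) max(abs(stepf(p) - p))
  neutral <- abs(z[1] - z[2]) < 1e-14
  # The monomorphic boundaries p = (0, 0) and (1, 1) are always fixed points
  # of the map; whether they attract is decided by the growth eigenvalue of
  # the missing allele when rare. A repelling boundary must never be reached
  # by the solver (Newton or extrapolation could otherwise jump onto it), so
  # the iterates are clamped just inside it.
  # with no between-habitat migration the habitats decouple and mixed corners
  # such as p = (1, 0) are legitimate attractors, so no clamping applies
  decoupled <- model$m[1, 2] + model$m[2, 1] < 1e-12
  lo <- 0; hi <- 1
  if (!neutral && !decoupled) {
    if (cue_invasion_eigenvalue(z[2], z[1], model) > 1) lo <- 1e-8
    if (cue_invasion_eigenvalue(z[1], z[2], model) > 1) hi <- 1 - 1e-8
  }
  clampp <- function(p) pmin(pmax(p, lo), hi)
  # scaled (per-capita) residual: near a repelling boundary the raw residual
  # is tiny (proportional to the rare frequency) although the point is far
  # from any admissible equilibrium, so accelerated steps are judged on the
  # residual relative to the frequency scale
  sresf <- function(p) {
    f <- stepf(p) - p
    max(abs(f) / pmax(p * (1 - p), 1e-15))
  }
  p <- clampp(pmin(pmax(p0, 1e-3), 1 - 1e-3))
  resid <- Inf; iters <- 0L; converged <- FALSE
  best <- Inf; best_age <- 0L; newton_rej <- 0L
  while (iters < max_iter) {
    f0 <- stepf(p) - p
    resid <- max(abs(f0))
    if (resid < tol) { converged <- TRUE; break }
    sres <- max(abs(f0) / pmax(p * (1 - p), 1e-15))
    if (sres < best * 0.999) { best <- sres; best_age <- 0L }
    else if ((best_age <- best_age + 1L) > 2000L) break   # stagnation guard
    moved <- FALSE
    if (!neutral && iters >= 3L) {
      # Newton with backtracking on f(p) = step(p) - p; near-neutral
      # dimorphisms make plain iteration arbitrarily slow, Newton does not
      h <- 1e-7
      J <- vapply(1:2, function(d) {
        pp <- p; pp[d] <- pp[d] + h
        (stepf(pp) - pp - f0) / h
      }, numeric(2))
      dl <- tryCatch(solve(J, -f0), error = function(e) NULL)
      if (!is.null(dl) && all(is.finite(dl))) {
        for (sc in c(1, 0.5, 0.25, 0.1)) {
          pn <- clampp(p + sc * dl)
          if (sresf(pn) < 0.9 * sres) { p <- pn; moved <- TRUE; break }
        }
        # watchdog: the residual is not monotone along a curved Newton path,
        # so after repeated rejections take the full step anyway -- but never
        # onto a point that is itself far from equilibrium on the per-capita
        # scale (e.g. a clamped repelling boundary)
        if (!moved && (newton_rej <- newton_rej + 1L) >= 5L) {
          pn <- clampp(p + dl)
          if (sresf(pn) < 0.02) { p <- pn; moved <- TRUE }
          newton_rej <- 0L
        }
        if (moved) newton_rej <- 0L
      }
    }
    if (!moved && best_age > 50L) {
      # persistent stalls are usually period-2 overshoot of the map
      # (eigenvalue below -1); damping stabilises those
      p <- clampp(p + 0.5 * f0)
    } else if (!moved) {
      # plain iteration with vector-Aitken extrapolation for the slow mode
      p1 <- clampp(p + f0)
      f1 <- stepf(p1) - p1
      d2 <- f1 - f0
      pA <- clampp(ifelse(abs(d2) > 1e-14, p - f0^2 / d2, p1))
      # strict margin: an escaping geometric sequence extrapolates backwards
      # onto the repelling point and must not be accepted on a tie
      p <- if (!neutral && sresf(pA) < 0.7 * sresf(p1)) pA else p1
    }
    iters <- iters + 1L
    if (neutral && iters > 1e4) break           # geometric mixing; safeguard
  }
  # near-diagonal dimorphisms are almost neutral and the slow mode cannot be
  # pinned much beyond 1e-9 in double precision; treat that as converged
  converged <- converged || resid < 1e-9
  if (!converged)
    warning(sprintf(
      "resident dynamics not converged after %d iterations (residual %.3g)",
      iters, resid), call. = FALSE)

  n <- cbind(cap * p, cap * (1 - p))
  st <- resident_step(n, z, model)
  p_ik <- n / cap
  q_i <- cap / sum(cap)
  p_k <- colSums(n) / sum(cap)
  mono <- any(p_k < extinct_tol) || any(p_k > 1 - extinct_tol)
  q_ik <- conditional_habitat_probability(n)
  structure(
    list(z = z, n = n, p_ik = p_ik, q_i = q_i, q_ik = q_ik, p_k = p_k,
         phi = st$phi, pool_freq = st$pool_freq, w = st$w,
         monomorphic = mono, converged = converged, iterations = iters,
         residual = resid, model = model),
    class = "resident_equilibrium"
  )
}

#' Conditional habitat probabilities of a cue allele
#'
#' For an allele at a modifier locus, the probability of being in habitat
#' `i` conditional on being linked to cue allele `k`:
#' `q_ik = n_ik / (n_1k + n_2k)`, equivalently `p_ik q_i / sum_j p_jk q_j`.
#' This is the Bayesian-information content of the cue allele about habitat.
#'
#' @param x a `"resident_equilibrium"` or a 2x2 abundance matrix
#'   `n[i, k]`.
#' @return 2x2 matrix `q_ik[i, k]`; columns sum to one. A column is `NaN`
#'   when the allele is extinct (zero total count), in which case a warning
#'   is emitted.
#' @export
conditional_habitat_probability <- function(x) {
  n <- if (inherits(x, "resident_equilibrium")) x$n else x
  stopifnot(is.matrix(n), all(dim(n) == 2L), all(n >= 0))
  tot <- colSums(n)
  if (any(tot == 0))
    warning("cue allele ", which(tot == 0)[1],
            " extinct: conditional habitat probability undefined",
            call. = FALSE)
  sweep(n, 2L, tot, "/")
}

#' @export
print.resident_equilibrium <- function(x, ...) {
  cat("Resident equilibrium for dimorphism z = (",
      sprintf("%.5g", x$z[1]), ", ", sprintf("%.5g", x$z[2]), ")\n", sep = "")
  cat(sprintf("  allele-1 frequency per habitat: %.5f, %.5f%s\n",
              x$p_ik[1, 1], x$p_ik[2, 1],
              if (x$monomorphic) "  [monomorphic]" else ""))
  cat(sprintf("  dilution factors p_k: %.5f, %.5f\n", x$p_k[1], x$p_k[2]))
  cat(sprintf("  q_ik (habitat x allele):\n"))
  q <- round(x$q_ik, 5)
  cat(sprintf("    x1: %.5f / %.5f    x2: %.5f / %.5f\n",
              q[1, 1], q[2, 1], q[1, 2], q[2, 2]))
  cat(sprintf("  converged: %s after %d iterations (residual %.2g)\n",
              x$converged, x$iterations, x$residual))
  invisible(x)
}
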