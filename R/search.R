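#' Mutual invasibility of two cue-allele phenotypes
#'
#' Tests whether a dimorphism `(z1, z2)` is protected: each phenotype, as a
#' rare cue allele, must have positive invasion fitness against a
#' monomorphism of the other. Because the invader here is the cue allele
#' itself (fully linked to itself), the invasion uses the 2-class
#' habitat-only projection matrix `B[j, i] = phi_j * m_ji * w'_i(z_inv)`
#' built on the monomorphic resident's demographic equilibrium; the
#' cue-modifier recombination rate plays no role.
#'
#' @param z1,z2 candidate phenotypes in `[0, 1]`. Equal phenotypes are
#'   neutral and return `FALSE`.
#' @param model a [cue_model()].
#' @return Logical; attribute `"lambda"` holds the two invasion
#'   eigenvalues (`z2` into `z1`-monomorphism, then `z1` into `z2`).
#' @export
coexistence_test <- function(z1, z2, model) {
  stopifnot(z1 >= 0, z1 <= 1, z2 >= 0, z2 <= 1)
  if (abs(z1 - z2) < 1e-12) {
    out <- FALSE
    attr(out, "lambda") <- c(NA_real_, NA_real_)
    return(out)
  }
  l1 <- cue_invasion_eigenvalue(z1, z2, model)  # z2 invades z1-monomorphism
  l2 <- cue_invasion_eigenvalue(z2, z1, model)
  out <- l1 > 1 && l2 > 1
  attr(out, "lambda") <- c(l1, l2)
  out
}

# leading eigenvalue of the 2-class (habitat-only) matrix for a rare cue
# allele with phenotype `zi` invading a monomorphic resident `zr`
cue_invasion_eigenvalue <- function(zr, zi, model) {
  cap <- model$capacity
  wres <- fecundity(payoff(zr, zr, 1:2, model))
  pool <- as.vector(model$m %*% (cap * wres))
  if (any(pool <= 0)) stop("resident population not viable", call. = FALSE)
  phi <- cap / pool
  wmut <- fecundity(vapply(1:2, function(i)
    expected_mutant_payoff(zi, zr, i, model), numeric(1)))
  B <- outer(phi, wmut) * model$m
  max(Re(eigen(B, only.values = TRUE)$values))
}

#' Coexistence region over a phenotype grid
#'
#' Evaluates [coexistence_test()] on a regular grid over the unit square.
#'
#' @param model a [cue_model()].
#' @param grid_step grid spacing in `(0, 0.1]`.
#' @return Object of class `"coexistence_region"`: list with the grid
#'   values `z`, the logical `mask` (`mask[i, j]` for the pair
#'   `(z[i], z[j])`), and the model. The mask excludes the diagonal by
#'   construction and `any(mask)` tells whether any protected dimorphism
#'   exists at this resolution.
#' @export
coexistence_region <- function(model, grid_step = 0.02) {
  stopifnot(grid_step > 0, grid_step <= 0.1)
  z <- seq(0, 1, by = grid_step)
  nz <- length(z)
  mask <- matrix(FALSE, nz, nz)
  # eigenvalue of (zr <- zi) reused for both orientations of a pair
  lam <- matrix(NA_real_, nz, nz)
  for (a in seq_len(nz)) for (b in seq_len(nz))
    if (a != b) lam[a, b] <- cue_invasion_eigenvalue(z[a], z[b], model)
  for (a in seq_len(nz)) for (b in seq_len(nz))
    if (a != b) mask[a, b] <- lam[a, b] > 1 && lam[b, a] > 1
  structure(list(z = z, mask = mask, lambda = lam, model = model),
            class = "coexistence_region")
}

#' @export
print.coexistence_region <- function(x, ...) {
  npairs <- sum(x$mask[upper.tri(x$mask)])
  cat(sprintf("Coexistence region on a %.3g grid: %d protected pairs (of %d)\n",
              diff(x$z[1:2]), npairs, sum(upper.tri(x$mask))))
  invisible(x)
}

#' @export
plot.coexistence_region <- function(x, ...) {
  graphics::image(x$z, x$z, t(x$mask) * 1, col = c("white", "grey70"),
                  xlab = expression(z[1]), ylab = expression(z[2]),
                  main = "protected dimorphisms", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Gradient-path search for a dimorphic evolutionary equilibrium
#'
#' Follows the selection gradient through `(z1, z2)`-space in small
#' projected steps, re-solving the resident equilibrium at every step,
#' until the gradient norm falls below `tol` (with a Newton polish once
#' close), the path leaves the coexistence region (polymorphism collapse),
#' or the two phenotypes merge onto the diagonal (the dimorphism dissolves
#' into an effective monomorphism at the singular strategy).
#'
#' @param start length-2 starting dimorphism, inside the coexistence
#'   region.
#' @param model a [cue_model()].
#' @param rho recombination rate; defaults to the model's.
#' @param step_size step length on the phenotype scale (the step taken is
#'   `step_size` times the normalised gradient direction, adaptively halved
#'   on overshoot).
#' @param tol convergence tolerance on the gradient norm.
#' @param max_steps step cap.
#' @param merge_tol diagonal gap below which the pair is declared merged.
#' @return Object of class `"cue_equilibrium"`: list with the final `z`,
#'   `status` (`"converged"`, `"collapsed"`, `"merged"` or
#'   `"max_steps"`), the final `gradient`, number of `steps`, the final
#'   resident equilibrium `eq` (when dimorphic) and the model. A
#'   `boundary` flag marks equilibria within `1e-6` of the `[0, 1]`
#'   boundary.
#' @examples
#' mod <- cue_model(m = 0.01)
#' eqm <- ascend_to_equilibrium(c(0.2, 0.6), mod)
#' eqm$z
#' @export
ascend_to_equilibrium <- function(start, model, rho = NULL,
                                  step_size = 0.01, tol = 1e-6,
                                  max_steps = 5000, merge_tol = 1e-3) {
  if (is.null(rho)) rho <- model$rho
  z <- pmin(pmax(start, 0), 1)
  if (!coexistence_test(z[1], z[2], model))
    stop("starting dimorphism is not inside the coexistence region",
         call. = FALSE)
  p0 <- c(0.9, 0.1)
  step <- step_size
  gprev <- NULL
  inward <- 0L          # consecutive steps contracting toward the diagonal
  reversals <- 0L       # consecutive direction reversals (straddling a zero)
  polish_gate <- Inf    # only retry the Newton polish once gn has halved
  solve_eq <- function(zz, p_start) {
    eq <- suppressWarnings(
      find_resident_equilibrium(zz, model, p0 = p_start, max_iter = 3000))
    if (!eq$converged)
      eq <- find_resident_equilibrium(zz, model, p0 = c(0.9, 0.1),
                                      max_iter = 1e5)
    eq
  }
  done <- function(status, g, eq = NULL, steps = 0L) {
    structure(list(z = z, status = status, gradient = g, steps = steps,
                   eq = eq, rho = rho, model = model,
                   boundary = any(z < 1e-6 | z > 1 - 1e-6)),
              class = "cue_equilibrium")
  }
  for (it in seq_len(max_steps)) {
    gap <- abs(z[1] - z[2])
    if (gap < merge_tol || (gap < 5 * merge_tol && inward >= 10L)) {
      z <- rep(mean(z), 2)
      return(done("merged", c(NA, NA), steps = it))
    }
    if (!coexistence_test(z[1], z[2], model))
      return(done("collapsed", c(NA, NA), steps = it))
    eq <- solve_eq(z, p0)
    p0 <- eq$p_ik[, 1]
    g <- selection_gradient(eq = eq, rho = rho)
    if (any(is.na(g))) return(done("collapsed", g, steps = it))
    gn <- sqrt(sum(g^2))
    # contraction bookkeeping: is the pair being pushed together?
    lo <- which.min(z); hi <- 3L - lo
    inward <- if (g[lo] > 0 && g[hi] < 0) inward + 1L else 0L
    if ((gn < 1e-3 || reversals >= 4L) && gn < polish_gate) {
      # Newton polish on g(z) = 0
      for (nw in 1:25) {
        eq <- solve_eq(z, p0)
        p0 <- eq$p_ik[, 1]
        g <- selection_gradient(eq = eq, rho = rho)
        if (any(is.na(g))) return(done("collapsed", g, steps = it + nw))
        if (sqrt(sum(g^2)) < tol)
          return(done("converged", g, eq, steps = it + nw))
        h <- 1e-6
        J <- vapply(1:2, function(d) {
          zz <- z; zz[d] <- zz[d] + h
          (selection_gradient(eq = solve_eq(zz, p0), rho = rho) - g) / h
        }, numeric(2))
        dz <- tryCatch(solve(J, -g), error = function(e) NULL)
        if (is.null(dz) || any(!is.finite(dz)) || max(abs(dz)) > 0.1) break
        zn <- pmin(pmax(z + dz, 0), 1)
        if (abs(zn[1] - zn[2]) < merge_tol) {
          z <- rep(mean(zn), 2)
          return(done("merged", g, steps = it + nw))
        }
        if (!coexistence_test(zn[1], zn[2], model))
          return(done("collapsed", g, steps = it + nw))
        z <- zn
      }
      polish_gate <- gn / 2   # polish failed; wait for real progress
    }
    # adaptive normalised-gradient step: halve on direction reversal
    if (!is.null(gprev) && sum(g * gprev) < 0) {
      step <- max(step / 2, 1e-5)
      reversals <- reversals + 1L
    } else {
      step <- min(step * 1.2, step_size)
      reversals <- 0L
    }
    gprev <- g
    z <- pmin(pmax(z + step * g / gn, 0), 1)
  }
  warning("gradient path did not converge within max_steps", call. = FALSE)
  done("max_steps", g, steps = max_steps)
}

#' @export
print.cue_equilibrium <- function(x, ...) {
  cat(sprintf("Gradient-path result (rho = %g): %s\n", x$rho, x$status))
  cat(sprintf("  z = (%.5f, %.5f)  after %d steps\n", x$z[1], x$z[2], x$steps))
  if (x$status == "converged")
    cat(sprintf("  gradient = (%+.2e, %+.2e)%s\n", x$gradient[1], x$gradient[2],
                if (x$boundary) "  [boundary-constrained]" else ""))
  invisible(x)
}

#' Monomorphic singular strategy
#'
#' The equilibrium of gradual evolution in a cue-monomorphic population:
#' the root of the monomorphic selection gradient
#' `g(z) = sum_i V_i(z) d_i(z) u_i(z)` built from the 2-class habitat-only
#' projection matrix at the monomorphic demographic equilibrium. For
#' habitat-symmetric game parameters and symmetric migration it reduces to
#' `z* = b [ (2N1-1)/N1^2 + (2N2-1)/N2^2 ] / (4c)` and does not depend on
#' the migration or recombination rates.
#'
#' @param model a [cue_model()].
#' @param interval search interval for the root.
#' @return The singular phenotype `z*`; if the gradient has no sign change
#'   on the interval the better boundary is returned with attribute
#'   `"boundary" = TRUE`.
#' @examples
#' monomorphic_singular_strategy(cue_model())   # 0.42375
#' @export
monomorphic_singular_strategy <- function(model, interval = c(0, 1)) {
  g <- function(z) {
    wres <- fecundity(payoff(z, z, 1:2, model))
    pool <- as.vector(model$m %*% (model$capacity * wres))
    phi <- model$capacity / pool
    B <- outer(phi, wres) * model$m
    pr <- perron(B)
    V <- as.vector(t(pr$v * phi) %*% model$m)
    d <- vapply(1:2, function(i) payoff_derivative(z, i, model), numeric(1))
    sum(V * d * pr$u)
  }
  glo <- g(interval[1]); ghi <- g(interval[2])
  if (sign(glo) == sign(ghi)) {
    zb <- if (glo > 0) interval[2] else interval[1]
    attr(zb, "boundary") <- TRUE
    warning("monomorphic gradient has no interior root; boundary optimum",
            call. = FALSE)
    return(zb)
  }
  stats::uniroot(g, interval, tol = 1e-12)$root
}

#' Sweep of evolutionary equilibria over migration and recombination
#'
#' Runs [ascend_to_equilibrium()] for every combination of the supplied
#' migration and recombination rates, together with the (m- and
#' rho-independent) monomorphic singular strategy, reproducing the
#' equilibrium-dimorphism structure of the model: divergence
#' `|z2 - z1|` shrinking with recombination, more so at higher migration,
#' and collapse to monomorphism at high migration.
#'
#' @param model a [cue_model()]; its `m` and `rho` are overridden by the
#'   sweep values.
#' @param m_values migration rates to sweep.
#' @param rho_values recombination rates to sweep.
#' @param start starting dimorphism, or `"auto"` to start from the
#'   no-dispersal optima pair (shrunk toward the singular strategy until
#'   inside the coexistence region).
#' @param ... passed on to [ascend_to_equilibrium()].
#' @return Object of class `"cue_sweep"`: a data frame with columns `m`,
#'   `rho`, `z1`, `z2`, `divergence`, `status`, `converged`, `coexists`
#'   plus attributes `z_mono` (the singular strategy) and `model`.
#'   Individual cell failures are recorded as `status = "error"` rows.
#' @export
sweep_equilibria <- function(model, m_values, rho_values, start = "auto", ...) {
  z_mono <- monomorphic_singular_strategy(model)
  rows <- vector("list", length(m_values) * length(rho_values))
  idx <- 0L
  for (m in m_values) for (rho in rho_values) {
    idx <- idx + 1L
    mod <- update_model(model, m = m, rho = rho)
    res <- tryCatch({
      s0 <- if (identical(start, "auto")) auto_start(mod) else start
      if (is.null(s0)) {
        list(z = c(NA, NA), status = "no_coexistence")
      } else ascend_to_equilibrium(s0, mod, rho = rho, ...)
    }, error = function(e) list(z = c(NA, NA), status = "error",
                                message = conditionMessage(e)))
    dim_ok <- res$status == "converged"
    rows[[idx]] <- data.frame(
      m = m, rho = rho, z1 = res$z[1], z2 = res$z[2],
      divergence = if (res$status %in% c("merged", "collapsed", "no_coexistence"))
        0 else abs(res$z[2] - res$z[1]),
      status = res$status, converged = dim_ok,
      coexists = dim_ok && isTRUE(coexistence_test(res$z[1], res$z[2], mod)))
  }
  out <- do.call(rbind, rows)
  attr(out, "z_mono") <- z_mono
  attr(out, "model") <- model
  class(out) <- c("cue_sweep", "data.frame")
  out
}

# deterministic ascent start: the pair of no-dispersal habitat optima,
# pulled toward the singular strategy until protected
auto_start <- function(model, min_scale = 0.05) {
  zopt <- model$b * (2 * model$N - 1) / (2 * model$c * model$N^2)
  zopt <- pmin(pmax(zopt, 0), 1)
  zs <- monomorphic_singular_strategy(model)
  for (t in seq(1, min_scale, by = -0.05)) {
    cand <- zs + t * (zopt - zs)
    if (isTRUE(coexistence_test(cand[1], cand[2], model))) return(cand)
  }
  NULL
}

#' @export
print.cue_sweep <- function(x, ...) {
  cat(sprintf("Equilibrium sweep (%d cells), monomorphic singular strategy z* = %.5f\n",
              nrow(x), attr(x, "z_mono")))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cue_sweep <- function(x, ...) {
  ms <- unique(x$m)
  graphics::plot(NULL, xlim = range(x$rho), ylim = c(0, 1),
                 xlab = expression(rho), ylab = "equilibrium z",
                 main = "equilibrium dimorphisms", ...)
  graphics::abline(h = attr(x, "z_mono"), col = "grey50")
  for (i in seq_along(ms)) {
    sub <- x[x$m == ms[i], ]
    graphics::lines(sub$rho, sub$z1, col = "blue", lty = i, type = "b", pch = i)
    graphics::lines(sub$rho, sub$z2, col = "red", lty = i, type = "b", pch = i)
  }
  graphics::legend("topright", legend = paste("m =", ms), lty = seq_along(ms),
                   bty = "n")
  invisible(x)
}

#' Migration threshold for the collapse of the cue polymorphism
#'
#' For each migration rate in `m_values`, determines whether the joint
#' evolutionary dynamics still supports a dimorphism: the gradient path is
#' followed from the protected no-dispersal-optima start at each
#' recombination rate in `rho_values`, and the outcome is monomorphic when
#' every path merges onto the diagonal, collapses out of the coexistence
#' region, or no protected starting pair exists. Tight linkage is the case
#' most favourable to polymorphism, so `rho_values = 0` suffices to locate
#' the threshold; additional values confirm "regardless of rho".
#'
#' Note that the static mutual-invasibility region can remain non-empty at
#' migration rates where modifier evolution nevertheless destroys the
#' polymorphism; the threshold reported here is the evolutionary outcome.
#'
#' @param model a [cue_model()].
#' @param m_values migration rates to scan (scanned in increasing order).
#' @param rho_values recombination rates that must all collapse.
#' @param ... passed to [ascend_to_equilibrium()].
#' @return List with `threshold` (smallest scanned `m` at which the
#'   outcome is monomorphic for all `rho`, or `NA` if none) and the
#'   per-`m` outcome table `outcomes`.
#' @export
collapse_threshold <- function(model, m_values = c(0.05, 0.10, 0.15, 0.20),
                               rho_values = 0, ...) {
  m_values <- sort(m_values)
  rows <- lapply(m_values, function(m) {
    mono <- vapply(rho_values, function(rho) {
      mod <- update_model(model, m = m, rho = rho)
      s0 <- auto_start(mod)
      if (is.null(s0)) return(TRUE)
      res <- ascend_to_equilibrium(s0, mod, rho = rho, ...)
      res$status %in% c("merged", "collapsed")
    }, logical(1))
    data.frame(m = m, monomorphic = all(mono))
  })
  outcomes <- do.call(rbind, rows)
  thr <- outcomes$m[outcomes$monomorphic][1]
  list(threshold = if (length(thr) && !is.na(thr)) thr else NA_real_,
       outcomes = outcomes)
}
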