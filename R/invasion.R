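#' Cue inheritance probabilities
#'
#' Probability that an offspring founded in habitat `j` carries cue allele
#' `l` given its (modifier-side) parent carried allele `k`:
#' `h_jlk = (1 - rho) * delta_lk + rho * p_jl`, mixing faithful transmission
#' with recombination onto a random cue allele from the dispersal pool.
#'
#' @param rho recombination rate between cue and modifier locus.
#' @param pool_freq 2x2 matrix of pool cue-allele frequencies,
#'   `pool_freq[j, l]`; rows must sum to one.
#' @return A 2x2x2 array `h[j, l, k]`; for each `(j, k)` the `l`-slices sum
#'   to one.
#' @export
cue_inheritance <- function(rho, pool_freq) {
  stopifnot(rho >= 0, rho <= 0.5, is.matrix(pool_freq),
            all(dim(pool_freq) == 2L))
  if (any(abs(rowSums(pool_freq) - 1) > 1e-8))
    stop("pool frequencies must be normalised per habitat", call. = FALSE)
  h <- array(0, c(2, 2, 2), dimnames = list(habitat = NULL, l = NULL, k = NULL))
  for (j in 1:2) for (l in 1:2) for (k in 1:2)
    h[j, l, k] <- (if (l == k) 1 - rho else 0) + rho * pool_freq[j, l]
  h
}

# class index of (habitat j, linked cue allele l) in the 4x4 ordering
class_index <- function(j, l) (j - 1L) * 2L + l

#' Mutant-modifier projection matrix
#'
#' The 4x4 projection matrix of a rare mutant modifier over the classes
#' (habitat, linked cue allele), built on a converged resident equilibrium.
#' The entry for transition `(i, k) -> (j, l)` is
#' `phi_j * m_ji * w'_i(z'_k) * h_jlk`, where `w'_i(z'_k)` is the expected
#' (clamped) payoff of a mutant expressing `z'_k` in habitat `i`
#' ([expected_mutant_payoff()]) and `h` is the cue inheritance evaluated at
#' the equilibrium pool composition. With the resident phenotypes as mutant
#' (`zprime = z`) the matrix has leading eigenvalue 1 and right eigenvector
#' equal to the equilibrium class abundances.
#'
#' @param zprime length-2 vector of mutant phenotypes `(z'_1, z'_2)`
#'   expressed when linked to cue alleles 1 and 2.
#' @param eq a converged [find_resident_equilibrium()].
#' @param rho recombination rate; defaults to the model's.
#' @return 4x4 non-negative matrix, class order
#'   `(h1,x1), (h1,x2), (h2,x1), (h2,x2)`.
#' @export
mutant_projection_matrix <- function(zprime, eq, rho = NULL) {
  stopifnot(inherits(eq, "resident_equilibrium"))
  if (!eq$converged)
    stop("resident equilibrium has not converged", call. = FALSE)
  model <- eq$model
  if (is.null(rho)) rho <- model$rho
  h <- cue_inheritance(rho, eq$pool_freq)
  ztilde <- eq$p_ik[, 1] * eq$z[1] + eq$p_ik[, 2] * eq$z[2]
  wm <- sapply(1:2, function(k) sapply(1:2, function(i)
    fecundity(expected_mutant_payoff(zprime[k], ztilde[i], i, model))))
  A <- matrix(0, 4, 4)
  lab <- c("h1.x1", "h1.x2", "h2.x1", "h2.x2")
  dimnames(A) <- list(to = lab, from = lab)
  for (j in 1:2) for (l in 1:2) for (i in 1:2) for (k in 1:2)
    A[class_index(j, l), class_index(i, k)] <-
      eq$phi[j] * model$m[j, i] * wm[i, k] * h[j, l, k]
  A
}

# leading (Perron) eigenvalue and eigenvectors of a non-negative matrix;
# right eigenvector sign-fixed to non-negative entries, left eigenvector
# normalised v.u = 1 with sum(u) = 1
perron <- function(A) {
  ed <- eigen(A)
  i <- which.max(Re(ed$values))
  lam <- Re(ed$values[i])
  u <- Re(ed$vectors[, i])
  if (sum(u) < 0) u <- -u
  if (any(u < -1e-8 * max(abs(u))))
    warning("leading eigenvector has mixed signs; eigenstructure may be degenerate",
            call. = FALSE)
  u <- pmax(u, 0); u <- u / sum(u)
  v <- Re(solve(ed$vectors)[i, ])
  v <- v / sum(v * u)
  list(lambda = lam, u = u, v = v)
}

#' Invasion fitness of a mutant modifier
#'
#' `F = log(lambda)` where `lambda` is the leading eigenvalue of the mutant
#' projection matrix built on the resident equilibrium of the dimorphism
#' `z`. `F > 0` means the mutant modifier invades. The resident itself is
#' neutral: `F(z; z) = 0`.
#'
#' @param zprime length-2 mutant phenotype pair.
#' @param z length-2 resident dimorphism; ignored when `eq` is supplied.
#' @param model a [cue_model()].
#' @param rho recombination rate; defaults to the model's.
#' @param eq optionally a precomputed resident equilibrium.
#' @return An object of class `"invasion_result"`: list with `matrix`,
#'   `lambda`, `F`, stable class distribution `u`, reproductive values `v`.
#' @examples
#' mod <- cue_model(m = 0.05, rho = 0.25)
#' inv <- invasion_fitness(c(0.1, 0.7), c(0.12, 0.68), mod)
#' inv$F
#' @export
invasion_fitness <- function(zprime, z = NULL, model = NULL, rho = NULL,
                             eq = NULL) {
  if (is.null(eq)) {
    stopifnot(!is.null(z), !is.null(model))
    eq <- find_resident_equilibrium(z, model)
  }
  if (is.null(rho)) rho <- eq$model$rho
  A <- mutant_projection_matrix(zprime, eq, rho)
  pr <- suppressWarnings(perron(A))
  structure(list(matrix = A, lambda = pr$lambda, F = log(pr$lambda),
                 u = pr$u, v = pr$v, zprime = zprime, z = eq$z, rho = rho),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Mutant modifier (%.5g, %.5g) vs resident (%.5g, %.5g), rho = %g\n",
              x$zprime[1], x$zprime[2], x$z[1], x$z[2], x$rho))
  cat(sprintf("  leading eigenvalue = %.8f   invasion fitness F = %+.3e  (%s)\n",
              x$lambda, x$F,
              if (x$F > 0) "invades" else "does not invade"))
  invisible(x)
}

#' Reproductive values of the resident classes
#'
#' Left Perron eigenvector `v_jl` of the resident-valued projection matrix
#' (reproductive value of an individual in class `(j, l)` at the census
#' point, normalised so `v . u = 1` with `u` the stable class distribution),
#' together with the offspring reproductive values
#' `V_ik = sum_jl v_jl * phi_j * h_jlk * m_ji` that weight the selection
#' gradient.
#'
#' At full linkage (`rho = 0`) the projection matrix is block-diagonal in
#' the cue-allele lineages and the leading eigenvalue 1 is degenerate (both
#' lineages are stationary), so `v` and `V` are computed per 2x2 habitat
#' block, each block normalised against its own stable distribution.
#'
#' @param eq a converged [find_resident_equilibrium()].
#' @param rho recombination rate; defaults to the model's.
#' @return List with `v` (length 4, census reproductive values), `u`
#'   (stable class distribution), `V` (2x2 matrix `V[i, k]` of offspring
#'   reproductive values) and the per-block eigen data at `rho = 0`.
#' @export
reproductive_values <- function(eq, rho = NULL) {
  stopifnot(inherits(eq, "resident_equilibrium"))
  model <- eq$model
  if (is.null(rho)) rho <- model$rho
  h <- cue_inheritance(rho, eq$pool_freq)
  V <- matrix(0, 2, 2, dimnames = list(habitat = NULL, allele = NULL))
  if (rho > 0) {
    A <- mutant_projection_matrix(eq$z, eq, rho)
    pr <- perron(A)
    v <- pr$v; u <- pr$u
    for (i in 1:2) for (k in 1:2)
      for (j in 1:2) for (l in 1:2)
        V[i, k] <- V[i, k] +
          v[class_index(j, l)] * eq$phi[j] * h[j, l, k] * model$m[j, i]
    return(list(v = v, u = u, V = V, rho = rho))
  }
  # rho = 0: per-allele 2x2 habitat blocks, each stationary at the resident
  v <- numeric(4); u <- numeric(4)
  for (k in 1:2) {
    Ak <- outer(eq$phi, eq$w[, k]) * model$m     # [j, i]
    pk <- perron(Ak)
    for (j in 1:2) v[class_index(j, k)] <- pk$v[j]
    for (j in 1:2) u[class_index(j, k)] <- pk$u[j] * eq$p_k[k]
    V[, k] <- as.vector(t(pk$v * eq$phi) %*% model$m)  # V_i = sum_j v_j phi_j m_ji
  }
  list(v = v, u = u, V = V, rho = 0)
}

#' Selection gradient on the dimorphism
#'
#' Derivative of the invasion fitness of a mutant modifier with respect to
#' the mutant phenotypes, evaluated at the resident:
#' `g_k = V_1k d_1k p_k q_1k + V_2k d_2k p_k q_2k`, combining the offspring
#' reproductive values `V_ik`, the payoff derivatives `d_ik`
#' ([payoff_derivative()]), the dilution factor `p_k` (overall frequency of
#' the cue allele the mutant is linked to) and the conditional habitat
#' probabilities `q_ik`. Equals the eigenvalue sensitivity
#' `dF/dz'_k` of [invasion_fitness()] (at `rho = 0`, of the per-allele
#' block fitness).
#'
#' @param z length-2 resident dimorphism; ignored when `eq` is supplied.
#' @param model a [cue_model()].
#' @param rho recombination rate; defaults to the model's.
#' @param eq optionally a precomputed resident equilibrium.
#' @return Length-2 numeric gradient `(g_1, g_2)`. When the equilibrium is
#'   monomorphic the gradient of the extinct allele's phenotype is `NA` and
#'   a `"monomorphic"` attribute is set.
#' @export
selection_gradient <- function(z = NULL, model = NULL, rho = NULL, eq = NULL) {
  if (is.null(eq)) {
    stopifnot(!is.null(z), !is.null(model))
    eq <- find_resident_equilibrium(z, model)
  }
  model <- eq$model
  if (is.null(rho)) rho <- model$rho
  rv <- reproductive_values(eq, rho)
  g <- numeric(2)
  for (k in 1:2) {
    d <- c(payoff_derivative(eq$z[k], 1, model),
           payoff_derivative(eq$z[k], 2, model))
    if (rho > 0) {
      # u_ik = p_k q_ik when u is the stable distribution summing to one
      g[k] <- sum(rv$V[, k] * d * rv$u[class_index(1:2, k)])
    } else {
      g[k] <- eq$p_k[k] * sum(rv$V[, k] * d * eq$q_ik[, k])
    }
  }
  if (eq$monomorphic) {
    dead <- which(eq$p_k < 1e-8)
    g[dead] <- NA_real_
    attr(g, "monomorphic") <- TRUE
  }
  g
}
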