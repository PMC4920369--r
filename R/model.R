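#' Two-habitat social-evolution model parameters
#'
#' Bundles the parameters of the two-habitat public-goods model: group sizes,
#' habitat capacities, game payoff constants, migration and the recombination
#' rate between the cue locus and a modifier locus. The returned object is the
#' first argument of essentially every other function in the package.
#'
#' Habitat `i` hosts groups founded by `N[i]` haploid individuals; founders
#' reproduce asexually so that pairwise relatedness among offspring group
#' members is `r[i] = 1/N[i]`. The payoff to an individual investing `z` in a
#' group with mean investment `zbar` is `W[i] + b[i]*zbar - c[i]*z^2`.
#' Offspring disperse between habitats at rates given by `m`, mate at random
#' in the per-habitat dispersal pool (with cue-modifier recombination at rate
#' `rho`), and found the next round of groups, each habitat being regulated to
#' a fixed capacity.
#'
#' @param N integer vector of length 2, founders per group in each habitat;
#'   default `(20, 2)`, low relatedness in habitat 1, high in habitat 2.
#' @param capacity positive vector of length 2, relative (or absolute) census
#'   population size of each habitat. Only ratios matter for the
#'   deterministic machinery.
#' @param W,b,c numeric length-2 vectors of per-habitat payoff constants
#'   (baseline, benefit and cost coefficients). `b >= 0`, `c > 0`.
#' @param m between-habitat migration. Either a single rate in `[0, 0.5]`
#'   (symmetric: an offspring switches habitat with probability `m`) or a
#'   2x2 column-stochastic matrix with `m[j, i]` the rate from habitat `i`
#'   to `j`.
#' @param rho recombination rate between cue and modifier locus, in
#'   `[0, 0.5]`. `rho = 0` is full linkage, `rho = 0.5` free recombination.
#'
#' @return An object of class `"cue_model"`: a list with elements `N`,
#'   `capacity`, `W`, `b`, `c`, `m` (always stored as the 2x2 matrix),
#'   `rho` and the derived relatedness vector `r = 1/N`.
#'
#' @examples
#' mod <- cue_model()              # the reference parameter set
#' mod
#' cue_model(m = 0.1, rho = 0.5)
#' @export
cue_model <- function(N = NULL, capacity = rep(1, 2),
                      W = rep(0.5, 2), b = rep(3, 2), c = rep(1.5, 2),
                      m = 0.05, rho = 0) {
  # the cost argument is named `c` (the field's standard symbol), so defaults
  # must not call base::c(); the reference N = (20, 2) is resolved here
  if (is.null(N)) N <- as.integer(10)^(1:0) * as.integer(2)
  N <- as.integer(N)
  if (length(N) != 2L || any(is.na(N)) || any(N < 1L))
    stop("`N` must be two integers >= 1", call. = FALSE)
  stopifnot(length(capacity) == 2L, all(is.finite(capacity)), all(capacity > 0))
  for (nm in c("W", "b", "c")) {
    v <- get(nm)
    if (length(v) == 1L) v <- rep(v, 2L)
    if (length(v) != 2L || any(!is.finite(v)))
      stop("`", nm, "` must be a finite length-2 vector", call. = FALSE)
    assign(nm, v)
  }
  if (any(b < 0)) stop("benefit coefficients `b` must be >= 0", call. = FALSE)
  if (any(c <= 0)) stop("cost coefficients `c` must be > 0", call. = FALSE)
  m <- mig_matrix(m)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 0.5)
    stop("`rho` must be a single value in [0, 0.5]", call. = FALSE)
  structure(
    list(N = N, capacity = as.numeric(capacity), W = W, b = b, c = c,
         m = m, rho = rho, r = 1 / N),
    class = "cue_model"
  )
}

#' Build and validate a migration matrix
#'
#' `m[j, i]` is the rate of migration from habitat `i` to habitat `j`;
#' columns must sum to one. A scalar is expanded to the symmetric matrix
#' with off-diagonal `m`.
#'
#' @param m scalar migration rate or 2x2 column-stochastic matrix.
#' @return A 2x2 column-stochastic matrix.
#' @export
mig_matrix <- function(m) {
  if (is.matrix(m)) {
    if (!all(dim(m) == c(2L, 2L)) || any(m < 0) ||
        any(abs(colSums(m) - 1) > 1e-12))
      stop("migration matrix must be 2x2 with columns summing to 1",
           call. = FALSE)
    return(unname(m))
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > 0.5)
    stop("scalar migration rate must lie in [0, 0.5]", call. = FALSE)
  matrix(c(1 - m, m, m, 1 - m), 2L, 2L)
}

#' @export
print.cue_model <- function(x, ...) {
  cat("Two-habitat social-evolution model\n")
  cat(sprintf("  founders per group  N = (%d, %d)   relatedness r = (%.4g, %.4g)\n",
              x$N[1], x$N[2], x$r[1], x$r[2]))
  cat(sprintf("  capacities          (%g, %g)\n", x$capacity[1], x$capacity[2]))
  cat(sprintf("  payoff  W = (%g, %g)  b = (%g, %g)  c = (%g, %g)\n",
              x$W[1], x$W[2], x$b[1], x$b[2], x$c[1], x$c[2]))
  off <- c(x$m[2, 1], x$m[1, 2])
  cat(sprintf("  migration m21 = %g, m12 = %g   recombination rho = %g\n",
              off[1], off[2], x$rho))
  invisible(x)
}

# internal: replace the migration and/or rho of a model without re-validating
# the untouched pieces
update_model <- function(model, m = NULL, rho = NULL) {
  if (!is.null(m)) model$m <- mig_matrix(m)
  if (!is.null(rho)) model$rho <- rho
  model
}
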