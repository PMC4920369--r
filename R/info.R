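#' Information carried by a cue about habitat
#'
#' From a 2x2 table of (habitat x cue-allele) counts -- analytic class
#' abundances or an empirical census -- computes the conditional habitat
#' probabilities `q_ik` and the mutual information (in bits) between cue
#' state and habitat, `MI = sum p(i,k) log2[ p(i,k) / (p(i) p(k)) ]`.
#' With two habitats `MI` is bounded by 1 bit. When an allele is extinct
#' the MI is computed on the remaining support and that allele's `q`
#' column is undefined (`NaN`).
#'
#' @param x a 2x2 count/abundance matrix `n[i, k]`, a
#'   `"resident_equilibrium"`, or a `"cue_sim"` (final census of one
#'   replicate).
#' @param replicate replicate index for simulation input.
#' @return Object of class `"info_summary"`: list with `counts`, `q_ik`,
#'   `mi` (bits), and the marginal entropies `H_habitat`, `H_cue`.
#' @examples
#' empirical_cue_information(matrix(c(900, 100, 100, 900), 2))$mi
#' @export
empirical_cue_information <- function(x, replicate = 1) {
  n <- if (inherits(x, "resident_equilibrium")) {
    x$n
  } else if (inherits(x, "cue_sim")) {
    fin <- x$final[[replicate]]
    rbind(tabulate(fin[[1]]$cue + 1L, 2L), tabulate(fin[[2]]$cue + 1L, 2L))
  } else x
  stopifnot(is.matrix(n), all(dim(n) == 2L), all(n >= 0), sum(n) > 0)
  q_ik <- suppressWarnings(conditional_habitat_probability(n))
  p <- n / sum(n)
  pi_ <- rowSums(p); pk <- colSums(p)
  terms <- p * log2(p / outer(pi_, pk))
  mi <- sum(terms[p > 0])
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  structure(list(counts = n, q_ik = q_ik, mi = mi,
                 H_habitat = ent(pi_), H_cue = ent(pk)),
            class = "info_summary")
}

#' @export
print.info_summary <- function(x, ...) {
  cat(sprintf("Cue information: MI = %.4f bits (H_habitat = %.4f, H_cue = %.4f)\n",
              x$mi, x$H_habitat, x$H_cue))
  cat(sprintf("  P(habitat 1 | x1) = %.4f   P(habitat 1 | x2) = %.4f\n",
              x$q_ik[1, 1], x$q_ik[1, 2]))
  invisible(x)
}

#' Logistic regression of habitat on liability
#'
#' Maximum-likelihood logistic fit of habitat-1 membership on the genetic
#' liability `a0 + ag*x`, the simulation analogue of the analytic
#' conditional habitat probabilities. Complete or quasi-complete separation
#' (liabilities of the two habitats non-overlapping, where the MLE
#' diverges) is detected and reported with a capped slope of magnitude 50,
#' the intercept placed to give probability one half at the separating
#' midpoint.
#'
#' @param liability numeric vector of liabilities.
#' @param habitat habitat labels (1/2) of the same length; both habitats
#'   must be represented.
#' @param at optional liabilities at which to return predicted
#'   probabilities of habitat 1.
#' @return List with `intercept`, `slope`, `separated` flag, standard
#'   errors (`NA` under separation), and `predicted` (when `at` is given).
#' @export
habitat_logistic_regression <- function(liability, habitat, at = NULL) {
  stopifnot(length(liability) == length(habitat),
            all(habitat %in% 1:2))
  y <- as.integer(habitat == 1L)
  if (length(unique(y)) < 2L)
    stop("both habitats must be represented", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ liability, family = stats::binomial()))
  co <- stats::coef(fit)
  separated <- !fit$converged || abs(co[2]) > 50 ||
    any(!is.finite(co))
  if (separated) {
    # capped-slope fallback at the midpoint between the class boundaries
    hi <- range(liability[y == 1]); lo <- range(liability[y == 0])
    mid <- if (min(hi) >= max(lo)) (min(hi) + max(lo)) / 2
           else (max(hi) + min(lo)) / 2
    slope <- unname(sign(co[2])) * 50
    if (!is.finite(slope) || slope == 0)
      slope <- if (mean(liability[y == 1]) >= mean(liability[y == 0])) 50 else -50
    intercept <- -slope * mid
    se <- c(NA_real_, NA_real_)
    warning("separation detected; slope capped at ±50", call. = FALSE)
  } else {
    intercept <- unname(co[1]); slope <- unname(co[2])
    se <- unname(sqrt(diag(stats::vcov(fit))))
  }
  out <- list(intercept = intercept, slope = slope, separated = separated,
              se = se)
  if (!is.null(at))
    out$predicted <- stats::plogis(intercept + slope * at)
  out
}

#' Rank runs by the information their genotypes carry about habitat
#'
#' Orders simulation end states by the mutual information between a
#' discretised genotype-derived liability and habitat. Liabilities are
#' binned into `bins` equal-width intervals over the pooled observed
#' range; replicate runs of the same condition provide the uncertainty.
#'
#' @param runs named list of `"cue_sim"` objects (each possibly with
#'   several replicates).
#' @param bins number of liability bins.
#' @return A data frame ordered by decreasing mean MI with columns
#'   `run`, `mi_mean`, `mi_sd`, `n_replicates`.
#' @export
information_ordering <- function(runs, bins = 20) {
  stopifnot(length(runs) >= 2)
  if (is.null(names(runs)) || any(names(runs) == ""))
    names(runs) <- paste0("run", seq_along(runs))
  per_run <- lapply(runs, function(sim) {
    stopifnot(inherits(sim, "cue_sim"))
    vapply(seq_along(sim$final), function(r) {
      fin <- sim$final[[r]]
      liab <- c(fin[[1]]$liability, fin[[2]]$liability)
      hab <- rep(1:2, times = c(length(fin[[1]]$liability),
                                length(fin[[2]]$liability)))
      liability_mi(liab, hab, bins)
    }, numeric(1))
  })
  out <- data.frame(
    run = names(runs),
    mi_mean = vapply(per_run, mean, numeric(1)),
    mi_sd = vapply(per_run, stats::sd, numeric(1)),
    n_replicates = vapply(per_run, length, numeric(1)))
  out[order(-out$mi_mean), , drop = FALSE]
}

# MI (bits) between a binned continuous variable and a 2-level label
liability_mi <- function(liab, habitat, bins = 20) {
  rng <- range(liab)
  if (diff(rng) == 0) return(0)
  cut_ <- cut(liab, breaks = seq(rng[1], rng[2], length.out = bins + 1),
              include.lowest = TRUE)
  tab <- table(habitat, cut_)
  p <- tab / sum(tab)
  pi_ <- rowSums(p); pk <- colSums(p)
  terms <- p * log2(p / outer(pi_, pk))
  sum(terms[p > 0])
}
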