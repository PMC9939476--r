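#' Simulation configuration for synthetic cohorts
#'
#' Describes the generative model the analysis assumes: final pathology is
#' Bernoulli with the given malignancy prevalence, the FNA category is drawn
#' from an outcome-conditional 6-level distribution, and the FS category
#' from a distribution conditional on outcome and (optionally) on the FNA
#' category. Optional covariates (age stratum, sex, diameter stratum,
#' bilaterality/multifocality among malignant cases) are drawn independently
#' given outcome.
#'
#' @param n cohort size.
#' @param prevalence P(final pathology = MALIGNANT).
#' @param fna_given_outcome 2x6 matrix of probabilities, rows `MALIGNANT`,
#'   `BENIGN`, columns in `fna_levels()` order; each row sums to 1.
#' @param fs_given_outcome either a 2x4 matrix (FS independent of FNA given
#'   outcome) or a 2x6x4 array (outcome x FNA x FS); probability vectors sum
#'   to 1 within 1e-9.
#' @param covariate_model optional list with per-outcome probabilities:
#'   `age_lt55`, `sex_f`, `diameter` (2x3 matrix over the <5 / 5-10 / >=10 mm
#'   strata), `bilateral`, `multifocal` (malignant cases only).
#' @param seed integer seed; the draw is fully reproducible.
#' @return An object of class `simulation_config`.
#' @seealso [default_simulation_config()] for the reference-cohort-derived
#'   defaults, [simulate_cohort()], [recover_parameters()].
#' @export
simulation_config <- function(n, prevalence, fna_given_outcome,
                              fs_given_outcome, covariate_model = NULL,
                              seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    fnafs_abort("n must be a positive integer", "fnafs_config_error")
  }
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    fnafs_abort("prevalence must lie in [0, 1]", "fnafs_config_error")
  }
  check_pvec <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      fnafs_abort(sprintf(
        "%s must be a nonnegative probability vector summing to 1", what),
        "fnafs_config_error")
    }
  }
  fna_given_outcome <- as.matrix(fna_given_outcome)
  stopifnot(dim(fna_given_outcome) == c(2L, 6L))
  dimnames(fna_given_outcome) <- list(outcome_levels(), fna_levels())
  for (o in outcome_levels()) check_pvec(fna_given_outcome[o, ],
                                         paste("fna |", o))
  if (length(dim(fs_given_outcome)) == 3L) {
    stopifnot(dim(fs_given_outcome) == c(2L, 6L, 4L))
    dimnames(fs_given_outcome) <- list(outcome_levels(), fna_levels(),
                                       fs_levels())
    for (o in outcome_levels()) for (f in fna_levels()) {
      check_pvec(fs_given_outcome[o, f, ], paste("fs |", o, f))
    }
  } else {
    fs_given_outcome <- as.matrix(fs_given_outcome)
    stopifnot(dim(fs_given_outcome) == c(2L, 4L))
    dimnames(fs_given_outcome) <- list(outcome_levels(), fs_levels())
    for (o in outcome_levels()) check_pvec(fs_given_outcome[o, ],
                                           paste("fs |", o))
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 fna_given_outcome = fna_given_outcome,
                 fs_given_outcome = fs_given_outcome,
                 covariate_model = covariate_model,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default simulation parameters
#'
#' The empirical (maximum-likelihood) parameters of the reconstructed
#' reference cohort: n = 3807, malignancy prevalence 3544/3807, and the
#' observed outcome-conditional FNA and (outcome, FNA)-conditional FS
#' frequencies, together with the observed covariate rates.
#'
#' @param n cohort size (default the reference size).
#' @param seed integer seed.
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(n = 3807L, seed = 1L) {
  est <- recover_parameters(reference_cohort())
  simulation_config(n = n, prevalence = est$prevalence,
                    fna_given_outcome = est$fna_given_outcome,
                    fs_given_outcome = est$fs_given_outcome,
                    covariate_model = est$covariate_model,
                    seed = seed)
}

#' Simulate a synthetic cohort
#'
#' Draws `n` independent records under a [simulation_config()]. Identical
#' seeds give identical cohorts.
#'
#' @param config a `simulation_config`.
#' @return A [cohort].
#' @examples
#' co <- simulate_cohort(default_simulation_config(n = 200, seed = 42))
#' table(co$fna_category, co$outcome)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  set.seed(config$seed)
  outcome <- ifelse(stats::runif(n) < config$prevalence,
                    "MALIGNANT", "BENIGN")
  fna <- character(n)
  for (o in outcome_levels()) {
    idx <- which(outcome == o)
    if (length(idx)) {
      fna[idx] <- sample(fna_levels(), length(idx), replace = TRUE,
                         prob = config$fna_given_outcome[o, ])
    }
  }
  fs <- character(n)
  if (length(dim(config$fs_given_outcome)) == 3L) {
    for (o in outcome_levels()) for (f in fna_levels()) {
      idx <- which(outcome == o & fna == f)
      if (length(idx)) {
        fs[idx] <- sample(fs_levels(), length(idx), replace = TRUE,
                          prob = config$fs_given_outcome[o, f, ])
      }
    }
  } else {
    for (o in outcome_levels()) {
      idx <- which(outcome == o)
      if (length(idx)) {
        fs[idx] <- sample(fs_levels(), length(idx), replace = TRUE,
                          prob = config$fs_given_outcome[o, ])
      }
    }
  }
  co <- cohort(fna_category = fna, fs_category = fs, outcome = outcome,
               patient_id = sprintf("S%06d", seq_len(n)),
               label = sprintf("simulated cohort (n=%d, seed=%d)",
                               n, config$seed))
  cm <- config$covariate_model
  if (!is.null(cm)) {
    age <- integer(n); sex <- character(n); diam <- numeric(n)
    bilat <- rep(NA, n); multi <- rep(NA, n)
    for (o in outcome_levels()) {
      idx <- which(outcome == o)
      if (!length(idx)) next
      lt55 <- stats::runif(length(idx)) < cm$age_lt55[[o]]
      age[idx] <- ifelse(lt55, sample(18:54, length(idx), replace = TRUE),
                         sample(55:85, length(idx), replace = TRUE))
      sex[idx] <- ifelse(stats::runif(length(idx)) < cm$sex_f[[o]], "F", "M")
      stratum <- sample(1:3, length(idx), replace = TRUE,
                        prob = cm$diameter[o, ])
      diam[idx] <- c(3, 7.5, 12)[stratum]
      if (o == "MALIGNANT") {
        bilat[idx] <- stats::runif(length(idx)) < cm$bilateral
        multi[idx] <- stats::runif(length(idx)) < cm$multifocal
      }
    }
    co$age_years <- age
    co$sex <- factor(sex, levels = c("F", "M"))
    co$diameter_mm <- diam
    co$bilateral <- as.logical(bilat)
    co$multifocal <- as.logical(multi)
  }
  co
}

#' Recover empirical simulation parameters from a cohort
#'
#' The closing half of the simulate-recover loop: empirical prevalence and
#' conditional category frequencies (and covariate rates, where the
#' covariates are present), in the same layout [simulation_config()]
#' expects.
#'
#' @param cohort a [cohort].
#' @return A list with `n`, `prevalence`, `fna_given_outcome` (2x6),
#'   `fs_given_outcome` (2x6x4 array; rows with no data get a uniform
#'   placeholder), and `covariate_model` when covariates are present.
#' @export
recover_parameters <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort)
  prevalence <- mean(cohort$outcome == "MALIGNANT")
  fna_p <- matrix(0, 2L, 6L, dimnames = list(outcome_levels(), fna_levels()))
  fs_p <- array(1 / 4, dim = c(2L, 6L, 4L),
                dimnames = list(outcome_levels(), fna_levels(), fs_levels()))
  for (o in outcome_levels()) {
    sel <- cohort$outcome == o
    if (any(sel)) {
      fna_p[o, ] <- as.numeric(table(cohort$fna_category[sel])) / sum(sel)
    }
    for (f in fna_levels()) {
      sub <- sel & cohort$fna_category == f
      if (any(sub)) {
        fs_p[o, f, ] <- as.numeric(table(cohort$fs_category[sub])) / sum(sub)
      }
    }
  }
  cm <- NULL
  if (!is.null(cohort$age_years) && !is.null(cohort$sex) &&
      !is.null(cohort$diameter_mm)) {
    mal <- cohort$outcome == "MALIGNANT"
    rate <- function(x, sel) mean(x[sel], na.rm = TRUE)
    diam <- matrix(0, 2L, 3L,
                   dimnames = list(outcome_levels(),
                                   c("lt5", "d5to10", "ge10")))
    for (o in outcome_levels()) {
      sel <- cohort$outcome == o
      d <- cohort$diameter_mm[sel]
      diam[o, ] <- c(mean(d < 5, na.rm = TRUE),
                     mean(d >= 5 & d < 10, na.rm = TRUE),
                     mean(d >= 10, na.rm = TRUE))
    }
    cm <- list(
      age_lt55 = c(MALIGNANT = rate(cohort$age_years < 55, mal),
                   BENIGN = rate(cohort$age_years < 55, !mal)),
      sex_f = c(MALIGNANT = rate(cohort$sex == "F", mal),
                BENIGN = rate(cohort$sex == "F", !mal)),
      diameter = diam,
      bilateral = if (is.null(cohort$bilateral)) NA else
        rate(cohort$bilateral, mal),
      multifocal = if (is.null(cohort$multifocal)) NA else
        rate(cohort$multifocal, mal))
  }
  list(n = n, prevalence = prevalence, fna_given_outcome = fna_p,
       fs_given_outcome = fs_p, covariate_model = cm)
}
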