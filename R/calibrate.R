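#' Expected sample CV of a lognormal population at a finite sample size
#'
#' The moment estimator of the coefficient of variation is biased downwards
#' for skewed distributions at small n — severely so for heavy-tailed
#' lognormals, where the expected sample CV at n of order 60 saturates near
#' sqrt(n) * 100 / something well below the population value. This helper
#' estimates E[sample CV at n] by Monte Carlo and is the workhorse of the
#' preset calibration (`inst/calibration/calibrate_presets.R`): population
#' CVs are chosen so that the expected sample CV at the study's sample size
#' reproduces the observed one.
#'
#' @param n sample size.
#' @param cv_pop population CV, percent.
#' @param reps Monte Carlo replicates.
#' @param seed integer seed.
#' @return expected sample CV, percent.
#' @export
expected_sample_cv <- function(n, cv_pop, reps = 20000, seed = 1) {
  with_seed(seed, {
    mean(replicate(reps, {
      x <- rlnorm_cv(n, 1, cv_pop)
      100 * sd(x) / mean(x)
    }))
  })
}

#' Calibrate a population CV to an observed sample CV
#'
#' Finds the population lognormal CV whose expected sample CV at size `n`
#' equals `target_percent`, by root-finding on [expected_sample_cv()].
#'
#' @param n sample size of the observed CV.
#' @param target_percent observed sample CV, percent.
#' @param reps Monte Carlo replicates per evaluation.
#' @param seed integer seed (fixed across evaluations so the objective is
#'   deterministic).
#' @return calibrated population CV, percent.
#' @export
calibrate_population_cv <- function(n, target_percent, reps = 20000,
                                    seed = 1) {
  f <- function(lc) expected_sample_cv(n, exp(lc), reps, seed) - target_percent
  exp(uniroot(f, log(c(target_percent * 0.5, 20000)), tol = 1e-3)$root)
}
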