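## Generator calibration: pins two emergent cohort statistics to their
## target values by iterating against brute-force simulation.
##
## The two knobs are the log-scale intron-CDS length correlation (for the
## natural-scale Pearson r, which is attenuated by the lognormal
## transformation and the class mixture) and the baseline substitution
## rate (for the cohort mean intron divergence, which is inflated by the
## lognormal rate heterogeneity and the CpG-site fraction). Neither has a
## clean closed form once class effects, CpG thinning and per-gene ratio
## estimation enter, hence simulation.

#' Calibrate the generator's emergent statistics
#'
#' Adjusts `length_model$log_length_correlation` until the simulated
#' natural-scale Pearson correlation between total intron and total CDS
#' length hits `target_r`, and `rate_model$baseline_rate` until the
#' simulated cohort mean per-gene intron divergence hits
#' `target_mean_divergence`. Length calibration uses a secant update on
#' length-only simulations; rate calibration uses multiplicative updates
#' on full sequence simulations.
#'
#' @param config starting [cohort_config()].
#' @param target_r target Pearson correlation (natural scale).
#' @param target_mean_divergence target cohort mean of per-gene `d_all`.
#' @param tolerance absolute tolerances, recycled to length 2 (r,
#'   divergence).
#' @param max_iter maximum iterations per knob.
#' @param n_sim genes per sequence simulation (larger = less Monte-Carlo
#'   noise in the calibration itself).
#' @param n_sim_lengths genes per length-only simulation; length draws are
#'   cheap, so a much larger n keeps the correlation knob from chasing
#'   sampling noise.
#' @param seed RNG seed for the calibration simulations.
#' @return the calibrated `dga_config`; errors with the last residuals on
#'   non-convergence.
#' @export
calibrate_generator <- function(config = paper_defaults(), target_r = 0.36,
                                target_mean_divergence = 0.0105,
                                tolerance = c(0.005, 1e-4), max_iter = 12L,
                                n_sim = 8000L, n_sim_lengths = 200000L,
                                seed = 20140227L) {
  config <- validate_config(config)
  tolerance <- rep_len(tolerance, 2L)
  set.seed(seed)

  ## common random numbers: r(rho) becomes a smooth deterministic function
  ## of rho, so the secant iteration converges instead of chasing noise
  cf <- config$class_fractions
  crn_classes <- sample(rep(.CLASS_LEVELS,
                            round(cf[.CLASS_LEVELS] * n_sim_lengths)))
  crn_z1 <- rnorm(length(crn_classes))
  crn_z2 <- rnorm(length(crn_classes))
  sim_r <- function(cfg) {
    lm_ <- cfg$length_model
    rho <- lm_$log_length_correlation
    Tlen <- exp(lm_$total_cds_meanlog +
                log(lm_$class_mult_total_cds[crn_classes]) +
                lm_$total_cds_sdlog * crn_z1)
    Ilen <- exp(lm_$intron_meanlog + log(lm_$class_mult_intron[crn_classes]) +
                lm_$intron_sdlog * (rho * crn_z1 + sqrt(1 - rho^2) * crn_z2))
    cor(pmax(round(Ilen), 100), 3 * pmax(3, round(Tlen / 3)))
  }
  sim_mean_div <- function(cfg) {
    cf <- cfg$class_fractions
    classes <- sample(rep(.CLASS_LEVELS, round(cf[.CLASS_LEVELS] * n_sim)))
    len <- sample_lengths(classes, cfg$length_model)
    cov <- sample_covariates(length(classes), cfg$covariate_model)
    rate <- cfg$rate_model$baseline_rate *
      exp(as.numeric(cov$z %*% cfg$rate_model$coefficients)) *
      cfg$rate_model$class_mult_divergence[classes]
    L <- pmax(as.integer(len$total_intron_length), 200L)
    d <- numeric(0)
    for (cs in seq(1L, length(L), by = .CHUNK_SIZE)) {
      ce <- min(cs + .CHUNK_SIZE - 1L, length(L))
      sim <- .sim_sequences(L[cs:ce], rate[cs:ce],
                            cfg$rate_model$cpg_multiplier, cfg$seq_model,
                            keep_codes = TRUE)
      diffs <- sim$human != sim$chimp
      cls <- .classify_chunk(sim$human, sim$gidx)
      ok <- !is.na(cls)
      nd <- tapply(diffs[ok], sim$gidx[ok], sum)
      ns <- tapply(ok, sim$gidx, sum)
      d <- c(d, as.numeric(nd) / as.numeric(ns))
    }
    mean(d)
  }

  ## knob 1: log-length correlation by secant iteration
  r_hat <- sim_r(config)
  if (abs(r_hat - target_r) > tolerance[1]) {
    rho0 <- config$length_model$log_length_correlation
    rho1 <- min(0.99, max(-0.99, rho0 * target_r / max(r_hat, 1e-6)))
    f0 <- r_hat - target_r
    for (it in seq_len(max_iter)) {
      config$length_model$log_length_correlation <- rho1
      f1 <- sim_r(config) - target_r
      if (abs(f1) <= tolerance[1]) break
      step <- if (abs(f1 - f0) > 1e-8) f1 * (rho1 - rho0) / (f1 - f0) else 0
      rho0 <- rho1; f0 <- f1
      rho1 <- min(0.99, max(-0.99, rho1 - step))
      if (it == max_iter)
        stop("length-correlation calibration did not converge; residual ",
             format(f1, digits = 3))
    }
  }

  ## knob 2: baseline rate by multiplicative update
  for (it in seq_len(max_iter)) {
    m_hat <- sim_mean_div(config)
    resid <- m_hat - target_mean_divergence
    if (abs(resid) <= tolerance[2]) break
    config$rate_model$baseline_rate <- config$rate_model$baseline_rate *
      target_mean_divergence / m_hat
    if (it == max_iter)
      stop("baseline-rate calibration did not converge; residual ",
           format(resid, digits = 3))
  }
  validate_config(config)
}
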