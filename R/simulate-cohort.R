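## Pearson correlation induced between expression = exp(mu + sx * Zx) and
## editing = qbeta(pnorm(Zy), shape1, shape2) when (Zx, Zy) are standard
## bivariate normal with latent correlation rho, evaluated by common-random-
## number Monte Carlo so it is smooth and monotone in rho.
inducedPearson <- function(rho, zx, w, mu, sx, shape1, shape2) {
  zy <- rho * zx + sqrt(1 - rho^2) * w
  cor(exp(mu + sx * zx), qbeta(pnorm(zy), shape1, shape2))
}

## latent rho achieving a target Pearson r under the marginal transforms;
## a property of the transforms alone, so it uses a fixed internal stream
## (independent of the user's seed) and is cached per parameter set
.rhoCache <- new.env(parent = emptyenv())
calibrateLatentRho <- function(targetR, mu, sx, shape1, shape2) {
  if (targetR == 0) return(0)
  key <- paste(targetR, mu, sx, shape1, shape2, sep = "|")
  if (!is.null(.rhoCache[[key]])) return(.rhoCache[[key]])
  rho <- withStreamSeed(20240601, 20L, {
    m <- 100000L
    zx <- rnorm(m); w <- rnorm(m)
    f <- function(rho) inducedPearson(rho, zx, w, mu, sx, shape1, shape2) - targetR
    uniroot(f, lower = -0.9999, upper = 0.9999, tol = 1e-6)$root
  })
  .rhoCache[[key]] <- rho
  rho
}

#' Simulate a cohort with correlated expression, editing and survival
#'
#' Expression is log-normal; the editing fraction is beta-distributed with
#' its latent Gaussian coupled to expression so the realized Pearson
#' correlation between the two observed variables targets `targetR` (the
#' latent correlation is calibrated deterministically under the marginal
#' transforms). Survival is exponential with hazard
#' `h0 * hazardRatioPerUnitScore^score`, where the score is the
#' expression/editing signature ([signatureScore()]) of the generated
#' cohort, with independent uniform censoring tuned to `censorFrac`.
#'
#' @param nPatients cohort size.
#' @param targetR target Pearson correlation in (-1, 1) (default 0.5).
#' @param hazardRatioPerUnitScore hazard ratio per unit signature score
#'   (default 2; 1 = no survival effect).
#' @param censorFrac expected censored fraction (default 0.3).
#' @param mu,sx log-mean and log-sd of expression (defaults 5, 0.4).
#' @param shape1,shape2 beta shapes of the editing fraction (defaults 2, 8).
#' @param baselineHazard exponential baseline hazard per day (default 1/365).
#' @param seed integer seed.
#' @return data.frame cohort with patient_id, adar1_expr, scd1_editing,
#'   survival_time (days), event (logical), signature_score, stratum.
#' @export
simulateCohort <- function(nPatients, targetR = 0.5,
                           hazardRatioPerUnitScore = 2, censorFrac = 0.3,
                           mu = 5, sx = 0.4, shape1 = 2, shape2 = 8,
                           baselineHazard = 1 / 365, seed = 1) {
  if (targetR <= -1 || targetR >= 1)
    stop("targetR must lie in (-1, 1)", call. = FALSE)
  if (censorFrac < 0 || censorFrac >= 1)
    stop("censorFrac must lie in [0, 1)", call. = FALSE)
  rho <- calibrateLatentRho(targetR, mu, sx, shape1, shape2)
  withStreamSeed(seed, 21L, {
    zx <- rnorm(nPatients)
    zy <- rho * zx + sqrt(1 - rho^2) * rnorm(nPatients)
    expr <- exp(mu + sx * zx)
    editing <- qbeta(pnorm(zy), shape1, shape2)
    cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(nPatients)),
                         adar1_expr = expr, scd1_editing = editing,
                         stringsAsFactors = FALSE)
    cohort <- signatureScore(cohort)
    hazard <- baselineHazard * hazardRatioPerUnitScore^cohort$signature_score
    death <- rexp(nPatients, rate = hazard)
    if (censorFrac > 0) {
      ## uniform censoring window scaled so the expected censored fraction
      ## approximates censorFrac at the baseline hazard
      cmax <- stats::qexp(0.99, baselineHazard) * (1 - censorFrac)
      cens <- runif(nPatients, 0, cmax)
    } else cens <- rep(Inf, nPatients)
    cohort$survival_time <- pmin(death, cens)
    cohort$event <- death <= cens
    cohort
  })
}

#' Simulate a limiting-dilution experiment under the single-hit model
#'
#' Responding wells are Binomial(tested, 1 - exp(-f * dose)) per dose row.
#' A frequency of exactly 0 is the valid all-negative boundary.
#'
#' @param trueFreq true initiating-cell fraction (>= 0).
#' @param doses vector of cells-per-well doses.
#' @param wellsPerDose tested wells at each dose (recycled).
#' @param seed integer seed.
#' @return data.frame with dose, tested, responding.
#' @export
simulateLda <- function(trueFreq, doses, wellsPerDose, seed = 1) {
  if (trueFreq < 0) stop("trueFreq must be non-negative", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  tested <- rep_len(wellsPerDose, length(doses))
  withStreamSeed(seed, 30L, {
    p <- -expm1(-trueFreq * doses)
    data.frame(dose = doses, tested = tested,
               responding = rbinom(length(doses), tested, p))
  })
}

#' Write a cohort table as TSV
#' @param cohort data.frame from [simulateCohort()] or [signatureScore()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCohortTsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort TSV (patient_id, adar1_expr, scd1_editing, ...)
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readCohortTsv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "adar1_expr", "scd1_editing")
  if (!all(need %in% names(d)))
    stop("cohort TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Read a limiting-dilution wells TSV (group, dose, tested, responding)
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readWellsTsv <- function(path) {
  if (!file.exists(path)) stop("wells file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("dose", "tested", "responding")
  if (!all(need %in% names(d)))
    stop("wells TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}
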