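## binomial log-likelihood of the single-hit model at log-frequency phi:
## P(well responds | dose d) = 1 - exp(-f d), f = exp(phi)
ldaLogLik <- function(phi, dose, tested, responding) {
  f <- exp(phi)
  p <- -expm1(-f * dose)              # 1 - exp(-f d), accurate for small f d
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  sum(responding * log(p) + (tested - responding) * (-f * dose))
}

validateLdaData <- function(data) {
  need <- c("dose", "tested", "responding")
  if (!all(need %in% names(data)))
    stop("limiting-dilution data needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(data)) stop("no dose rows", call. = FALSE)
  if (any(data$dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(data$responding < 0 | data$responding > data$tested))
    stop("0 <= responding <= tested violated", call. = FALSE)
  if (all(data$tested == 0)) stop("all doses have zero tested wells", call. = FALSE)
  data
}

#' Fit the single-hit limiting-dilution frequency
#'
#' Maximizes the binomial log-likelihood of the single-hit Poisson model
#' `P(responding | dose d) = 1 - exp(-f d)` over log frequency (the
#' complementary log-log scale on which the model is linear in log dose).
#' The 95\% confidence interval is Wald on log f, back-transformed. When
#' every well is negative (or every well positive) the estimate sits on the
#' boundary and the one-sided bound is taken from the profile likelihood at
#' a drop of qchisq(0.95, 1)/2.
#'
#' @param data data.frame with columns dose (cells per well), tested
#'   (well count), responding (positive wells). One row per dose.
#' @return an [LDAResult-class].
#' @export
fitFrequency <- function(data) {
  data <- validateLdaData(data)
  d <- data$dose; n <- data$tested; r <- data$responding
  totalPos <- sum(r); totalWells <- sum(n)
  drop95 <- qchisq(0.95, 1) / 2

  if (totalPos == 0) {
    ## loglik(f) = -f * sum(n d): monotone decreasing; upper bound where the
    ## drop from the supremum (at f -> 0) reaches drop95
    upper <- drop95 / sum(n * d)
    return(new("LDAResult", freq = 0, ciLower = 0, ciUpper = upper,
               logLik = 0, boundary = "all_negative", data = data))
  }
  if (totalPos == totalWells) {
    ## loglik increasing in f with supremum 0; lower bound from the profile
    ll <- function(f) sum(r * log(pmax(-expm1(-f * d), 1e-300)))
    lo <- uniroot(function(f) ll(f) + drop95,
                  lower = 1e-12 / max(d), upper = 1e6 / min(d),
                  tol = 1e-14, extendInt = "upX")$root
    return(new("LDAResult", freq = Inf, ciLower = lo, ciUpper = Inf,
               logLik = 0, boundary = "all_positive", data = data))
  }

  interval <- c(log(1e-9 / max(d)), log(100 / min(d)))
  opt <- optimize(function(phi) ldaLogLik(phi, d, n, r),
                  interval = interval, maximum = TRUE, tol = 1e-10)
  phi <- opt$maximum
  ## observed information via central second difference on phi
  h <- 1e-4
  ll0 <- opt$objective
  info <- -(ldaLogLik(phi + h, d, n, r) - 2 * ll0 +
            ldaLogLik(phi - h, d, n, r)) / h^2
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  zc <- qnorm(0.975)
  new("LDAResult", freq = exp(phi),
      ciLower = if (is.na(se)) NA_real_ else exp(phi - zc * se),
      ciUpper = if (is.na(se)) NA_real_ else exp(phi + zc * se),
      logLik = ll0, boundary = "none", data = data)
}

#' Likelihood-ratio comparison of two limiting-dilution frequencies
#'
#' Fits each group separately and jointly (shared frequency) and forms the
#' likelihood-ratio statistic `2 * [loglik(separate) - loglik(shared)]`.
#' The two-sided p-value is the upper chi-square(1) tail; the one-sided
#' p-value is half the tail when the observed direction of
#' `log f_a - log f_b` matches the stated alternative, else one minus the
#' half tail.
#'
#' @param a,b data.frames of dose/tested/responding for the two groups.
#' @param alternative "two_sided" (default), "a_greater" or "b_greater".
#' @return list with `statistic`, `p`, and the two fitted frequencies.
#' @export
compareFrequencies <- function(a, b,
                               alternative = c("two_sided", "a_greater",
                                               "b_greater")) {
  alternative <- match.arg(alternative)
  fa <- fitFrequency(a); fb <- fitFrequency(b)
  if (fa@boundary == "all_negative" && fb@boundary == "all_negative")
    stop("both groups are all-negative; frequency comparison undefined",
         call. = FALSE)
  pooled <- fitFrequency(rbind(validateLdaData(a)[c("dose", "tested", "responding")],
                               validateLdaData(b)[c("dose", "tested", "responding")]))
  statistic <- max(0, 2 * (fa@logLik + fb@logLik - pooled@logLik))
  pTwo <- pchisq(statistic, df = 1, lower.tail = FALSE)
  if (alternative == "two_sided") {
    p <- pTwo
  } else {
    half <- pTwo / 2
    dirA <- fa@freq > fb@freq
    matches <- (alternative == "a_greater" && dirA) ||
               (alternative == "b_greater" && !dirA)
    p <- if (fa@freq == fb@freq) 0.5 else if (matches) half else 1 - half
  }
  list(statistic = statistic, p = p, freqA = fa@freq, freqB = fb@freq)
}
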