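#' Immunoreactive score (IRS)
#'
#' `IRS = intensity x percentage category`, where intensity grades staining
#' 0 (negative) to 3 (strong) and the positive-cell percentage is binned as
#' 0 for 0%, 1 for (0,10]%, 2 for (10,50]%, 3 for (50,80]% and 4 for >80%.
#'
#' @param intensity integer 0-3.
#' @param pctPositive percentage of positively stained cells, 0-100.
#' @return integer IRS in 0-12 (vectorized).
#' @export
irs <- function(intensity, pctPositive) {
  if (any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3))
    stop("intensity must be an integer in 0-3", call. = FALSE)
  if (any(pctPositive < 0 | pctPositive > 100))
    stop("pctPositive must lie in [0, 100]", call. = FALSE)
  bin <- findInterval(pctPositive, c(0, 10, 50, 80), left.open = TRUE)
  as.integer(intensity) * bin
}

#' Two-marker quartile stratification of IRS scores
#'
#' Per marker, patients at or above the 75th percentile (nearest-rank) are
#' "high" and at or below the 25th percentile are "low"; ties at a cutoff
#' fall in the extreme group. The joint label is `HIGH_HIGH` (high for
#' both), `LOW_LOW` (low for both), else `OTHER`.
#'
#' @param scores data.frame with two numeric columns, one IRS vector per
#'   marker (e.g. adar1, scd1); n >= 4.
#' @return character vector of joint labels.
#' @export
stratifyIrs <- function(scores) {
  if (ncol(scores) != 2L) stop("scores must have exactly two marker columns",
                               call. = FALSE)
  if (nrow(scores) < 4L) stop("quartile stratification needs n >= 4", call. = FALSE)
  lab <- function(v) {
    hi <- quantile(v, 0.75, type = 1)   # nearest-rank
    lo <- quantile(v, 0.25, type = 1)
    ifelse(v >= hi, "high", ifelse(v <= lo, "low", "mid"))
  }
  a <- lab(scores[[1]]); b <- lab(scores[[2]])
  ifelse(a == "high" & b == "high", "HIGH_HIGH",
         ifelse(a == "low" & b == "low", "LOW_LOW", "OTHER"))
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,sample - Ct_ref,sample) - (Ct_target,control - Ct_ref,control)]`.
#'
#' @param ctTargetSample,ctRefSample Ct of target and reference gene in the
#'   sample of interest.
#' @param ctTargetControl,ctRefControl Ct of target and reference gene in
#'   the calibrator/control.
#' @return relative expression (1 when sample and control delta-Ct agree).
#' @export
ddct <- function(ctTargetSample, ctRefSample, ctTargetControl, ctRefControl) {
  2^(-((ctTargetSample - ctRefSample) - (ctTargetControl - ctRefControl)))
}

#' Xenograft tumor volume from caliper diameters
#'
#' `volume = 0.5 * L * W^2` with L and W the largest and smallest diameters
#' in mm.
#'
#' @param L largest diameter (mm).
#' @param W smallest diameter (mm); requires 0 < W <= L.
#' @return volume in mm^3 (vectorized).
#' @export
tumorVolume <- function(L, W) {
  if (any(W <= 0)) stop("W must be positive", call. = FALSE)
  if (any(W > L)) stop("W must not exceed L (largest vs smallest diameter)",
                       call. = FALSE)
  0.5 * L * W^2
}

#' Windowed correlation of copy-number log R ratios between paired samples
#'
#' Pearson correlation of per-marker LRR values within each window of SNP
#' markers; windows with fewer than 3 markers are reported as undefined
#' (`NA` with a reason), never NaN-propagated.
#'
#' @param lrrA,lrrB numeric per-marker LRR vectors for the paired samples,
#'   aligned marker-for-marker.
#' @param window window assignment (factor/character/integer per marker).
#' @return list with `windows` (data.frame window, n_markers, r) and
#'   `summary` (mean r over defined windows, count defined/undefined).
#' @export
lrrWindowCorrelation <- function(lrrA, lrrB, window) {
  if (length(lrrA) != length(lrrB) || length(lrrA) != length(window))
    stop("lrrA, lrrB and window must align marker-for-marker", call. = FALSE)
  sp <- split(seq_along(window), window)
  r <- vapply(sp, function(i) {
    if (length(i) < 3L) return(NA_real_)
    suppressWarnings(cor(lrrA[i], lrrB[i]))
  }, 0)
  win <- data.frame(window = names(sp), n_markers = lengths(sp), r = r,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(windows = win,
       summary = list(mean_r = mean(r, na.rm = TRUE),
                      n_defined = sum(!is.na(r)),
                      n_undefined = sum(is.na(r))))
}

#' Linear fit of RNA percent remaining against time
#'
#' Ordinary least squares of percent remaining (normalized to 100 at time
#' 0) on time after transcription arrest.
#'
#' @param timepoints hours after treatment (must include 0; >= 2 distinct).
#' @param remaining percent remaining at each timepoint.
#' @return list with `slope` (percent per hour), `intercept`, and the `lm`
#'   fit.
#' @export
stabilityFit <- function(timepoints, remaining) {
  if (length(unique(timepoints)) < 2L)
    stop("need at least two distinct timepoints", call. = FALSE)
  if (!any(timepoints == 0))
    stop("time 0 must be present (percent remaining is relative to 0 h)",
         call. = FALSE)
  fit <- lm(remaining ~ timepoints)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit = fit)
}
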