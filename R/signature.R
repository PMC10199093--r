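#' Standardize a vector to z-scores
#'
#' Centered to mean 0 and scaled to unit sample standard deviation
#' (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return numeric vector of z-scores.
#' @export
zScore <- function(values) {
  if (length(values) < 2L)
    stop("z-score needs at least two values", call. = FALSE)
  if (anyNA(values)) stop("z-score input contains NA", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("z-score undefined for a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Expression/editing signature scores and survival strata
#'
#' The signature score is the average of the z-score of ADAR1 mRNA
#' expression and the z-score of SCD1 editing level across the cohort:
#' `score = (z_expr + z_edit) / 2`. Strata follow the sign of the score:
#' `HIGH` for score > 0, `LOW` for score < 0, `EXCLUDED` for exactly 0.
#' Patients missing either component are excluded (with a message) before
#' z-scoring.
#'
#' @param cohort data.frame with columns patient_id, adar1_expr,
#'   scd1_editing (editing fractions in [0,1]) and optionally survival
#'   columns, carried through.
#' @return the cohort with `signature_score` and `stratum` columns added
#'   (excluded patients keep `NA` score and stratum "EXCLUDED").
#' @export
signatureScore <- function(cohort) {
  need <- c("patient_id", "adar1_expr", "scd1_editing")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.na(cohort$scd1_editing) &
          (cohort$scd1_editing < 0 | cohort$scd1_editing > 1)))
    stop("scd1_editing must be an editing fraction in [0,1]", call. = FALSE)
  ok <- !is.na(cohort$adar1_expr) & !is.na(cohort$scd1_editing)
  if (any(!ok))
    message(sum(!ok), " patient(s) missing a signature component; excluded")
  score <- rep(NA_real_, nrow(cohort))
  score[ok] <- (zScore(cohort$adar1_expr[ok]) +
                zScore(cohort$scd1_editing[ok])) / 2
  stratum <- rep("EXCLUDED", nrow(cohort))
  stratum[!is.na(score) & score > 0] <- "HIGH"
  stratum[!is.na(score) & score < 0] <- "LOW"
  cohort$signature_score <- score
  cohort$stratum <- stratum
  cohort
}

#' Pearson correlation of expression with editing level
#'
#' Two-tailed Pearson correlation between ADAR1 mRNA expression and SCD1
#' editing level across a cohort.
#'
#' @param cohort data.frame with columns adar1_expr, scd1_editing.
#' @return list with `r` (Pearson coefficient) and `p` (two-tailed p-value).
#' @export
correlateExprEditing <- function(cohort) {
  ok <- !is.na(cohort$adar1_expr) & !is.na(cohort$scd1_editing)
  if (sum(ok) < 3L)
    stop("Pearson correlation needs at least 3 complete pairs", call. = FALSE)
  ct <- cor.test(cohort$adar1_expr[ok], cohort$scd1_editing[ok],
                 method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
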