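#' Agreement statistics between two LAI series
#'
#' Quantifies how well an estimated LAI series reproduces a reference
#' series (typically: indirect estimates vs destructive measurements, or
#' LAI vs the theoretical-leaf-number vigor index) with the standard
#' agronomic model-evaluation metrics:
#' \itemize{
#'   \item RRMSE, percent: `100 * sqrt(mean((est - obs)^2)) / mean(obs)`;
#'     0 to +Inf, optimum 0.
#'   \item MAE: `mean(|est - obs|)`; same units as the series, optimum 0.
#'   \item EF (modelling efficiency):
#'     `1 - sum((est - obs)^2) / sum((obs - mean(obs))^2)`; -Inf to 1,
#'     optimum 1; negative means the reference mean outpredicts the method.
#'   \item CRM (coefficient of residual mass):
#'     `(sum(obs) - sum(est)) / sum(obs)`; optimum 0, positive means the
#'     method underestimates the reference, negative overestimation.
#' }
#' plus the squared Pearson correlation and the ordinary least squares
#' regression of `est` on `obs` (free intercept). R^2 is the squared
#' correlation, not the regression's; significance is a two-sided t-test
#' on the correlation, reported as a flag at `alpha`.
#'
#' @param obs reference values (destructive LAIv or TL).
#' @param est estimated values, same length (>= 2).
#' @param alpha significance level for the correlation flag
#'   (default 0.001).
#' @return An object of class `lai_agreement` with fields `n`, `rrmse`,
#'   `mae`, `ef`, `crm`, `r2`, `slope`, `intercept`, `p_value` and
#'   `significant`.
#' @export
agreement_metrics <- function(obs, est, alpha = 0.001) {
  if (length(obs) != length(est))
    vinelai_input_error("'obs' and 'est' must have equal length")
  n <- length(obs)
  if (n < 2L)
    vinelai_input_error("at least two paired values are required")
  if (anyNA(obs) || anyNA(est) || any(!is.finite(c(obs, est))))
    vinelai_input_error("series must be finite and complete")
  mobs <- mean(obs)
  if (abs(mobs) < .Machine$double.eps)
    vinelai_input_error("mean of 'obs' is zero: RRMSE and CRM are undefined")
  ss_obs <- sum((obs - mobs)^2)
  if (ss_obs < .Machine$double.eps)
    vinelai_input_error("'obs' has zero variance: EF and R^2 are undefined")

  resid <- est - obs
  rrmse <- 100 * sqrt(mean(resid^2)) / mobs
  mae <- mean(abs(resid))
  ef <- 1 - sum(resid^2) / ss_obs
  crm <- (sum(obs) - sum(est)) / sum(obs)

  if (sd(est) < .Machine$double.eps) {
    r2 <- 0; p <- 1                              # constant estimate: no association
  } else {
    ct <- cor.test(obs, est, alternative = "two.sided")
    r2 <- unname(ct$estimate)^2
    p <- ct$p.value
  }
  fit <- lm(est ~ obs)

  structure(
    list(n = n, rrmse = rrmse, mae = mae, ef = ef, crm = crm, r2 = r2,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         p_value = p, significant = p < alpha, alpha = alpha),
    class = "lai_agreement"
  )
}

#' @export
print.lai_agreement <- function(x, digits = 4, ...) {
  cat(sprintf("<lai_agreement> n = %d\n", x$n))
  cat(sprintf("  RRMSE = %.*f %%   MAE = %.*f\n",
              2, x$rrmse, digits, x$mae))
  cat(sprintf("  EF    = %.*f     CRM = %.*f\n", digits, x$ef, digits, x$crm))
  cat(sprintf("  R^2   = %.*f%s   est = %.*f * obs + %.*f\n",
              digits, x$r2, if (x$significant) " *" else "  ",
              digits, x$slope, digits, x$intercept))
  if (x$significant)
    cat(sprintf("  * p < %g\n", x$alpha))
  invisible(x)
}

#' @export
as.data.frame.lai_agreement <- function(x, ...) {
  data.frame(n = x$n, rrmse = x$rrmse, mae = x$mae, ef = x$ef, crm = x$crm,
             r2 = x$r2, slope = x$slope, intercept = x$intercept,
             p_value = x$p_value, significant = x$significant)
}

#' Exclude a point from a paired series
#'
#' Removes one pair by explicit index - the in-field practice of setting
#' aside a known anomalous sampling area (e.g. an unpruned, unusually
#' dense canopy) and re-running the agreement analysis. Detection is never
#' automatic: the caller states which point goes.
#'
#' @param obs,est the paired series (length >= 3).
#' @param index 1-based position of the pair to remove.
#' @return A list with the reduced `obs` and `est` and a `removed` record
#'   (`index`, `obs`, `est`).
#' @export
exclude_outlier <- function(obs, est, index) {
  if (length(obs) != length(est))
    vinelai_input_error("'obs' and 'est' must have equal length")
  if (length(obs) < 3L)
    vinelai_input_error("need at least 3 pairs so that 2 remain")
  if (length(index) != 1L || index < 1L || index > length(obs))
    vinelai_input_error("'index' out of range")
  list(obs = obs[-index], est = est[-index],
       removed = list(index = index, obs = obs[index], est = est[index]))
}
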