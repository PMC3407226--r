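#' Reporting surfaces: percent change in rate and spatial classification
#'
#' Translates a fitted model into the conventional epidemiological
#' summaries: percent change in relative rate for each day-of-week and
#' dust-storm-lag indicator (with 95% Wald intervals on the log scale,
#' then transformed), and the three-way classification of district
#' spatial effects by 80% posterior probability relative to a relative
#' rate of 1.
#'
#' @name inference_report
#' @keywords internal
NULL

#' Percent change in rate for a log-link coefficient
#'
#' `100 * (exp(coef) - 1)` with the 95% interval
#' `100 * (exp(coef +/- 1.96 se) - 1)` and a two-sided normal p-value.
#'
#' @param coef log-rate coefficient(s)
#' @param se standard error(s), `>= 0`
#' @return data frame `percent, lo, hi, p`
#' @export
percent_change <- function(coef, se) {
  if (any(se < 0)) stop("standard errors must be nonnegative")
  z <- ifelse(se > 0, coef / se, ifelse(coef == 0, 0, Inf * sign(coef)))
  data.frame(percent = 100 * (exp(coef) - 1),
             lo = 100 * (exp(coef - 1.96 * se) - 1),
             hi = 100 * (exp(coef + 1.96 * se) - 1),
             p = 2 * stats::pnorm(-abs(z)))
}

#' Effect report for the day-of-week and dust-storm-lag dummies
#'
#' @param fit a `star_fit`
#' @return data frame `block, term, percent, lo, hi, p` with one row per
#'   DOW and DSLI dummy (the intercept is omitted)
#' @export
effect_report <- function(fit) {
  fx <- fixed_effects(fit)
  fx <- fx[fx$term != "(Intercept)", ]
  pc <- percent_change(fx$estimate, fx$se)
  data.frame(block = ifelse(grepl("^lag", fx$term), "DSLI", "DOW"),
             term = fx$term, pc, row.names = NULL)
}

#' Classify district spatial effects by posterior probability
#'
#' For each district the marginal posterior of its spatial effect is the
#' normal `N(effect, se^2)`; with `p_above = P(effect > 0)` (equivalently
#' `P(RR > 1)`), a district is `positive` when `p_above >= threshold`,
#' `negative` when `1 - p_above >= threshold`, else `nonsignificant`.
#'
#' @param fit a `star_fit`
#' @param threshold posterior-probability cutoff in (0.5, 1); default 0.8
#' @return data frame `district, effect, rr, se, p_above_1, class`
#' @export
classify_spatial <- function(fit, threshold = 0.8) {
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie strictly between 0.5 and 1")
  sp <- spatial_effects(fit)
  p_above <- ifelse(sp$se > 0,
                    stats::pnorm(sp$effect / sp$se),
                    as.numeric(sp$effect > 0) + 0.5 * (sp$effect == 0))
  cls <- ifelse(p_above >= threshold, "positive",
                ifelse(1 - p_above >= threshold, "negative", "nonsignificant"))
  data.frame(district = sp$district, effect = sp$effect,
             rr = exp(sp$effect), se = sp$se,
             p_above_1 = p_above, class = cls, row.names = NULL)
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Write the report tables of a fit
#'
#' Writes `effects_<group>.csv` (percent change, 95% CI and p-value per
#' DOW/DSLI dummy, with explicit "Reference level" rows for Sunday and
#' the other days), `spatial_<group>.csv` (district effects, RR,
#' posterior probability above 1, class), and `summary_<group>.txt`.
#' Numbers in the effects table are formatted to 2 decimals; output is
#' byte-identical across runs on the same fit.
#'
#' @param fit a `star_fit`
#' @param dir output directory (created if needed)
#' @param threshold posterior-probability cutoff for the classification
#' @return named character vector of the files written, invisibly
#' @export
report_tables <- function(fit, dir, threshold = 0.8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grp <- if (is.null(fit$age_group)) "fit" else fit$age_group

  er <- effect_report(fit)
  eff <- data.frame(block = er$block, term = er$term,
                    percent = fmt2(er$percent),
                    lo = fmt2(er$lo), hi = fmt2(er$hi),
                    p = format.pval(er$p, digits = 3, eps = 1e-4))
  ref <- data.frame(block = c("DOW", "DSLI"),
                    term = c("Sunday", "The other days"),
                    percent = "Reference level", lo = "", hi = "", p = "")
  dow <- eff[eff$block == "DOW", ]
  dsli <- eff[eff$block == "DSLI", ]
  eff_out <- rbind(dow, ref[1, ], dsli, ref[2, ])
  f_eff <- file.path(dir, paste0("effects_", grp, ".csv"))
  utils::write.csv(eff_out, f_eff, row.names = FALSE)

  sp <- classify_spatial(fit, threshold)
  sp_out <- data.frame(district = sp$district,
                       effect = fmt2(sp$effect), rr = fmt2(sp$rr),
                       p_above_1 = sprintf("%.4f", sp$p_above_1),
                       class = sp$class)
  f_sp <- file.path(dir, paste0("spatial_", grp, ".csv"))
  utils::write.csv(sp_out, f_sp, row.names = FALSE)

  f_txt <- file.path(dir, paste0("summary_", grp, ".txt"))
  con <- file(f_txt, "w")
  writeLines(c(
    sprintf("Age group: %s", grp),
    sprintf("Observations: %d   total edf: %.2f   overdispersion phi: %.4f",
            length(fit$y), fit$edf_total, fit$phi),
    sprintf("Smoothing variances tau^2: %s",
            paste(sprintf("%s = %.4g", names(fit$tau2), fit$tau2), collapse = ", ")),
    "",
    "Percent change in rate (vs reference):",
    sprintf("  %-12s %8s  [%s, %s]", er$term, fmt2(er$percent), fmt2(er$lo), fmt2(er$hi)),
    "",
    sprintf("Spatial classification (threshold %.2f):", threshold),
    sprintf("  %-12s effect %6s  RR %5s  P(RR>1) %6s  %s",
            sp$district, fmt2(sp$effect), fmt2(sp$rr),
            sprintf("%.4f", sp$p_above_1), sp$class)
  ), con)
  close(con)

  invisible(c(effects = f_eff, spatial = f_sp, summary = f_txt))
}
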