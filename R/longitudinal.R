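# Longitudinal inference: random-intercept mixed models of log10
# responses against age and sex, slope conversion to percent change per
# year, replicate-based SD of richness estimates, and per-donor change
# classification.

#' Fit the longitudinal mixed model for one response
#'
#' Random-intercept linear mixed model of the (optionally log10) response
#' on age and sex, with donor as the random intercept
#' (`nlme::lme(y ~ age + sex, random = ~ 1 | donor)`). The age slope on
#' the log10 scale (`S_old`) is converted to percent change per year
#' (`S_new`); the p-value is the Wald test on the age coefficient. When
#' the mixed fit fails (e.g. a singular fit on noise-free data) the
#' function falls back to ordinary least squares with a warning.
#'
#' @param data Long-format data with columns `donor`, `age`, `sex`, and
#'   the response.
#' @param response Name of the response column.
#' @param log10_transform Model `log10(response)` (the scale used for
#'   richness and cell counts)? Requires positive responses.
#' @return An object of class `slope_result`: list with `response`,
#'   `s_old` (per-year slope on the model scale), `s_new` (percent per
#'   year; equals `s_old` untransformed when `log10_transform = FALSE`),
#'   `se`, `ci` (95% on the `s_new` scale), `p_value`, `n_donors`, `n_obs`,
#'   `model` (`"mixed"` or `"linear"`).
#' @export
fit_mixed_model <- function(data, response, log10_transform = TRUE) {
  stopifnot(all(c("donor", "age", response) %in% names(data)))
  df <- data.frame(
    donor = factor(data$donor),
    age = data$age,
    sex = if ("sex" %in% names(data)) factor(data$sex) else factor("unknown"),
    y = data[[response]]
  )
  df <- df[stats::complete.cases(df), ]
  if (log10_transform) {
    if (any(df$y <= 0)) {
      stop("log10 transform requires positive responses", call. = FALSE)
    }
    df$y <- log10(df$y)
  }
  use_sex <- nlevels(droplevels(df$sex)) > 1
  fixed <- if (use_sex) y ~ age + sex else y ~ age
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | donor, data = df),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("mixed model failed (", conditionMessage(fit),
            "); falling back to ordinary regression", call. = FALSE)
    lfit <- stats::lm(fixed, data = df)
    co <- summary(lfit)$coefficients
    s_old <- co["age", "Estimate"]
    se <- co["age", "Std. Error"]
    p <- co["age", "Pr(>|t|)"]
    model <- "linear"
  } else {
    tt <- summary(fit)$tTable
    s_old <- tt["age", "Value"]
    se <- tt["age", "Std.Error"]
    p <- tt["age", "p-value"]
    model <- "mixed"
  }
  ci_old <- s_old + c(-1, 1) * stats::qnorm(0.975) * se
  s_new <- if (log10_transform) slope_to_percent(s_old) else s_old
  ci_new <- if (log10_transform) slope_to_percent(ci_old) else ci_old
  structure(
    list(response = response, s_old = s_old, s_new = s_new, se = se,
         ci = ci_new, p_value = p, n_donors = nlevels(df$donor),
         n_obs = nrow(df), model = model,
         log10_transform = log10_transform),
    class = "slope_result"
  )
}

#' @export
print.slope_result <- function(x, ...) {
  cat("Age slope for '", x$response, "' (", x$model, " model, ",
      x$n_donors, " donors, ", x$n_obs, " obs)\n", sep = "")
  if (x$log10_transform) {
    cat(sprintf("  S_old = %.5f log10 units/year\n", x$s_old))
    cat(sprintf("  S_new = %.3f %%/year  [95%% CI %.3f, %.3f]\n",
                x$s_new, x$ci[1], x$ci[2]))
  } else {
    cat(sprintf("  slope = %.5f per year  [95%% CI %.3f, %.3f]\n",
                x$s_new, x$ci[1], x$ci[2]))
  }
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Convert a log10-scale slope to percent change per year
#'
#' `S_new = (10^S_old - 1) x 100`. [percent_to_slope()] is the exact
#' inverse, `log10(1 + S_new / 100)`.
#'
#' @param s_old Slope on the log10 scale (per year).
#' @return Percent change of the raw response per year.
#' @examples
#' slope_to_percent(-0.01)  # -2.2763
#' percent_to_slope(slope_to_percent(-0.01))
#' @export
slope_to_percent <- function(s_old) {
  (10^s_old - 1) * 100
}

#' @rdname slope_to_percent
#' @param s_new Percent change per year.
#' @export
percent_to_slope <- function(s_new) {
  log10(1 + s_new / 100)
}

#' Replicate SD of richness estimates
#'
#' Sample standard deviation of replicate richness estimates measured on
#' aliquots collected at the same time; the technical yardstick against
#' which longitudinal changes are judged. Computed on the log10 scale by
#' default, consistent with the log10 analysis of richness.
#'
#' @param estimates Numeric vector of replicate estimates (>= 2), or a
#'   data frame with columns `cell_type` and `estimate` for per-type SDs.
#' @param log10_transform Compute the SD of log10 estimates?
#' @return A single SD, or a tibble with one SD per cell type.
#' @export
replicate_sd <- function(estimates, log10_transform = TRUE) {
  if (is.data.frame(estimates)) {
    stopifnot(all(c("cell_type", "estimate") %in% names(estimates)))
    return(
      estimates |>
        dplyr::group_by(.data$cell_type) |>
        dplyr::summarise(
          n_replicates = dplyr::n(),
          sd = replicate_sd(.data$estimate, log10_transform = log10_transform),
          .groups = "drop"
        )
    )
  }
  if (length(estimates) < 2) {
    stop("replicate SD needs at least 2 replicates", call. = FALSE)
  }
  x <- if (log10_transform) log10(estimates) else estimates
  stats::sd(x)
}

#' Classify a per-donor longitudinal change against the replicate SD
#'
#' An age-associated change is called only when it exceeds one replicate
#' SD (strictly): `decreased` if `v2 < v1 - sd`, `increased` if
#' `v2 > v1 + sd`, otherwise `no_change`. Applied on the log10 scale by
#' default.
#'
#' @param visit1,visit2 Richness estimates at the two visits (vectorized).
#' @param sd Replicate SD for the matching cell type (on the comparison
#'   scale; must be >= 0).
#' @param log10_transform Compare on the log10 scale?
#' @return A factor with levels `decreased`, `no_change`, `increased`.
#' @export
classify_change <- function(visit1, visit2, sd, log10_transform = TRUE) {
  if (any(sd < 0)) {
    stop("sd must be non-negative", call. = FALSE)
  }
  if (log10_transform) {
    visit1 <- log10(visit1)
    visit2 <- log10(visit2)
  }
  out <- ifelse(visit2 < visit1 - sd, "decreased",
                ifelse(visit2 > visit1 + sd, "increased", "no_change"))
  factor(out, levels = c("decreased", "no_change", "increased"))
}
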