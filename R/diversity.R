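# Richness extrapolation by multi-model rarefaction-curve fitting and
# clonality by the Inverse Simpson's Index.
#
# The estimator follows the rarefaction-extrapolation recipe: build a
# rarefaction curve (and a second curve spanning half the depth), fit an
# ensemble of saturating models to the full curve by least squares, score
# each model by its fit error plus its ability to extrapolate the
# half-depth curve out to full depth plus penalties for implausible
# behavior (non-monotone, accelerating, or below the observed count), and
# report the geometric mean of the 3-5 lowest-scoring models' predictions
# at the target population size.

#' Rarefaction curve of a clonotype table
#'
#' Mean number of unique clonotypes observed in random subsamples (without
#' replacement) of the UMI pool, at each requested subsample size.
#'
#' @param table A `clonotype_table`, or a numeric vector of clonotype UMI
#'   counts.
#' @param sizes Subsample sizes; defaults to `nrf` evenly spaced sizes
#'   from 1 to the total UMI count. All sizes must be within
#'   `[1, total_umi]`.
#' @param n_resamples Number of random subsamples averaged per size.
#' @param nrf Rarefaction length used when `sizes` is NULL.
#' @param seed Optional seed.
#' @return A tibble of class `rarefaction_curve` with columns `size` and
#'   `unique`, and attributes `n_resamples`, `total_umi`,
#'   `observed_unique`.
#' @examples
#' rarefy(c(A = 2, B = 1), sizes = 1:3, n_resamples = 200, seed = 1)
#' @export
rarefy <- function(table, sizes = NULL, n_resamples = 1000L, nrf = 2000L,
                   seed = NULL) {
  counts <- if (is.numeric(table)) table else table$duplicate_count
  stopifnot(all(counts >= 1))
  n_total <- sum(counts)
  if (is.null(sizes)) {
    sizes <- unique(pmax(1, round(seq(1, n_total, length.out = min(nrf, n_total)))))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > n_total)) {
    stop("subsample sizes must lie in [1, total UMI count]", call. = FALSE)
  }
  pop <- rep.int(seq_along(counts), counts)
  acc <- numeric(length(sizes))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      perm <- sample(pop)
      cum_unique <- cumsum(!duplicated(perm))
      acc <- acc + cum_unique[sizes]
    }
  })
  curve <- tibble::tibble(size = sizes, unique = acc / n_resamples)
  attr(curve, "n_resamples") <- n_resamples
  attr(curve, "total_umi") <- n_total
  attr(curve, "observed_unique") <- length(counts)
  class(curve) <- unique(c("rarefaction_curve", class(curve)))
  curve
}

#' Registry of saturating rarefaction models
#'
#' Eight named saturating forms fitted to rarefaction curves. Each entry
#' provides the model function (on a depth scale normalized to the full
#' curve), a starting-value heuristic, and box constraints. The registry is
#' a plain named list and can be extended or subset by the caller.
#'
#' @return A named list of model definitions.
#' @export
dive_models <- function() {
  list(
    michaelis_menten = list(
      fun = function(u, p) p[1] * u / (p[2] + u),
      start = function(u, y) c(2 * max(y), 0.5),
      lower = c(1e-8, 1e-8), upper = c(Inf, Inf)
    ),
    power = list(
      fun = function(u, p) p[1] * u^p[2],
      start = function(u, y) {
        fit <- stats::lm(log(y) ~ log(u))
        c(exp(stats::coef(fit)[1]), min(max(stats::coef(fit)[2], 0.05), 0.95))
      },
      lower = c(1e-8, 1e-8), upper = c(Inf, 1)
    ),
    logarithmic = list(
      fun = function(u, p) p[1] + p[2] * log(u),
      start = function(u, y) {
        fit <- stats::lm(y ~ log(u))
        c(stats::coef(fit)[1], max(stats::coef(fit)[2], 1e-6))
      },
      lower = c(-Inf, 1e-8), upper = c(Inf, Inf)
    ),
    negative_exponential = list(
      fun = function(u, p) p[1] * (1 - exp(-p[2] * u)),
      start = function(u, y) c(1.5 * max(y), 1),
      lower = c(1e-8, 1e-8), upper = c(Inf, Inf)
    ),
    weibull = list(
      fun = function(u, p) p[1] * (1 - exp(-p[2] * u^p[3])),
      start = function(u, y) c(1.5 * max(y), 1, 0.7),
      lower = c(1e-8, 1e-8, 0.01), upper = c(Inf, Inf, 1)
    ),
    rational = list(
      # rational 2/1: quadratic over linear, asymptotically linear growth
      fun = function(u, p) (p[1] + p[2] * u + p[3] * u^2) / (1 + p[4] * u),
      start = function(u, y) c(0, 2 * max(y), 0.5 * max(y), 1),
      lower = c(-Inf, 1e-8, 0, 1e-8), upper = c(Inf, Inf, Inf, Inf)
    ),
    gompertz = list(
      fun = function(u, p) p[1] * exp(-p[2] * exp(-p[3] * u)),
      start = function(u, y) c(1.5 * max(y), 3, 3),
      lower = c(1e-8, 1e-8, 1e-8), upper = c(Inf, Inf, Inf)
    ),
    logistic = list(
      fun = function(u, p) p[1] / (1 + p[2] * exp(-p[3] * u)),
      start = function(u, y) c(1.5 * max(y), 5, 3),
      lower = c(1e-8, 1e-8, 1e-8), upper = c(Inf, Inf, Inf)
    )
  )
}

fit_one_model <- function(model, u, y) {
  start <- unname(model$start(u, y))
  fit <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) model$fun(u, p) - y,
    lower = model$lower, upper = model$upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) {
    return(NULL)
  }
  fit$par
}

#' Fit the model ensemble to a pair of rarefaction curves
#'
#' Each registry model is fitted (nonlinear least squares) to the full
#' curve and, separately, to the half-depth curve. The model score is
#' `100 x (MAPE of the full-curve fit + MAPE of the half-curve fit's
#' prediction over the full curve)` plus 1000 for each violated
#' plausibility criterion: the fitted curve must be non-decreasing up to
#' the target, must decelerate (non-increasing slope), and must predict at
#' least the observed unique count at the target. Models that fail to
#' converge are dropped with a message.
#'
#' @param curve Full-depth rarefaction curve.
#' @param half_curve Half-depth rarefaction curve.
#' @param target_pop Target population size (>= the deepest curve point).
#' @param models Model registry (see [dive_models()]).
#' @param max_points Curves are thinned to at most this many points before
#'   fitting.
#' @return A tibble with one row per converged model: `model`, `estimate`
#'   (prediction at `target_pop`), `score`, error components, and
#'   penalties.
#' @export
fit_models <- function(curve, half_curve, target_pop,
                       models = dive_models(), max_points = 300L) {
  stopifnot(target_pop >= max(curve$size))
  thin <- function(cv) {
    if (nrow(cv) > max_points) {
      cv[unique(round(seq(1, nrow(cv), length.out = max_points))), ]
    } else {
      cv
    }
  }
  cv <- thin(curve)
  hv <- thin(half_curve)
  xscale <- max(cv$size)
  u <- cv$size / xscale
  y <- cv$unique
  uh <- hv$size / xscale
  yh <- hv$unique
  u_target <- target_pop / xscale
  observed <- max(y)
  rows <- lapply(names(models), function(nm) {
    model <- models[[nm]]
    p_full <- fit_one_model(model, u, y)
    p_half <- fit_one_model(model, uh, yh)
    if (is.null(p_full) || is.null(p_half)) {
      message("model '", nm, "' did not converge; dropped")
      return(NULL)
    }
    estimate <- model$fun(u_target, p_full)
    mape_fit <- mean(abs(model$fun(u, p_full) - y) / y)
    # extrapolation skill: how well the half-depth fit predicts the part
    # of the full curve beyond the half depth
    beyond <- u > max(uh)
    if (!any(beyond)) {
      beyond <- rep(TRUE, length(u))
    }
    mape_half <- mean(abs(model$fun(u[beyond], p_half) - y[beyond]) / y[beyond])
    grid <- seq(min(u), u_target, length.out = 201)
    yy <- model$fun(grid, p_full)
    tol <- 1e-6 * max(abs(yy))
    penalties <- 1000 * ((any(diff(yy) < -tol)) +
                           (any(diff(diff(yy)) > tol)) +
                           (!is.finite(estimate) || estimate < observed))
    if (!is.finite(estimate) || estimate <= 0) {
      return(NULL)
    }
    tibble::tibble(
      model = nm, estimate = estimate,
      score = 100 * (mape_fit + mape_half) + penalties,
      mape_fit = mape_fit, mape_half = mape_half, penalties = penalties
    )
  })
  dplyr::bind_rows(rows)
}

#' Aggregate model fits into a richness estimate
#'
#' Filters fits to those scoring at or below `score_cutoff`, takes the 3
#' lowest-scoring models (extended to at most 5 while scores stay within
#' 10% of the best; fewer when fewer pass), and reports the geometric mean
#' of their estimates. When no model passes, an explicit failure result is
#' returned (status `"failed"`, estimate `NA`) with a warning.
#'
#' @param fits Model fits from [fit_models()].
#' @param score_cutoff Maximum acceptable score.
#' @param top_k Number of models averaged; NULL for the 3-to-5 rule.
#' @param target_pop,observed_unique Optional provenance carried into the
#'   result.
#' @return An object of class `richness_estimate`: a list with `estimate`,
#'   `models` (the fits used), `status`, `score_cutoff`, `target_pop`,
#'   `observed_unique`.
#' @export
estimate_richness <- function(fits, score_cutoff = 250, top_k = NULL,
                              target_pop = NULL, observed_unique = NULL) {
  passing <- fits[is.finite(fits$score) & fits$score <= score_cutoff &
                    fits$estimate > 0, , drop = FALSE]
  if (nrow(passing) == 0) {
    warning("no model passed the score cutoff; richness estimate failed",
            call. = FALSE)
    return(structure(
      list(estimate = NA_real_, models = passing, status = "failed",
           score_cutoff = score_cutoff, target_pop = target_pop,
           observed_unique = observed_unique),
      class = "richness_estimate"
    ))
  }
  passing <- passing[order(passing$score, passing$model), , drop = FALSE]
  if (is.null(top_k)) {
    k <- min(3L, nrow(passing))
    best <- passing$score[1]
    while (k < min(5L, nrow(passing)) && passing$score[k + 1] <= 1.1 * best) {
      k <- k + 1L
    }
  } else {
    k <- min(top_k, nrow(passing))
  }
  used <- passing[seq_len(k), , drop = FALSE]
  structure(
    list(estimate = geometric_mean(used$estimate), models = used,
         status = "ok", score_cutoff = score_cutoff,
         target_pop = target_pop, observed_unique = observed_unique),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  if (x$status == "failed") {
    cat("Richness estimate: FAILED (no model passed the score cutoff of",
        x$score_cutoff, ")\n")
  } else {
    cat("Richness estimate:", format(x$estimate, digits = 4),
        "unique clonotypes at target population",
        format(x$target_pop, digits = 4), "\n")
    cat("Geometric mean of", nrow(x$models), "models:",
        paste(x$models$model, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimate repertoire richness at a target population size
#'
#' End-to-end extrapolation for one sample: builds a full-depth and a
#' half-depth rarefaction curve, fits the model ensemble, and aggregates
#' the top models (see [fit_models()] and [estimate_richness()]).
#'
#' @param table A `clonotype_table` or numeric UMI-count vector.
#' @param target_pop Target population size (cells; must be at least the
#'   observed depth).
#' @param normalized_depth Optional common depth (UMIs) at which the curve
#'   is truncated, for comparisons across samples; NULL uses the full
#'   depth.
#' @param n_resamples,nrf Rarefaction parameters (see [rarefy()]).
#' @param score_cutoff,top_k Model selection parameters.
#' @param models Model registry.
#' @param seed Optional seed for the rarefaction resampling.
#' @return A `richness_estimate`.
#' @export
dive_richness <- function(table, target_pop, normalized_depth = NULL,
                          n_resamples = 1000L, nrf = 2000L,
                          score_cutoff = 250, top_k = NULL,
                          models = dive_models(), seed = NULL) {
  counts <- if (is.numeric(table)) table else table$duplicate_count
  n_total <- sum(counts)
  depth <- min(n_total, normalized_depth %||% n_total)
  if (target_pop < depth) {
    stop("target_pop must be at least the curve depth", call. = FALSE)
  }
  sizes_full <- unique(pmax(1, round(seq(1, depth, length.out = min(nrf, depth)))))
  half <- max(2, floor(depth / 2))
  sizes_half <- unique(pmax(1, round(seq(1, half, length.out = min(nrf, half)))))
  curve <- rarefy(counts, sizes = sizes_full, n_resamples = n_resamples,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  half_curve <- rarefy(counts, sizes = sizes_half, n_resamples = n_resamples,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  fits <- fit_models(curve, half_curve, target_pop, models = models)
  estimate_richness(fits, score_cutoff = score_cutoff, top_k = top_k,
                    target_pop = target_pop,
                    observed_unique = length(counts))
}

#' Inverse Simpson's Index
#'
#' `ISI = 1 / lambda` with `lambda = sum(p_i^2)`, where `p_i` is the UMI
#' share of clonotype `i`. Equals the clone count for a perfectly uniform
#' repertoire and decreases as UMI mass concentrates in expanded clones.
#'
#' @param table A `clonotype_table` or numeric vector of UMI counts.
#' @return The ISI.
#' @examples
#' inverse_simpson(c(5, 5, 5, 5)) # 4
#' inverse_simpson(c(8, 1, 1))    # ~1.515
#' @export
inverse_simpson <- function(table) {
  counts <- if (is.numeric(table)) table else table$duplicate_count
  if (length(counts) == 0 || sum(counts) <= 0) {
    stop("cannot compute ISI of an empty repertoire", call. = FALSE)
  }
  p <- counts / sum(counts)
  1 / sum(p^2)
}
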