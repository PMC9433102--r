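# Paired alpha-beta repertoire estimation. Bulk sequencing measures the
# TCR alpha and beta chain repertoires separately; single-cell paired data
# reveal a linear relation between the chain richness values and the
# number of distinct alpha-beta combinations:
#
#   paired - max(f * alpha, beta) = M * (f * alpha + beta)
#
# where f is the fraction of cells carrying a single TCR alpha (bulk alpha
# counts are deflated by f because dual-alpha cells contribute two alpha
# sequences but one paired clonotype), and M is a through-origin
# least-squares slope. Subtracting the larger chain richness before the
# fit and forcing the intercept through zero guarantee that paired
# projections are never below either unpaired richness.

#' Paired-richness model constructor and lineage defaults
#'
#' `pairing_model()` builds a model from a slope and single-alpha
#' fraction; `pairing_model_cd4()` and `pairing_model_cd8()` return the
#' published lineage constants (CD4: M = 0.138, f = 0.870; CD8: M = 0.035,
#' f = 0.846).
#'
#' @param M Through-origin slope (>= 0).
#' @param f Single-alpha fraction in (0, 1].
#' @param lineage Optional lineage label ("CD4"/"CD8").
#' @param provenance `"fitted"` or `"published"`.
#' @return An object of class `pairing_model`.
#' @examples
#' apply_pairing_equation(pairing_model_cd4(), 1000, 1000) # 1258.06
#' @export
pairing_model <- function(M, f, lineage = NA_character_,
                          provenance = "fitted") {
  if (M < 0) {
    stop("slope M must be non-negative", call. = FALSE)
  }
  if (f <= 0 || f > 1) {
    stop("single-alpha fraction f must lie in (0, 1]", call. = FALSE)
  }
  structure(list(M = M, f = f, lineage = lineage, provenance = provenance),
            class = "pairing_model")
}

#' @rdname pairing_model
#' @export
pairing_model_cd4 <- function() {
  pairing_model(M = 0.138, f = 0.870, lineage = "CD4",
                provenance = "published")
}

#' @rdname pairing_model
#' @export
pairing_model_cd8 <- function() {
  pairing_model(M = 0.035, f = 0.846, lineage = "CD8",
                provenance = "published")
}

#' @export
print.pairing_model <- function(x, ...) {
  cat("Paired alpha-beta richness model",
      if (!is.na(x$lineage)) paste0("(", x$lineage, ")"), "\n")
  cat("  paired = ", format(x$M), " x (", format(x$f),
      " x alpha + beta) + max(", format(x$f), " x alpha, beta)\n", sep = "")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Fraction of cells with a single TCR alpha
#'
#' From single-cell paired data: the fraction of cells carrying exactly
#' one distinct TCR alpha clonotype. Cells with no alpha chain are
#' excluded (their number is returned in the `n_excluded` attribute, with
#' a warning).
#'
#' @param sc_table Long-format single-cell clonotypes (`cell_id`, `chain`,
#'   `v_call`, `j_call`, `junction_aa`, ...), as produced by
#'   [simulate_paired_sc()].
#' @return The single-alpha fraction, with attribute `n_excluded`.
#' @export
single_alpha_fraction <- function(sc_table) {
  alpha <- sc_table[sc_table$chain == "alpha", , drop = FALSE]
  cells <- unique(sc_table$cell_id)
  n_alpha <- tapply(
    clonotype_key(alpha, key = "aa"), alpha$cell_id,
    function(k) length(unique(k))
  )
  n_excluded <- length(cells) - length(n_alpha)
  if (n_excluded > 0) {
    warning(n_excluded, " cell(s) with no TCR alpha excluded", call. = FALSE)
  }
  f <- mean(n_alpha == 1L)
  attr(f, "n_excluded") <- n_excluded
  f
}

#' Merge undersized single-cell samples
#'
#' Samples with fewer than `min_cells` cells are pooled by greedy
#' accumulation in input order until each pool reaches `min_cells`; a
#' final undersized pool passes through as the residual merge. Cell
#' totals are conserved.
#'
#' @param sc_samples Named list of single-cell tables (see
#'   [single_alpha_fraction()] for the format).
#' @param min_cells Minimum cells per output sample.
#' @return A named list of single-cell tables.
#' @export
merge_small_samples <- function(sc_samples, min_cells = 2000L) {
  stopifnot(length(sc_samples) >= 1)
  n_cells <- vapply(sc_samples, function(s) length(unique(s$cell_id)),
                    integer(1))
  out <- list()
  pool <- NULL
  pool_n <- 0L
  pool_names <- character(0)
  flush <- function() {
    if (!is.null(pool)) {
      out[[paste(pool_names, collapse = "+")]] <<- pool
    }
    pool <<- NULL; pool_n <<- 0L; pool_names <<- character(0)
  }
  for (i in seq_along(sc_samples)) {
    nm <- names(sc_samples)[i] %||% as.character(i)
    if (n_cells[i] >= min_cells && is.null(pool)) {
      out[[nm]] <- sc_samples[[i]]
      next
    }
    s <- sc_samples[[i]]
    # prefix cell ids with the sample name so merged cells stay distinct
    s$cell_id <- paste(nm, s$cell_id, sep = ":")
    pool <- if (is.null(pool)) s else dplyr::bind_rows(pool, s)
    pool_n <- pool_n + n_cells[i]
    pool_names <- c(pool_names, nm)
    if (pool_n >= min_cells) {
      flush()
    }
  }
  flush()
  out
}

#' Fit the paired-richness slope
#'
#' Through-origin least squares of `y = paired - max(f * alpha, beta)` on
#' `x = f * alpha + beta` across samples: `M = sum(x y) / sum(x^2)`.
#'
#' @param samples Data frame with one row per sample and columns
#'   `alpha_unique`, `beta_unique`, `paired_unique`.
#' @param f Single-alpha fraction applied to the alpha counts (both in the
#'   sum and in the max term).
#' @param lineage Optional lineage label stored in the model.
#' @return A `pairing_model` with provenance `"fitted"`; the per-sample
#'   `x`, `y` used are attached as attribute `data`.
#' @export
fit_pairing_model <- function(samples, f, lineage = NA_character_) {
  stopifnot(nrow(samples) >= 1)
  x <- f * samples$alpha_unique + samples$beta_unique
  y <- samples$paired_unique - pmax(f * samples$alpha_unique,
                                    samples$beta_unique)
  if (all(x == 0)) {
    stop("cannot fit a through-origin slope: all predictors are zero",
         call. = FALSE)
  }
  M <- sum(x * y) / sum(x^2)
  model <- pairing_model(M = max(M, 0), f = f, lineage = lineage,
                         provenance = "fitted")
  attr(model, "data") <- tibble::tibble(x = x, y = y)
  attr(model, "raw_slope") <- M
  model
}

#' Paired alpha-beta richness from unpaired chain richness
#'
#' `M x (f * alpha + beta) + max(f * alpha, beta)`. By construction the
#' result is never below either (alpha-corrected) unpaired richness, and
#' the equation is homogeneous of degree 1 in `(alpha, beta)`.
#'
#' @param model A `pairing_model`.
#' @param alpha_richness,beta_richness Unpaired chain richness values
#'   (vectorized, non-negative).
#' @return Estimated paired alpha-beta richness.
#' @examples
#' apply_pairing_equation(pairing_model_cd8(), 1000, 1000) # 1064.61
#' @export
apply_pairing_equation <- function(model, alpha_richness, beta_richness) {
  stopifnot(inherits(model, "pairing_model"))
  if (any(alpha_richness < 0) || any(beta_richness < 0)) {
    stop("richness values must be non-negative", call. = FALSE)
  }
  fa <- model$f * alpha_richness
  model$M * (fa + beta_richness) + pmax(fa, beta_richness)
}
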