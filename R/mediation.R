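#' OLS path coefficients of a simple mediation model
#'
#' Three regressions, all with intercepts and the same covariates:
#' `m ~ x + covariates` gives the `a` path; `y ~ x + m + covariates` gives
#' `b` (mediator) and `c_prime` (direct); `y ~ x + covariates` gives the
#' total effect `c`. For OLS on one sample the decomposition
#' `c = c_prime + a * b` holds exactly. Strong collinearity between `x` and
#' `m` is reported as a warning with the design condition number.
#'
#' @param x,m,y predictor, mediator and outcome vectors.
#' @param covariates numeric covariate matrix or `NULL`.
#' @return List with unstandardized weights `a`, `b`, `c`, `c_prime`,
#'   `indirect` (`a * b`) and `n`.
#' @export
fit_paths <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  cm <- as_covariate_matrix(covariates, n)
  if (n <= ncol(cm) + 3) stop("need n > n_covariates + 3 observations")
  check_full_rank(cm)
  Xa <- cbind(`(Intercept)` = 1, x = x, cm)
  Xb <- cbind(`(Intercept)` = 1, x = x, m = m, cm)
  kappa_xm <- kappa(scale(cbind(x, m)), exact = TRUE)
  if (!is.finite(kappa_xm) || kappa_xm > 1e4)
    warning(sprintf("x and m nearly collinear (condition number %.3g); path estimates unstable",
                    kappa_xm))
  a <- stats::lm.fit(Xa, m)$coefficients[["x"]]
  cc <- stats::lm.fit(Xa, y)$coefficients[["x"]]
  ab <- path_b(Xb, y, m, cm)
  list(a = a, b = ab[["b"]], c = cc,
       c_prime = if (is.na(ab[["c_prime"]])) cc - a * ab[["b"]]
                 else ab[["c_prime"]],
       indirect = a * ab[["b"]], n = n)
}

# b and c' from y ~ x + m + covariates. When m is an exact linear function
# of x the model is unidentified and pivoting aliases the mediator column;
# the shared effect is then attributed to the mediator path (b from
# y ~ m + covariates, c' by difference), the conventional reading of a
# noise-free chain.
path_b <- function(Xb, y, m, cm) {
  co <- stats::lm.fit(Xb, y)$coefficients
  if (!is.na(co[["m"]]))
    return(c(b = co[["m"]], c_prime = co[["x"]]))
  co_m <- stats::lm.fit(cbind(1, m = m, cm), y)$coefficients
  c(b = co_m[["m"]], c_prime = NA_real_)
}

#' Percentile bootstrap CI for the indirect effect
#'
#' Case resampling of subjects: each bootstrap draw refits the `a` and `b`
#' paths on a resample of rows and records `a * b`; the interval is the
#' percentile interval of those draws. Resamples in which `x` (or the
#' mediator) has zero variance are redrawn, counted, and capped at 1% of
#' `n_boot`. Deterministic under a fixed seed.
#'
#' @inheritParams fit_paths
#' @param n_boot number of bootstrap resamples (>= 1000 recommended).
#' @param level confidence level in (0, 1).
#' @param seed integer seed (required, for reproducibility).
#' @return List with `lower`, `upper`, `level`, `n_boot`, `seed`,
#'   `indirect_draws` and `n_redrawn`.
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, n_boot = 5000,
                               level = 0.95, seed) {
  stopifnot(level > 0, level < 1, n_boot >= 1)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  n <- length(x)
  cm <- as_covariate_matrix(covariates, n)
  set.seed(seed)
  draws <- numeric(n_boot)
  redrawn <- 0L
  max_redraw <- max(1L, floor(0.01 * n_boot))
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) > 0 && stats::var(m[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > max_redraw)
        stop("too many degenerate bootstrap resamples (zero variance in x or m)")
    }
    cmi <- cm[idx, , drop = FALSE]
    Xa <- cbind(1, x = x[idx], cmi)
    Xb <- cbind(1, x = x[idx], m = m[idx], cmi)
    a_i <- stats::lm.fit(Xa, m[idx])$coefficients[2L]
    b_i <- path_b(Xb, y[idx], m[idx], cmi)[["b"]]
    draws[i] <- a_i * b_i
  }
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 6)
  list(lower = qs[1], upper = qs[2], level = level, n_boot = n_boot,
       seed = seed, indirect_draws = draws, n_redrawn = redrawn)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * indirect / c`, in percent. Flagged as unstable when the indirect
#' effect exceeds the total in magnitude or the two disagree in sign
#' (inconsistent mediation); undefined (`NA`, flagged) when `c = 0`.
#'
#' @param indirect indirect effect `a * b`.
#' @param c total effect.
#' @return Numeric percentage with logical attribute `unstable`.
#' @export
proportion_mediated <- function(indirect, c) {
  if (c == 0) {
    warning("total effect is zero: proportion mediated undefined")
    return(structure(NA_real_, unstable = TRUE))
  }
  unstable <- abs(indirect) > abs(c) || sign(indirect) * sign(c) < 0
  if (unstable && indirect != 0)
    warning("inconsistent mediation: |indirect| > |c| or opposite signs")
  structure(100 * indirect / c, unstable = unstable)
}

#' Preacher-Hayes simple mediation with bootstrap CI
#'
#' Full analysis for one mediator: OLS path coefficients, percentile
#' bootstrap CI for the indirect effect, and the proportion mediated.
#'
#' @inheritParams bootstrap_indirect
#' @return Object of class `mediation_result` with the path weights,
#'   `indirect`, `ci` (lower/upper/level/n_boot/seed), `proportion_mediated`
#'   (%), `unstable` and the covariate names.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, level = 0.95,
                    seed) {
  paths <- fit_paths(x, m, y, covariates)
  ci <- bootstrap_indirect(x, m, y, covariates, n_boot = n_boot,
                           level = level, seed = seed)
  pm <- proportion_mediated(paths$indirect, paths$c)
  structure(list(a = paths$a, b = paths$b, c = paths$c,
                 c_prime = paths$c_prime, indirect = paths$indirect,
                 ci = ci[c("lower", "upper", "level", "n_boot", "seed")],
                 proportion_mediated = as.numeric(pm),
                 unstable = isTRUE(attr(pm, "unstable")),
                 n = paths$n,
                 covariates = colnames(as_covariate_matrix(covariates,
                                                           length(x)))),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("<mediation_result> a = %.3f, b = %.3f, c = %.3f, ",
                     "c' = %.3f\n  indirect = %.3f, %g%% CI [%.3f, %.3f], ",
                     "%.2f%% mediated%s\n"),
              x$a, x$b, x$c, x$c_prime, x$indirect, 100 * x$ci$level,
              x$ci$lower, x$ci$upper, x$proportion_mediated,
              if (x$unstable) " (unstable)" else ""))
  invisible(x)
}

#' Run single-mediator models for several regions of a cohort
#'
#' One [mediate()] call per mediator column, X and Y fixed, sharing the
#' covariate set (by default age, sex, education and total intracranial
#' volume).
#'
#' @param cohort cohort `data.frame` (see [generate_cohort()]); analysis is
#'   restricted to `group == "PD"` rows when a `group` column is present.
#' @param mediators character vector of mediator column names.
#' @param x_col,y_col predictor and outcome columns.
#' @param covars covariate column names.
#' @param n_boot,level,seed bootstrap settings; per-mediator seeds are
#'   derived from `seed` so regions are independent but reproducible.
#' @return `data.frame`, one row per mediator, with paths, CI bounds,
#'   proportion mediated and flags.
#' @export
mediate_regions <- function(cohort, mediators, x_col = "alps_m",
                            y_col = "mmse",
                            covars = c("age", "sex", "education", "tiv"),
                            n_boot = 5000, level = 0.95, seed = 17L) {
  if ("group" %in% names(cohort)) cohort <- cohort[cohort$group == "PD", ]
  miss <- setdiff(c(x_col, y_col, covars, mediators), names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  cm <- as.matrix(cohort[covars])
  rows <- lapply(seq_along(mediators), function(j) {
    med <- mediate(cohort[[x_col]], cohort[[mediators[j]]], cohort[[y_col]],
                   covariates = cm, n_boot = n_boot, level = level,
                   seed = derive_seed(seed, mediators[j]))
    data.frame(mediator = mediators[j], a = med$a, b = med$b, c = med$c,
               c_prime = med$c_prime, indirect = med$indirect,
               ci_lower = med$ci$lower, ci_upper = med$ci$upper,
               level = level, n_boot = n_boot,
               proportion_mediated = med$proportion_mediated,
               unstable = med$unstable, n = med$n)
  })
  do.call(rbind, rows)
}
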