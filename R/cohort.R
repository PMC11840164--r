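#' Default regional grey-matter table for the cohort generator
#'
#' Six cortical regions with plausible volume scales (cm^3), the
#' ALPS-to-volume slope `a` (cm^3 per index unit) and the volume-to-MMSE
#' slope `b` (points per cm^3). Slopes are calibrated so that, at the
#' patient-group ALPS spread (SD 0.17), the implied ALPS-volume correlations
#' sit in the 0.38-0.47 range typical of region-level atrophy studies, and
#' only the anterior cingulate and the orbital inferior frontal region carry
#' an indirect path to cognition (b > 0): with a total ALPS-MMSE effect of
#' 14 points per index unit, their true proportions mediated are 17.49% and
#' 32.24%.
#'
#' @return `data.frame` with columns `region`, `mean`, `sd`, `a`, `b`.
#' @export
default_region_table <- function() {
  c_total <- 14
  a <- c(temporal_pole = 0.43 * 1.8, posterior_orbital = 0.38 * 0.7,
         orbital_inf_frontal = 0.47 * 0.6, frontal_operculum = 0.39 * 0.5,
         central_operculum = 0.40 * 0.9, anterior_cingulate = 0.41 * 1.0) / 0.17
  b <- c(temporal_pole = 0, posterior_orbital = 0,
         orbital_inf_frontal = 0.3224 * c_total / a[["orbital_inf_frontal"]],
         frontal_operculum = 0, central_operculum = 0,
         anterior_cingulate = 0.1749 * c_total / a[["anterior_cingulate"]])
  data.frame(
    region = names(a),
    mean = c(14, 5, 4, 3.5, 7, 8),
    sd = c(1.8, 0.7, 0.6, 0.5, 0.9, 1.0),
    a = unname(a), b = unname(b),
    row.names = NULL
  )
}

#' Specification of a synthetic patient/control cohort
#'
#' Emulates a Parkinson's disease (PD) versus normal control (NC) glymphatic
#' study: per-group hemispheric ALPS distributions, demographic covariates,
#' regional grey-matter volumes linked to ALPS, and MMSE linked to both,
#' giving a known mediation structure ALPS -> GMV -> MMSE within the PD
#' group. Defaults reproduce the published group conditions: PD n = 51 with
#' mean ALPS 1.45 (left 1.46 +/- 0.19, right 1.44 +/- 0.18) and
#' MMSE 23.9 +/- 4.38; NC n = 30 with mean ALPS 1.64 (left 1.62 +/- 0.17,
#' right 1.66 +/- 0.20). Hemispheric indices are drawn bivariate-normal with
#' correlation `alps_lr_cor` chosen so the across-hemisphere mean has
#' SD 0.17 in both groups.
#'
#' @param n_pd,n_nc group sizes (>= 3).
#' @param alps_pd,alps_nc named `c(l, r)` hemispheric ALPS means per group.
#' @param alps_sd_pd,alps_sd_nc named `c(l, r)` hemispheric SDs.
#' @param alps_lr_cor left-right correlation of the hemispheric indices.
#' @param age_pd,age_nc `c(mean, sd)` in years.
#' @param male_p_pd,male_p_nc probability of male sex (encoded 1; female 0).
#' @param edu_pd,edu_nc `c(mean, sd)` education years.
#' @param tiv `c(mean, sd)` total intracranial volume, cm^3.
#' @param regions region table as from [default_region_table()].
#' @param c_prime direct ALPS -> MMSE effect (points per index unit) after
#'   the regional paths.
#' @param mmse_pd `c(mean, sd)` of PD MMSE; the mean anchors the model
#'   intercept at the PD mean ALPS and the sd sets the total variance from
#'   which the residual noise is derived.
#' @param mmse_nc `c(mean, sd)` of NC MMSE (controls sit near ceiling and
#'   are not part of the mediation model).
#' @param gmv_covariate_loadings,mmse_covariate_loadings named numeric
#'   vectors (`age`, `sex`, `education`, `tiv`) of covariate effects; all
#'   zero by default so adjustment code paths can be exercised both inert
#'   and active.
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 51, n_nc = 30,
                        alps_pd = c(l = 1.46, r = 1.44),
                        alps_nc = c(l = 1.62, r = 1.66),
                        alps_sd_pd = c(l = 0.19, r = 0.18),
                        alps_sd_nc = c(l = 0.17, r = 0.20),
                        alps_lr_cor = 0.69,
                        age_pd = c(61.65, 8.27), age_nc = c(59.2, 5.90),
                        male_p_pd = 28 / 51, male_p_nc = 11 / 30,
                        edu_pd = c(12.3, 3.7), edu_nc = c(13.0, 3.2),
                        tiv = c(1450, 130),
                        regions = default_region_table(),
                        c_prime = 14 * (1 - 0.1749 - 0.3224),
                        mmse_pd = c(23.9, 4.38), mmse_nc = c(28.4, 1.4),
                        gmv_covariate_loadings = c(age = 0, sex = 0, tiv = 0),
                        mmse_covariate_loadings = c(age = 0, sex = 0,
                                                    education = 0, tiv = 0),
                        seed = 1L) {
  stopifnot(n_pd >= 3, n_nc >= 3,
            all(alps_sd_pd > 0), all(alps_sd_nc > 0),
            abs(alps_lr_cor) < 1, tiv[2] > 0, mmse_pd[2] > 0)
  stopifnot(is.data.frame(regions),
            all(c("region", "mean", "sd", "a", "b") %in% names(regions)),
            all(regions$sd > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

# True single-mediator quantities implied by a cohort_spec: total effect,
# per-region indirect effect and proportion mediated (pre-rounding scale).
cohort_ground_truth <- function(spec) {
  ab <- spec$regions$a * spec$regions$b
  c_total <- spec$c_prime + sum(ab)
  list(a = stats::setNames(spec$regions$a, spec$regions$region),
       b = stats::setNames(spec$regions$b, spec$regions$region),
       c_prime = spec$c_prime, c_total = c_total,
       indirect = stats::setNames(ab, spec$regions$region),
       prop_mediated = stats::setNames(100 * ab / c_total, spec$regions$region),
       seed = spec$seed)
}

rbinorm <- function(n, mean1, mean2, sd1, sd2, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  x1 <- mean1 + sd1 * z1
  x2 <- mean2 + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  cbind(x1, x2)
}

#' Generate a synthetic cohort table
#'
#' Draws per-group ALPS, covariates, region volumes and MMSE under the
#' spec's structural model. Within the PD group the mean ALPS index `x`
#' (centred at the PD mean) drives each region volume
#' `m_j = mean_j + a_j x + loadings + noise` and
#' `MMSE = mean_MMSE + c' x + sum_j b_j (m_j - mean_j) + loadings + noise`,
#' then MMSE is rounded and clamped to `[0, 30]` (a warning is raised if
#' more than 20% of values clamp). The residual noise SDs are derived from
#' the marginal SDs in the spec so the generated margins match the stated
#' conditions. The true path coefficients (pre-rounding) are attached as
#' `attr(, "ground_truth")`.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with one row per subject: `id`, `group`, `age`,
#'   `sex` (0 female / 1 male), `education`, `tiv`, `mmse`, `alps_l`,
#'   `alps_r`, `alps_m` and one `gmv_<region>` column per region;
#'   `attr(, "ground_truth")` holds the generating path coefficients.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  truth <- cohort_ground_truth(spec)
  n <- spec$n_pd + spec$n_nc
  group <- rep(c("PD", "NC"), c(spec$n_pd, spec$n_nc))
  pd <- group == "PD"

  alps <- matrix(NA_real_, n, 2)
  alps[pd, ] <- rbinorm(spec$n_pd, spec$alps_pd[["l"]], spec$alps_pd[["r"]],
                        spec$alps_sd_pd[["l"]], spec$alps_sd_pd[["r"]],
                        spec$alps_lr_cor)
  alps[!pd, ] <- rbinorm(spec$n_nc, spec$alps_nc[["l"]], spec$alps_nc[["r"]],
                         spec$alps_sd_nc[["l"]], spec$alps_sd_nc[["r"]],
                         spec$alps_lr_cor)
  alps_m <- rowMeans(alps)

  age <- ifelse(pd, stats::rnorm(n, spec$age_pd[1], spec$age_pd[2]),
                stats::rnorm(n, spec$age_nc[1], spec$age_nc[2]))
  sex <- stats::rbinom(n, 1, ifelse(pd, spec$male_p_pd, spec$male_p_nc))
  education <- pmax(0, ifelse(pd,
                              stats::rnorm(n, spec$edu_pd[1], spec$edu_pd[2]),
                              stats::rnorm(n, spec$edu_nc[1], spec$edu_nc[2])))
  tiv <- stats::rnorm(n, spec$tiv[1], spec$tiv[2])

  gl <- spec$gmv_covariate_loadings
  ml <- spec$mmse_covariate_loadings
  x_pd_mean <- mean(c(spec$alps_pd[["l"]], spec$alps_pd[["r"]]))
  var_x_spec <- ((spec$alps_sd_pd[["l"]]^2 + spec$alps_sd_pd[["r"]]^2 +
                    2 * spec$alps_lr_cor * spec$alps_sd_pd[["l"]] *
                    spec$alps_sd_pd[["r"]]) / 4)
  xc <- alps_m - x_pd_mean

  gmv <- matrix(NA_real_, n, nrow(spec$regions))
  colnames(gmv) <- paste0("gmv_", spec$regions$region)
  resid_sd_m <- numeric(nrow(spec$regions))
  for (j in seq_len(nrow(spec$regions))) {
    rj <- spec$regions[j, ]
    v_resid <- rj$sd^2 - rj$a^2 * var_x_spec
    if (v_resid <= 0)
      stop("region '", rj$region, "': a^2 Var(ALPS) exceeds the stated ",
           "volume variance; reduce a or raise sd")
    resid_sd_m[j] <- sqrt(v_resid)
    gmv[, j] <- rj$mean + rj$a * xc +
      gl[["age"]] * (age - 60) + gl[["sex"]] * sex +
      gl[["tiv"]] * (tiv - spec$tiv[1]) / 100 +
      stats::rnorm(n, 0, resid_sd_m[j])
  }

  # MMSE = c_total * x + sum_j b_j u_j + e, with u_j the region residuals
  c_total <- spec$c_prime + sum(spec$regions$a * spec$regions$b)
  var_struct <- c_total^2 * var_x_spec + sum(spec$regions$b^2 * resid_sd_m^2)
  v_e <- spec$mmse_pd[2]^2 - var_struct
  if (v_e <= 0)
    stop("structural paths explain more MMSE variance (", format(var_struct),
         ") than the stated total (", format(spec$mmse_pd[2]^2), ")")
  mmse_raw <- spec$mmse_pd[1] + spec$c_prime * xc +
    gmv %*% spec$regions$b - sum(spec$regions$mean * spec$regions$b) +
    ml[["age"]] * (age - 60) + ml[["sex"]] * sex +
    ml[["education"]] * (education - 12) +
    ml[["tiv"]] * (tiv - spec$tiv[1]) / 100 +
    stats::rnorm(n, 0, sqrt(v_e))
  mmse_raw[!pd] <- stats::rnorm(spec$n_nc, spec$mmse_nc[1], spec$mmse_nc[2])
  mmse <- pmin(30L, pmax(0L, as.integer(round(mmse_raw))))
  clamp_rate <- mean(mmse_raw < -0.5 | mmse_raw > 30.5)
  if (clamp_rate > 0.2)
    warning(sprintf("%.0f%% of MMSE values clamped to [0, 30]; the linear model is a poor fit to the scale",
                    100 * clamp_rate))

  out <- data.frame(id = sprintf("S%03d", seq_len(n)), group = group,
                    age = age, sex = sex, education = education, tiv = tiv,
                    mmse = mmse, alps_l = alps[, 1], alps_r = alps[, 2],
                    alps_m = alps_m, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(gmv))
  attr(out, "ground_truth") <- truth
  out
}

#' Write a cohort to CSV with a ground-truth JSON sidecar
#'
#' @param cohort result of [generate_cohort()].
#' @param csv_path output CSV path.
#' @param truth_path optional JSON path for the generating coefficients;
#'   default replaces the CSV extension with `_truth.json`.
#' @return The CSV path, invisibly.
#' @export
write_cohort <- function(cohort, csv_path, truth_path = NULL) {
  df <- cohort
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, digits = 10)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  truth <- attr(cohort, "ground_truth")
  if (!is.null(truth)) {
    if (is.null(truth_path))
      truth_path <- sub("\\.csv$", "_truth.json", csv_path)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read a cohort CSV
#'
#' @param path CSV written by [write_cohort()] (or matching its schema).
#' @return `data.frame` with the subject-record columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "education", "tiv", "mmse", "alps_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV '", path, "' is missing columns: ",
         paste(miss, collapse = ", "))
  df
}
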