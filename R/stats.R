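#' Shapiro-Wilk normality gate
#'
#' Returns `TRUE` (treat as normal, route to ANCOVA) iff the Shapiro-Wilk
#' p-value is at least `alpha`; otherwise `FALSE` (route to the Quade rank
#' analysis of covariance). A constant vector is non-normal by convention
#' and flagged with a warning.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha gate level, default 0.05.
#' @return Logical scalar with attribute `p_value`.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (stats::sd(values) == 0) {
    warning("constant vector: treated as non-normal")
    return(structure(FALSE, p_value = NA_real_))
  }
  p <- stats::shapiro.test(values)$p.value
  structure(p >= alpha, p_value = p)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0))
    return(matrix(numeric(0), n, 0))
  cm <- as.matrix(covariates)
  stopifnot(nrow(cm) == n)
  if (is.null(colnames(cm))) colnames(cm) <- paste0("cov", seq_len(ncol(cm)))
  storage.mode(cm) <- "double"
  cm
}

check_full_rank <- function(cm) {
  if (ncol(cm) == 0) return(invisible())
  X <- cbind(1, cm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)]) - 1L
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(colnames(cm)[drop], collapse = ", "))
  }
}

#' Group comparison by ANCOVA
#'
#' Linear model `y ~ group + covariates`; the group effect is tested by the
#' extra-sum-of-squares F test of the group term against the model without
#' it (with a single two-level factor this is the Type-III test). Adjusted
#' group means are evaluated at the covariate means.
#'
#' @param y numeric outcome.
#' @param group two-level factor or character/logical vector.
#' @param covariates numeric matrix (or `NULL`) of covariates.
#' @return Object of class `group_comparison`: `method`, `f`, `df`,
#'   `p_value`, `adjusted_means`, `covariates`.
#' @export
ancova_group_compare <- function(y, group, covariates = NULL) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L, all(table(group) >= 2L),
            length(y) == length(group))
  cm <- as_covariate_matrix(covariates, length(y))
  check_full_rank(cm)
  dat <- data.frame(y = y, group = group)
  full <- if (ncol(cm)) stats::lm(y ~ group + cm, data = dat)
          else stats::lm(y ~ group, data = dat)
  red <- if (ncol(cm)) stats::lm(y ~ cm, data = dat)
         else stats::lm(y ~ 1, data = dat)
  an <- stats::anova(red, full)
  f <- an$F[2]; p <- an$`Pr(>F)`[2]
  co <- stats::coef(full)
  base <- co[1] + if (ncol(cm)) sum(co[-(1:2)] * colMeans(cm)) else 0
  adj <- c(base, base + co[2])
  names(adj) <- levels(group)
  structure(list(method = "ancova", f = f, df = c(an$Df[2], an$Res.Df[2]),
                 p_value = p, adjusted_means = adj,
                 covariates = colnames(cm)),
            class = "group_comparison")
}

#' Group comparison by the Quade rank analysis of covariance
#'
#' Nonparametric analogue of ANCOVA: the outcome and each covariate are
#' rank-transformed (midranks for ties), the outcome ranks are regressed on
#' the covariate ranks by OLS, and a one-way ANOVA on the residuals tests
#' the group effect.
#'
#' @inheritParams ancova_group_compare
#' @return A `group_comparison` with `method = "quade"`.
#' @export
quade_rank_ancova <- function(y, group, covariates = NULL) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L, length(y) == length(group))
  if (length(unique(y)) == 1L) stop("all y values tied: Quade test undefined")
  cm <- as_covariate_matrix(covariates, length(y))
  check_full_rank(cm)
  ry <- rank(y)
  rcm <- apply(cm, 2, rank)
  resid <- if (ncol(cm)) stats::lm.fit(cbind(1, rcm), ry)$residuals
           else ry - mean(ry)
  an <- stats::anova(stats::lm(resid ~ group))
  structure(list(method = "quade", f = an$`F value`[1],
                 df = c(an$Df[1], an$Df[2]), p_value = an$`Pr(>F)`[1],
                 adjusted_means = tapply(resid, group, mean),
                 covariates = colnames(cm)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$method, x$df[1], x$df[2], x$f, x$p_value))
  invisible(x)
}

#' Normality-gated group comparison
#'
#' Applies [shapiro_gate()] to the outcome and routes to
#' [ancova_group_compare()] when normal, [quade_rank_ancova()] otherwise.
#' The route taken is recorded in the result's `method` field.
#'
#' @inheritParams ancova_group_compare
#' @param alpha gate level for the Shapiro-Wilk test.
#' @return A `group_comparison`.
#' @export
group_compare <- function(y, group, covariates = NULL, alpha = 0.05) {
  if (shapiro_gate(y, alpha)) ancova_group_compare(y, group, covariates)
  else quade_rank_ancova(y, group, covariates)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Without continuity correction by default (`correct = TRUE` applies the
#' Yates correction on 2 x 2 tables).
#'
#' @param table matrix of non-negative integer counts.
#' @param correct apply the Yates continuity correction.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: the test is undefined")
  ct <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS regression
#' on the covariates (with intercept); identical to the recursive-formula
#' partial correlation. The p-value uses the t distribution with
#' `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (or `NULL` for the plain Pearson
#'   correlation).
#' @return Object of class `partial_corr`: `r`, `p_value`, `df`,
#'   `covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  cm <- as_covariate_matrix(covariates, n)
  if (n <= ncol(cm) + 2) stop("need n > n_covariates + 2 observations")
  check_full_rank(cm)
  X <- cbind(1, cm)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance after residualization: partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2 - ncol(cm)
  tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p_value = 2 * stats::pt(-abs(tstat), df), df = df,
                 covariates = colnames(cm)),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("<partial_corr> r = %.3f (df = %d, p = %.4g)\n",
              x$r, x$df, x$p_value))
  invisible(x)
}

#' ROC curve and AUC by the Mann-Whitney construction
#'
#' AUC is the probability that a random positive-class score exceeds a
#' random negative-class score, ties counting one half — computed from
#' midranks. The curve is evaluated at every distinct score threshold.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels binary labels; `positive` names the positive class.
#' @param positive value of `labels` treated as positive.
#' @return Object of class `roc_result`: `auc`, `thresholds`,
#'   `sensitivities`, `specificities`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("labels must contain exactly two classes, found ", length(lv))
  if (is.null(positive)) positive <- sort(as.character(lv))[2L]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 1)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 1)
  structure(list(auc = auc, thresholds = thr, sensitivities = sens,
                 specificities = spec, n_pos = n_pos, n_neg = n_neg,
                 positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positive vs %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
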