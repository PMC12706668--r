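#' Cronbach's alpha
#'
#' Internal-consistency reliability of a respondents x items score table:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`
#' with sample (n-1) variances.
#'
#' @param x Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least 2 of each.
#' @return A single numeric value. Errors when the total-score variance is
#'   zero (alpha undefined).
#' @export
#' @examples
#' set.seed(1)
#' item <- sample(1:5, 20, replace = TRUE)
#' cronbach_alpha(cbind(item, item))  # duplicated item: exactly 1
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("score table must be numeric", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  }
  if (anyNA(x)) stop("score table contains missing values", call. = FALSE)
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var == 0) {
    stop("total-score variance is zero: Cronbach's alpha undefined",
         call. = FALSE)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' KMO measure and Bartlett's test of sphericity
#'
#' Sampling-adequacy and factorability diagnostics for a respondents x items
#' score table. The Kaiser-Meyer-Olkin measure compares squared correlations
#' against squared anti-image partial correlations over the off-diagonal:
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))`, where the partial correlations
#' `q_ij = -S_ij / sqrt(S_ii * S_jj)` come from the inverse `S` of the
#' correlation matrix. Bartlett's statistic is
#' `chi2 = -(n - 1 - (2k + 5)/6) * log(det(R))` on `k(k-1)/2` degrees of
#' freedom.
#'
#' @param x Numeric matrix or data frame, respondents in rows, at least 3
#'   item columns.
#' @return A list of class `"kano_qc"`: `n_respondents`, `n_items`, `kmo`
#'   (`NA` with a warning when the correlation matrix is singular),
#'   `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
kmo_bartlett <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("score table must be numeric", call. = FALSE)
  if (ncol(x) < 3L) stop("need at least 3 items", call. = FALSE)
  if (nrow(x) <= ncol(x)) {
    warning("fewer respondents than items + 1; diagnostics may be unstable",
            call. = FALSE)
  }
  if (anyNA(x)) stop("score table contains missing values", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  R <- cor(x)
  detR <- det(R)
  chi2 <- max(0, -(n - 1 - (2 * k + 5) / 6) * log(max(detR, .Machine$double.xmin)))
  df <- k * (k - 1) / 2
  kmo <- tryCatch({
    S <- solve(R)
    Qp <- -S / sqrt(outer(diag(S), diag(S)))
    off <- upper.tri(R)
    sum(R[off]^2) / (sum(R[off]^2) + sum(Qp[off]^2))
  }, error = function(e) {
    warning("correlation matrix is singular; KMO not computable",
            call. = FALSE)
    NA_real_
  })
  structure(
    list(n_respondents = n, n_items = k, kmo = kmo,
         bartlett_chi2 = chi2, bartlett_df = df,
         bartlett_p = pchisq(chi2, df, lower.tail = FALSE)),
    class = "kano_qc"
  )
}

#' @export
print.kano_qc <- function(x, ...) {
  cat("Questionnaire QC (", x$n_respondents, " respondents, ",
      x$n_items, " items)\n", sep = "")
  cat("  KMO:      ", format(round(x$kmo, 3)), "\n")
  cat("  Bartlett: chi2 = ", format(round(x$bartlett_chi2, 2)),
      ", df = ", x$bartlett_df,
      ", p = ", format.pval(x$bartlett_p, digits = 3), "\n", sep = "")
  invisible(x)
}
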