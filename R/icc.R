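#' Intraclass correlation coefficients from a subjects x raters table
#'
#' Single-measure intraclass correlation from the two-way ANOVA
#' decomposition of a complete subjects-by-columns matrix (columns are
#' raters for an inter-observer design, or repeats for an intra-observer
#' design). With `n` subjects, `k` columns, grand mean `g`, row means
#' `R_i` and column means `C_j`:
#'
#' \deqn{SSR = k \sum_i (R_i - g)^2, \quad SSC = n \sum_j (C_j - g)^2,}
#' \deqn{SSE = \sum_{ij} (x_{ij} - g)^2 - SSR - SSC,}
#'
#' with mean squares `MSR = SSR/(n-1)`, `MSC = SSC/(k-1)`,
#' `MSE = SSE/((n-1)(k-1))`. Then
#'
#' * ICC(2,1) (two-way random effects, absolute agreement):
#'   `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' * ICC(3,1) (two-way mixed effects, consistency):
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`
#'
#' A systematic shift between columns lowers ICC(2,1) but not ICC(3,1).
#' Missing cells are an error; no imputation is performed.
#'
#' @param values Numeric matrix, subjects in rows (n >= 2), raters or
#'   repeats in columns (k >= 2), no missing cells.
#' @param form `"icc_2_1"` or `"icc_3_1"`.
#' @return An object of class `icc_result`: `icc`, `form`, `ms_rows`,
#'   `ms_cols`, `ms_error`, `n_subjects`, `k_raters`.
#' @examples
#' x <- cbind(1:6, 1:6 + 0.5)         # constant shift between raters
#' icc(x, "icc_3_1")$icc              # 1: perfectly consistent
#' icc(x, "icc_2_1")$icc              # < 1: absolute agreement penalised
#' @export
icc <- function(values, form = c("icc_2_1", "icc_3_1")) {
  form <- match.arg(form)
  values <- as.matrix(values)
  if (anyNA(values))
    stop("reliability table has missing cells; no imputation is performed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("at least 2 subjects and 2 columns are required")
  g <- mean(values)
  rmeans <- rowMeans(values)
  cmeans <- colMeans(values)
  ssr <- k * sum((rmeans - g)^2)
  ssc <- n * sum((cmeans - g)^2)
  sse <- sum((values - g)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- switch(form,
    icc_2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    icc_3_1 = (msr - mse) / (msr + (k - 1) * mse)
  )
  structure(
    list(icc = val, form = form, ms_rows = msr, ms_cols = msc,
         ms_error = mse, n_subjects = n, k_raters = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  lab <- c(icc_2_1 = "ICC(2,1) two-way random, absolute agreement",
           icc_3_1 = "ICC(3,1) two-way mixed, consistency")
  cat(sprintf("%s: %.4f  (n = %d subjects, k = %d)\n",
              lab[[x$form]], x$icc, x$n_subjects, x$k_raters))
  invisible(x)
}

#' Reliability report for a per-eye repeated-measures table
#'
#' Computes one ICC per metric from a wide table of repeated measurements.
#' Inter-observer designs use ICC(2,1); intra-observer designs use
#' ICC(3,1).
#'
#' @param table Data frame: one row per subject (eye), one column per
#'   rater/repeat per metric, or a plain numeric matrix for a single
#'   metric.
#' @param design `"inter_observer"` or `"intra_observer"`.
#' @return For a matrix input, an [icc()] result; for a data frame whose
#'   columns follow the `metric.rep` naming (e.g. `init_mm.1`,
#'   `init_mm.2`), a data frame with one row per metric: `metric`,
#'   `design`, `form`, `icc`, `ms_rows`, `ms_cols`, `ms_error`.
#' @export
reliability_report <- function(table,
                               design = c("inter_observer",
                                          "intra_observer")) {
  design <- match.arg(design)
  form <- if (design == "inter_observer") "icc_2_1" else "icc_3_1"
  if (is.matrix(table) || !any(grepl("\\.", names(table)))) {
    return(icc(as.matrix(table), form))
  }
  base <- sub("\\.[^.]+$", "", names(table))
  metrics <- unique(base[grepl("\\.", names(table))])
  rows <- lapply(metrics, function(m) {
    mat <- as.matrix(table[, base == m, drop = FALSE])
    res <- icc(mat, form)
    data.frame(metric = m, design = design, form = form, icc = res$icc,
               ms_rows = res$ms_rows, ms_cols = res$ms_cols,
               ms_error = res$ms_error)
  })
  do.call(rbind, rows)
}
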