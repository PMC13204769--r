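#' Krippendorff's alpha
#'
#' Chance-corrected agreement for any number of raters with missing data,
#' via the coincidence-matrix formulation: `alpha = 1 - Do / De` where the
#' observed disagreement weights each within-unit pair by `1 / (m_u - 1)`.
#' Difference functions: nominal (0/1), ordinal (squared cumulative
#' coincidence margins) and interval (squared value difference).
#'
#' @param ratings Units x raters matrix (numeric; `NA` = missing).
#' @param level Scale level: `"nominal"`, `"ordinal"` or `"interval"`.
#' @return Alpha in \[-1, 1\]. When every pairable value is identical the
#'   expected disagreement is zero; alpha is reported as 1 by convention,
#'   with a warning.
#' @export
krippendorff_alpha <- function(ratings,
                               level = c("ordinal", "nominal", "interval")) {
  level <- match.arg(level)
  ratings <- as.matrix(ratings)
  stopifnot(ncol(ratings) >= 2)
  m_u <- rowSums(!is.na(ratings))
  if (!any(m_u >= 2)) stop("need at least one unit with >= 2 ratings")
  vals <- sort(unique(stats::na.omit(as.vector(ratings))))
  k <- length(vals)
  O <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in which(m_u >= 2)) {
    r <- stats::na.omit(as.numeric(ratings[u, ]))
    idx <- match(r, vals)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i != j) O[idx[i], idx[j]] <- O[idx[i], idx[j]] + 1 / (m_u[u] - 1)
    }
  }
  n_c <- rowSums(O)
  n <- sum(n_c)
  delta <- .alpha_delta(vals, n_c, level)
  Do <- sum(O * delta) / n
  De <- sum(outer(n_c, n_c) * delta) / (n * (n - 1))
  if (De <= .Machine$double.eps) {
    warning("zero expected disagreement; alpha = 1 by convention")
    return(1)
  }
  1 - Do / De
}

.alpha_delta <- function(vals, n_c, level) {
  k <- length(vals)
  if (level == "nominal") {
    delta <- 1 - diag(k)
  } else if (level == "interval") {
    delta <- outer(vals, vals, function(a, b) (a - b)^2)
  } else {  # ordinal: squared sums of coincidence margins between ranks
    delta <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      lo <- min(i, j); hi <- max(i, j)
      delta[i, j] <- (sum(n_c[lo:hi]) - (n_c[lo] + n_c[hi]) / 2)^2
    }
  }
  delta
}

#' Weighted Cohen's kappa
#'
#' Two-rater chance-corrected agreement on a shared ordinal scale:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with disagreement weights
#' `w_ij = |i - j| / (k - 1)` (linear) or its square (quadratic) and the
#' marginal-product expectation `E`.
#'
#' @param a,b Equal-length paired rating vectors.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param categories Optional full ordered category set (defaults to the
#'   values observed in either vector).
#' @return Kappa in \[-1, 1\]; degenerate marginals with perfect agreement
#'   return 1 with a warning.
#' @export
weighted_kappa <- function(a, b, weights = c("linear", "quadratic"),
                           categories = NULL) {
  weights <- match.arg(weights)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  k <- length(categories)
  ia <- match(a, categories); ib <- match(b, categories)
  stopifnot(!anyNA(ia), !anyNA(ib))
  n <- length(a)
  O <- matrix(0, k, k)
  for (t in seq_len(n)) O[ia[t], ib[t]] <- O[ia[t], ib[t]] + 1
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / max(1, k - 1)
  if (weights == "quadratic") w <- w^2
  E <- outer(rowSums(O), colSums(O)) / n
  denom <- sum(w * E)
  if (denom <= .Machine$double.eps) {
    warning("degenerate marginals; kappa = 1 by convention")
    return(1)
  }
  1 - sum(w * O) / denom
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way, absolute-agreement, single-measure intraclass correlation from
#' the mean-square decomposition of a subjects x raters table, with a
#' Satterthwaite-style F confidence interval (the McGraw--Wong convention
#' for this estimand).
#'
#' @param a,b Paired numeric score vectors (n >= 3).
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high`, `ms` (mean squares).
#'   Zero total variance yields `NA` values with a warning.
#' @export
icc_a1 <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  x <- cbind(a[ok], b[ok])
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 3)
  if (stats::var(as.vector(x)) <= .Machine$double.eps) {
    warning("zero total variance; ICC undefined")
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ms = NULL))
  }
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha2 <- (1 - conf_level) / 2
  r <- max(icc, .Machine$double.eps)
  aa <- k * r / (n * (1 - r))
  bb <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (aa * MSC + bb * MSE)^2 /
    ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha2, n - 1, v)
  FU <- stats::qf(1 - alpha2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci_low = min(lo, hi, icc), ci_high = max(lo, hi, icc),
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}

#' Diagnostic concordance of binary classifications
#'
#' Accuracy, sensitivity (positive recall) and specificity (negative
#' recall) of predicted against reference diagnoses, as percentages. When
#' continuous scores are supplied instead of labels for the prediction,
#' the rank-statistic AUC (Mann--Whitney) is also reported.
#'
#' @param reference Reference labels (logical or the positive level given
#'   by `positive`).
#' @param predicted Predicted labels on the same coding.
#' @param scores Optional continuous predictor scores for AUC (larger =
#'   more positive).
#' @param positive The positive (neglect) level, default `"N+"`.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent;
#'   `NA` when the reference lacks the class), `table`, and `auc`.
#' @export
diagnostic_concordance <- function(reference, predicted, scores = NULL,
                                   positive = "N+") {
  to_log <- function(x) if (is.logical(x)) x else x == positive
  ref <- to_log(reference); pred <- to_log(predicted)
  stopifnot(length(ref) == length(pred))
  tp <- sum(ref & pred); fn <- sum(ref & !pred)
  fp <- sum(!ref & pred); tn <- sum(!ref & !pred)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / length(ref)
  auc <- NA_real_
  if (!is.null(scores) && any(ref) && any(!ref)) {
    r <- rank(scores)
    n1 <- sum(ref)
    auc <- (sum(r[ref]) - n1 * (n1 + 1) / 2) / (n1 * sum(!ref))
  }
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       table = matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(reference = c("pos", "neg"),
                                      predicted = c("pos", "neg"))),
       auc = auc)
}

#' Full score concordance between two raters/pipelines
#'
#' The comparison bundle used to validate automated against reference
#' scores: exact agreement and within-one-point agreement (percent), mean
#' absolute difference, ICC(A,1) with confidence interval, weighted kappa,
#' and Kendall's tau (tau-b, tie-corrected).
#'
#' @param a,b Paired numeric score vectors.
#' @param kappa_weights Weighting for [weighted_kappa()].
#' @return List of class `concordance_result`.
#' @export
score_concordance <- function(a, b, kappa_weights = "linear") {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  icc <- tryCatch(icc_a1(a, b), warning = function(w)
    list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  tau <- suppressWarnings(stats::cor(a, b, method = "kendall"))
  structure(list(n = length(a),
                 exact_agreement = 100 * mean(a == b),
                 within_one = 100 * mean(abs(a - b) <= 1),
                 mean_abs_diff = mean(abs(a - b)),
                 icc = icc$icc, icc_ci = c(icc$ci_low, icc$ci_high),
                 weighted_kappa = tryCatch(
                   weighted_kappa(a, b, kappa_weights),
                   warning = function(w) 1),
                 kendall_tau = tau),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  cat(sprintf("  n = %d; exact %.2f%%; within +/-1 %.2f%%; MAD %.3f\n",
              x$n, x$exact_agreement, x$within_one, x$mean_abs_diff))
  cat(sprintf("  ICC(A,1) %.3f [%.3f, %.3f]; weighted kappa %.3f; tau %.3f\n",
              x$icc, x$icc_ci[1], x$icc_ci[2], x$weighted_kappa,
              x$kendall_tau))
  invisible(x)
}

#' Compare two CSV score files
#'
#' Joins two score tables on an ID column and computes [score_concordance()]
#' per shared numeric column, writing an optional JSON report shaped like a
#' per-subtest agreement table.
#'
#' @param file_a,file_b CSV paths.
#' @param id_col Shared identifier column.
#' @param out Optional JSON output path.
#' @return Named list of `concordance_result`s, invisibly when `out` is
#'   given.
#' @export
compare_score_files <- function(file_a, file_b, id_col = "patient_id",
                                out = NULL) {
  a <- utils::read.csv(file_a, stringsAsFactors = FALSE)
  b <- utils::read.csv(file_b, stringsAsFactors = FALSE)
  stopifnot(id_col %in% names(a), id_col %in% names(b))
  m <- merge(a, b, by = id_col, suffixes = c(".a", ".b"))
  shared <- intersect(setdiff(names(a), id_col), setdiff(names(b), id_col))
  res <- list()
  for (col in shared) {
    va <- suppressWarnings(as.numeric(m[[paste0(col, ".a")]]))
    vb <- suppressWarnings(as.numeric(m[[paste0(col, ".b")]]))
    if (all(is.na(va)) || all(is.na(vb))) next
    res[[col]] <- score_concordance(va, vb)
  }
  if (!is.null(out)) {
    jsonlite::write_json(lapply(res, unclass), out, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    return(invisible(res))
  }
  res
}
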