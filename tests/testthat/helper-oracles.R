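# Independent brute-force oracles used to validate the package's
# statistics and scoring arithmetic. These are written from the defining
# formulas (explicit loops over rating pairs, base-R ANOVA), not by
# sharing code with the implementation.

# --- Krippendorff's alpha: token-pair enumeration ------------------------
bf_alpha <- function(mat, level = "ordinal") {
  mat <- as.matrix(mat)
  keep <- rowSums(!is.na(mat)) >= 2
  mat <- mat[keep, , drop = FALSE]
  pooled <- stats::na.omit(as.vector(mat))
  vals <- sort(unique(pooled))
  n_c <- sapply(vals, function(v) sum(pooled == v))
  delta <- function(a, b) {
    if (a == b) return(0)
    if (level == "nominal") return(1)
    if (level == "interval") return((a - b)^2)
    ia <- which(vals == a); ib <- which(vals == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(n_c[lo:hi]) - (n_c[lo] + n_c[hi]) / 2)^2
  }
  num <- 0; n_pairable <- 0
  for (u in seq_len(nrow(mat))) {
    r <- stats::na.omit(as.numeric(mat[u, ]))
    m <- length(r)
    n_pairable <- n_pairable + m
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) num <- num + delta(r[i], r[j]) / (m - 1)
    }
  }
  Do <- num / n_pairable
  den <- 0
  for (g in seq_along(pooled)) for (h in seq_along(pooled)) {
    if (g != h) den <- den + delta(pooled[g], pooled[h])
  }
  De <- den / (n_pairable * (n_pairable - 1))
  if (De == 0) return(1)
  1 - Do / De
}

# --- weighted kappa: agreement-weight po/pe form -------------------------
bf_weighted_kappa <- function(a, b, weights = "linear") {
  cats <- sort(unique(c(a, b)))
  k <- length(cats)
  wfun <- function(i, j) {
    d <- abs(i - j) / (k - 1)
    if (weights == "quadratic") 1 - d^2 else 1 - d
  }
  n <- length(a)
  ia <- match(a, cats); ib <- match(b, cats)
  po <- mean(mapply(wfun, ia, ib))
  pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pe <- pe + wfun(i, j) * sum(ia == i) * sum(ib == j) / n^2
  }
  if (1 - pe == 0) return(1)
  (po - pe) / (1 - pe)
}

# --- ICC(A,1): base-R two-way ANOVA route --------------------------------
bf_icc_a1 <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# --- Kendall tau-b: explicit pair counting -------------------------------
bf_tau_b <- function(a, b) {
  n <- length(a)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(a[j] - a[i]); dy <- sign(b[j] - b[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# --- bisection band lookup oracle ----------------------------------------
oracle_zone <- function(offset, half, fractions) {
  ad <- abs(offset)
  if (ad <= fractions[1] * half) 3L
  else if (ad <= fractions[2] * half) 2L
  else if (ad <= fractions[3] * half) 1L
  else 0L
}

# --- rule evaluation of true diamond geometry ----------------------------
oracle_diamond_score <- function(truth, config = pipeline_config(),
                                 criteria = diamond_criteria()) {
  gap_missing <- length(truth$copy$gapped_edges) > 0 &&
    truth$copy$gap_width > config$closure_gap_max
  shape <- as.integer(!gap_missing)
  detail <- as.integer(isTRUE(truth$copy$midline))
  viol <- sum(abs(truth$copy$angles - criteria$expected_half_angle) >
                criteria$angle_tolerance + criteria$angle_epsilon)
  if (!detail) viol <- 4L   # no midline, no measurable angles
  arrangement <- as.integer(viol <= criteria$max_violations_allowed)
  c(shape = shape, detail = detail, arrangement = arrangement)
}

# --- convenience: render + score one synthetic sheet ---------------------
score_synthetic <- function(subtest, severity = 0, seed = 1,
                            response = list(), corruption = list(),
                            config = pipeline_config()) {
  sp <- synthetic_spec(subtest, severity = severity, seed = seed,
                       response = response, corruption = corruption)
  sh <- render_sheet(sp)
  list(scored = score_sheet(sh$sheet, sh$template, config),
       truth = sh$truth, template = sh$template, sheet = sh$sheet)
}
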