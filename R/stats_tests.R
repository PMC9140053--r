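# Statistical comparisons for the repeated-scan protocol: paired t-test,
# repeated-measures one-way ANOVA with Greenhouse-Geisser correction,
# Tukey's multiple comparisons on the within-subject error term, and
# Pearson correlation of log speeds with MAP.

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' degenerate zero-variance case: identical vectors give `t = 0, p = 1`;
#' constant non-zero differences are flagged and reported with `p = 0`.
#'
#' @param x,y paired numeric vectors of equal length `n >= 2`.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 2,
              "x and y must be paired with n >= 2")
  d <- x - y
  if (stats::sd(d) < 1e-12 * max(abs(mean(d)), 1)) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

# Within-subject one-way ANOVA sums of squares for an n x k matrix.
rm_anova_ss <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- Y - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  list(ss_cond = ss_cond, ss_err = ss_err,
       ms_cond = ss_cond / (k - 1), ms_err = ss_err / ((n - 1) * (k - 1)))
}

#' Repeated-measures one-way ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F-test of the condition effect with degrees of freedom
#' scaled by the Greenhouse-Geisser epsilon computed from the condition
#' covariance matrix via orthonormal contrasts:
#' `eps = tr(M)^2 / ((k-1) * sum(M^2))` with `M = C S C'`. Epsilon lies in
#' `[1/(k-1), 1]` and equals 1 under sphericity (in particular for k = 2).
#'
#' @param data n x k numeric matrix or data.frame: n subjects (rows) by
#'   k repeated conditions (columns); complete cases required.
#' @return list with `F`, `df1`, `df2` (GG-corrected), `epsilon`, `p`,
#'   `uncorrected_df = c(k-1, (n-1)(k-1))`, `flagged` (TRUE for constant
#'   data, where F is undefined).
#' @export
rm_anova_gg <- function(data) {
  Y <- as.matrix(data)
  stop_if_not(nrow(Y) >= 2 && ncol(Y) >= 2, "need n >= 2 subjects, k >= 2 conditions")
  stop_if_not(all(is.finite(Y)), "complete (finite) data required")
  n <- nrow(Y); k <- ncol(Y)
  ss <- rm_anova_ss(Y)
  if (ss$ss_err == 0 && ss$ss_cond == 0) {
    return(list(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                epsilon = NA_real_, p = NA_real_,
                uncorrected_df = c(k - 1, (n - 1) * (k - 1)), flagged = TRUE))
  }
  S <- stats::cov(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))   # k x (k-1), orthonormal contrasts
  M <- t(C) %*% S %*% C
  denom <- sum(M^2)
  eps <- if (denom <= 0) 1 else (sum(diag(M))^2) / ((k - 1) * denom)
  eps <- min(1, max(1 / (k - 1), eps))
  Fv <- ss$ms_cond / ss$ms_err
  df1 <- eps * (k - 1)
  df2 <- eps * (k - 1) * (n - 1)
  list(F = Fv, df1 = df1, df2 = df2, epsilon = eps,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       uncorrected_df = c(k - 1, (n - 1) * (k - 1)), flagged = FALSE)
}

#' Tukey's multiple comparisons for repeated measures
#'
#' All pairwise condition comparisons using the studentized-range
#' distribution on the within-subject error mean square, with
#' `df = (n-1)(k-1)`.
#'
#' @param data n x k matrix as in [rm_anova_gg()].
#' @param pairs optional 2-column matrix of condition index pairs; default
#'   all pairs.
#' @return data.frame with `i`, `j`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(data, pairs = NULL) {
  Y <- as.matrix(data)
  stop_if_not(nrow(Y) >= 2 && ncol(Y) >= 2, "need n >= 2 subjects, k >= 2 conditions")
  n <- nrow(Y); k <- ncol(Y)
  ss <- rm_anova_ss(Y)
  if (is.null(pairs)) pairs <- t(utils::combn(k, 2))
  m <- colMeans(Y)
  se <- sqrt(ss$ms_err / n)
  df_err <- (n - 1) * (k - 1)
  d <- m[pairs[, 2]] - m[pairs[, 1]]
  if (ss$ms_err == 0) {
    p <- ifelse(d == 0, 1, 0)
    return(data.frame(i = pairs[, 1], j = pairs[, 2], diff = d,
                      q = ifelse(d == 0, 0, Inf), p_adj = p))
  }
  q <- abs(d) / se
  data.frame(i = pairs[, 1], j = pairs[, 2], diff = unname(d), q = unname(q),
             p_adj = stats::ptukey(q, k, df_err, lower.tail = FALSE))
}

#' Squared Pearson correlation of log speeds with MAP
#'
#' @param map_values MAP values (mmHg), `n >= 3`.
#' @param log_speeds log-transformed speeds, same length.
#' @return list with `r2`, `r`, `p`, `flagged` (TRUE when either variable
#'   has zero variance, where the correlation is undefined).
#' @export
pearson_log <- function(map_values, log_speeds) {
  stop_if_not(length(map_values) == length(log_speeds) && length(map_values) >= 3,
              "need n >= 3 pairs")
  if (stats::sd(map_values) == 0 || stats::sd(log_speeds) == 0)
    return(list(r2 = NA_real_, r = NA_real_, p = NA_real_, flagged = TRUE))
  ct <- stats::cor.test(map_values, log_speeds, method = "pearson")
  list(r2 = unname(ct$estimate)^2, r = unname(ct$estimate),
       p = ct$p.value, flagged = FALSE)
}

#' Simulate per-subject bed scan means
#'
#' Generates subject-level mean speeds for the three scans around commanded
#' scan means, with a multiplicative subject random effect and residual
#' scan-level noise on the transformed scale (log for cortical beds, sqrt
#' for medullary beds). Used for power properties of the repeated-measures
#' analysis at realistic between/within-subject dispersions.
#'
#' @param scan_means length-3 vector of commanded scan means (mm/s).
#' @param n_subjects number of subjects (default 7).
#' @param sigma_subject between-subject sd on the transformed scale.
#' @param sigma_resid within-subject residual sd on the transformed scale.
#' @param region region of the bed (sets the transform).
#' @param seed optional RNG seed.
#' @return n_subjects x 3 matrix of speeds (mm/s).
#' @export
simulate_subject_means <- function(scan_means, n_subjects = 7,
                                   sigma_subject = 0.15, sigma_resid = 0.15,
                                   region = "cortex", seed = NULL) {
  stop_if_not(length(scan_means) == 3, "scan_means must have length 3")
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_subjects, 0, sigma_subject)
  e <- matrix(stats::rnorm(n_subjects * 3, 0, sigma_resid), n_subjects, 3)
  if (region == "cortex") {
    exp(outer(b, log(scan_means), "+") + e)
  } else {
    (pmax(0, outer(b, sqrt(scan_means), "+") + e))^2
  }
}
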