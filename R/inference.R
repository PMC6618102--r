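#' JZS Bayes factor from a t-statistic
#'
#' One-sample Jeffreys-Zellner-Siow Bayes factor (alternative over point
#' null) computed from a t-statistic: a Cauchy prior with scale `scale` on
#' standardised effect size, equivalently a normal prior on the effect with
#' inverse-gamma(1/2, scale^2/2) mixing variance g, integrated by adaptive
#' quadrature. The default scale is `sqrt(0.5)`. `BF10` is symmetric in the
#' sign of `t` and monotone increasing in `|t|`.
#'
#' @param t Observed t-statistic (finite).
#' @param n Effective sample size; degrees of freedom are `n - 1`.
#' @param scale Cauchy prior scale on effect size (default `sqrt(0.5)`).
#' @return An `osc_bf` list: `bf10`, `t`, `df`, `n`, `scale`.
#' @examples
#' jzs_bf_from_t(-0.22, 20)         # ~0.24, evidence for a null intercept
#' jzs_bf_from_t(sqrt(10.22), 19)   # ~9.30
#' @export
jzs_bf_from_t <- function(t, n, scale = sqrt(0.5)) {
  if (!is.finite(t)) stop("non-finite t-statistic", call. = FALSE)
  stopifnot(n >= 2, scale > 0)
  nu <- n - 1
  r2 <- scale^2
  # BF10 = int (1+ng)^(-1/2) * [ (1+t^2/nu) / (1+t^2/((1+ng)nu)) ]^((nu+1)/2)
  #        * dInvGamma(g; 1/2, r^2/2) dg  -- the (1+t^2/nu) factor from the
  # null likelihood is pulled inside; the integral is evaluated in log
  # space (peak factored out) so extreme t-statistics stay finite.
  log_f <- function(g) {
    -0.5 * log1p(n * g) +
      (nu + 1) / 2 * (log1p(t^2 / nu) - log1p(t^2 / ((1 + n * g) * nu))) +
      log(scale) - 0.5 * log(2 * pi) - 1.5 * log(g) - r2 / (2 * g)
  }
  peak <- max(log_f(10^seq(-8, 8, length.out = 400)))
  val <- stats::integrate(function(g) exp(log_f(g) - peak), 0, Inf,
                          rel.tol = 1e-8, subdivisions = 400L)$value
  log_bf <- peak + log(val)
  structure(list(bf10 = exp(log_bf), log_bf10 = log_bf, t = t, df = nu,
                 n = n, scale = scale),
            class = "osc_bf")
}

#' @export
print.osc_bf <- function(x, ...) {
  cat(sprintf("JZS Bayes factor: BF10 = %.4g (t = %.3f, df = %d, scale = %.3f)\n",
              x$bf10, x$t, x$df, x$scale))
  invisible(x)
}

#' Chauvenet's criterion for outlier exclusion
#'
#' Excludes any value whose expected count of equally or more extreme
#' observations under a normal fit, `N * P(|Z| >= |z|)`, falls below the
#' criterion. Applied once, non-iteratively; a zero-variance sample
#' excludes nothing.
#'
#' @param values Numeric vector (>= 3 finite values).
#' @param criterion Exclusion criterion (default 0.5).
#' @return Logical inclusion mask (`TRUE` = keep).
#' @examples
#' chauvenet(c(rep(0, 9), 10))  # the 10 is excluded
#' @export
chauvenet <- function(values, criterion = 0.5) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  z <- abs(values - mean(values)) / s
  length(values) * 2 * stats::pnorm(-z) >= criterion
}

#' Within-subject ANCOVA (participants partialled out)
#'
#' Fits `y ~ x + participant` (participants as a categorical covariate),
#' giving the common within-subject slope, its F test on
#' `(1, N - k - 1)` degrees of freedom, and the within-subject correlation
#' from the partial sums of squares. Per-participant intercepts under the
#' common slope (`mean(y_i) - b * mean(x_i)`) are tested against zero with
#' a one-sample t (df `k - 1`), with a JZS Bayes factor attached. With a
#' single participant the model reduces to ordinary regression.
#'
#' The slope Bayes factor uses `nu = N - k - 1` (the slope's residual
#' degrees of freedom) as its effective sample size basis; this choice is
#' reported alongside the value because a t-statistic from a partialled
#' regression has no unique one-sample-equivalent N. No Bayes factor is
#' computed for the participant factor (an F with k - 1 numerator df has
#' no JZS t equivalent).
#'
#' @param x,y Numeric vectors (the covariate and response).
#' @param participant_labels Participant id per observation; every
#'   participant needs at least 3 pairs.
#' @param scale Prior scale for the Bayes factors.
#' @return An `osc_ancova` list: `slope`, `slope_se`, `slope_t`,
#'   `slope_df` (c(1, N-k-1)), `slope_p`, `slope_bf`, `r` (signed
#'   within-subject correlation), `intercepts`, `intercept_mean`,
#'   `intercept_se`, `intercept_t`, `intercept_df`, `intercept_p`,
#'   `intercept_bf`, `participant_f`, `participant_df`, `participant_p`,
#'   `participant_bf` (NA, with note), `n_obs`, `n_participants`.
#' @export
within_subject_ancova <- function(x, y, participant_labels, scale = sqrt(0.5)) {
  stopifnot(length(x) == length(y), length(x) == length(participant_labels))
  id <- factor(participant_labels)
  k <- nlevels(id)
  if (any(table(id) < 3)) {
    stop("every participant needs at least 3 (x, y) pairs", call. = FALSE)
  }
  n_obs <- length(x)
  if (k > 1) {
    m0 <- stats::lm(y ~ id)
    m1 <- stats::lm(y ~ id + x)
  } else {
    m0 <- stats::lm(y ~ 1)
    m1 <- stats::lm(y ~ x)
  }
  if (any(is.na(stats::coef(m1)))) stop("rank-deficient design", call. = FALSE)
  cmp <- stats::anova(m0, m1)
  ss_x <- cmp$`Sum of Sq`[2]
  ss_res <- cmp$RSS[2]
  df_res <- cmp$Res.Df[2]  # N - k - 1 (or N - 2 for one participant)
  f_slope <- cmp$F[2]
  p_slope <- cmp$`Pr(>F)`[2]
  b <- stats::coef(m1)[["x"]]
  se_b <- summary(m1)$coefficients["x", "Std. Error"]
  r <- sign(b) * sqrt(ss_x / (ss_x + ss_res))
  slope_bf <- jzs_bf_from_t(b / se_b, n = df_res + 1, scale = scale)

  # participant factor adjusted for x
  if (k > 1) {
    cmp_p <- stats::anova(stats::lm(y ~ x), m1)
    f_part <- cmp_p$F[2]
    p_part <- cmp_p$`Pr(>F)`[2]
    df_part <- c(k - 1, df_res)
  } else {
    f_part <- NA_real_; p_part <- NA_real_; df_part <- c(NA, NA)
  }

  ybar <- tapply(y, id, mean)
  xbar <- tapply(x, id, mean)
  intercepts <- as.vector(ybar - b * xbar)
  if (k > 1) {
    int_se <- stats::sd(intercepts) / sqrt(k)
    y_scale <- max(stats::sd(y), .Machine$double.eps)
    if (max(abs(intercepts)) <= 1e-10 * y_scale) {
      # exact fit: intercepts are numerical zeros relative to the data
      int_t <- 0; int_p <- 1
      int_bf <- jzs_bf_from_t(0, n = k, scale = scale)
    } else if (int_se <= 1e-12 * max(abs(intercepts))) {
      # all intercepts numerically equal but nonzero
      int_t <- sign(mean(intercepts)) * Inf
      int_p <- 0
      int_bf <- NULL
    } else {
      tt <- stats::t.test(intercepts)
      int_t <- unname(tt$statistic); int_p <- tt$p.value
      int_bf <- jzs_bf_from_t(int_t, n = k, scale = scale)
    }
  } else {
    int_t <- NA_real_; int_p <- NA_real_; int_se <- NA_real_; int_bf <- NULL
  }

  structure(list(slope = b, slope_se = se_b, slope_t = b / se_b,
                 slope_df = c(1, df_res), slope_p = p_slope, slope_f = f_slope,
                 slope_bf = slope_bf, r = r,
                 intercepts = intercepts, intercept_mean = mean(intercepts),
                 intercept_se = int_se, intercept_t = int_t,
                 intercept_df = k - 1, intercept_p = int_p,
                 intercept_bf = int_bf,
                 participant_f = f_part, participant_df = df_part,
                 participant_p = p_part,
                 participant_bf = NA_real_,
                 notes = c("participant-factor BF not computed: no JZS t-equivalent for a multi-df F",
                           "slope BF effective N = residual df + 1 (reported, not unique)"),
                 n_obs = n_obs, n_participants = k),
            class = "osc_ancova")
}

#' @export
print.osc_ancova <- function(x, ...) {
  cat("Within-subject ANCOVA (participants partialled out)\n")
  cat(sprintf("  slope = %.4f (SE %.4f), r = %.3f, F(%d,%d) = %.2f, p = %.3g, BF10 = %.3g\n",
              x$slope, x$slope_se, x$r, x$slope_df[1], x$slope_df[2],
              x$slope_f, x$slope_p, x$slope_bf$bf10))
  if (!is.na(x$intercept_t)) {
    cat(sprintf("  intercept = %.4f (SE %.4f), T%d = %.2f, p = %.3g, BF10 = %.3g\n",
                x$intercept_mean, x$intercept_se, x$intercept_df,
                x$intercept_t, x$intercept_p, x$intercept_bf$bf10))
    cat(sprintf("  participant factor F(%d,%d) = %.2f, p = %.3g (BF not computed)\n",
                x$participant_df[1], x$participant_df[2], x$participant_f,
                x$participant_p))
  }
  invisible(x)
}

#' Repeated-measures ANOVA for the matched/unmatched entrainment table
#'
#' Two-way repeated-measures ANOVA with factors condition (matched vs
#' unmatched, 2 levels) and presentation frequency (12 levels) on a
#' complete participant x condition x frequency amplitude table. The main
#' effect of condition is tested on `(1, n - 1)` df and the interaction on
#' `(11, 11 (n - 1))` df; a JZS Bayes factor for the main effect is
#' computed from `t = sign(matched - unmatched) * sqrt(F)` with `n`
#' participants.
#'
#' @param amplitude_table Long data frame with columns `participant`,
#'   `condition` (two levels; `"matched"`/`"unmatched"`), `frequency`, and
#'   `amplitude`; must be complete (no missing cells).
#' @param scale Prior scale for the Bayes factor.
#' @return List with `f_main`, `df_main`, `p_main`, `bf_main`,
#'   `f_interaction`, `df_interaction`, `p_interaction`,
#'   `mean_difference` (matched - unmatched), `n_participants`.
#' @export
rm_anova_2x12 <- function(amplitude_table, scale = sqrt(0.5)) {
  d <- amplitude_table
  stopifnot(all(c("participant", "condition", "frequency", "amplitude") %in% names(d)))
  d$participant <- factor(d$participant)
  d$condition <- factor(d$condition)
  d$frequency <- factor(d$frequency)
  counts <- table(d$participant, d$condition, d$frequency)
  if (any(counts != 1)) stop("missing cells in the amplitude table", call. = FALSE)
  n <- nlevels(d$participant)
  nf <- nlevels(d$frequency)
  fit <- stats::aov(amplitude ~ condition * frequency +
                      Error(participant / (condition * frequency)), data = d)
  s <- summary(fit)
  get_row <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    i <- i[trimws(rownames(tab))[i] == term]
    tab[i, , drop = FALSE]
  }
  main <- get_row("Error: participant:condition", "condition")
  inter <- get_row("Error: participant:condition:frequency", "condition:frequency")
  f_main <- main[1, "F value"]
  p_main <- main[1, "Pr(>F)"]
  # identical conditions give 0/0 numerics; report F = 0 exactly
  if (main[1, "Sum Sq"] <= 1e-12 * stats::var(d$amplitude) * (nrow(d) - 1)) {
    f_main <- 0
    p_main <- 1
  }
  mm <- tapply(d$amplitude, d$condition, mean)
  dirn <- if ("matched" %in% names(mm)) {
    sign(mm[["matched"]] - mm[[setdiff(names(mm), "matched")[1]]])
  } else sign(mm[[1]] - mm[[2]])
  bf <- jzs_bf_from_t(dirn * sqrt(f_main), n = n, scale = scale)
  list(f_main = f_main, df_main = c(1, n - 1),
       p_main = p_main, bf_main = bf,
       f_interaction = inter[1, "F value"],
       df_interaction = c(nf - 1, (nf - 1) * (n - 1)),
       p_interaction = inter[1, "Pr(>F)"],
       mean_difference = if ("matched" %in% names(mm))
         mm[["matched"]] - mm[[setdiff(names(mm), "matched")[1]]]
       else mm[[1]] - mm[[2]],
       n_participants = n)
}
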