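#' Circular mean and resultant length
#'
#' Mean direction (argument) and mean resultant length (modulus) of the
#' mean unit vector of a set of angles.
#'
#' @param angles Numeric vector of angles in radians.
#' @return List with `mean` (radians in (-pi, pi]; `NA` when the resultant
#'   length is numerically zero and the mean direction is undefined) and
#'   `r` (mean resultant length in [0, 1]).
#' @examples
#' circ_mean(c(0, pi / 2))  # mean pi/4, r = cos(pi/4)
#' @export
circ_mean <- function(angles) {
  if (!length(angles)) stop("empty set of angles", call. = FALSE)
  s <- mean(sin(angles)); c <- mean(cos(angles))
  r <- sqrt(s^2 + c^2)
  list(mean = if (r < 1e-12) NA_real_ else atan2(s, c), r = r)
}

#' Phase-locking value across trials
#'
#' Modulus of the mean unit phasor `|mean(exp(i * theta))|` across trials:
#' 1 for perfectly aligned phase angles, approaching 0 as consistency is
#' lost (expectation about `sqrt(pi / (4 N))` under uniform phases).
#'
#' @param phase_set Angles in radians: a vector (one PLV), or a
#'   trials-by-time matrix (one PLV per time point / column).
#' @return Scalar or per-column numeric vector in [0, 1].
#' @export
plv <- function(phase_set) {
  if (is.null(dim(phase_set))) {
    if (!length(phase_set)) stop("empty phase set", call. = FALSE)
    return(sqrt(mean(sin(phase_set))^2 + mean(cos(phase_set))^2))
  }
  if (!nrow(phase_set)) stop("empty phase set", call. = FALSE)
  sqrt(colMeans(sin(phase_set))^2 + colMeans(cos(phase_set))^2)
}

circ_result <- function(method, statistic, stat_name, p, mean_angle, r, n,
                        flags = character(), extra = list()) {
  structure(c(list(method = method, statistic = stats::setNames(statistic, stat_name),
                   p.value = p, mean_angle = mean_angle, r = r, n = n,
                   flags = flags), extra),
            class = "osc_circtest")
}

#' @export
print.osc_circtest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4f, p = %.4g, n = %s\n", names(x$statistic),
              x$statistic, x$p.value, paste(x$n, collapse = "+")))
  if (!is.na(x$mean_angle)) {
    cat(sprintf("  mean angle %.3f rad, resultant length %.3f\n", x$mean_angle, x$r))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests phase consistency (unimodal concentration) against uniformity:
#' `z = n * rbar^2`, with the standard large-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (n rbar)^2)) - (1 + 2n))`.
#'
#' @param angles Angles in radians.
#' @return An `osc_circtest` with statistic `z`, p-value, mean angle and
#'   resultant length. Samples with fewer than 4 angles are flagged
#'   `"small_n"` with a warning.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (!n) stop("empty set of angles", call. = FALSE)
  flags <- character()
  if (n < 4) {
    warning("Rayleigh test with n < 4 is unreliable", call. = FALSE)
    flags <- "small_n"
  }
  cm <- circ_mean(angles)
  z <- n * cm$r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * cm$r)^2)) - (1 + 2 * n))
  circ_result("Rayleigh test of circular uniformity", z, "z",
              min(p, 1), cm$mean, cm$r, n, flags)
}

# Fisher's approximation of the inverse of A(kappa) = I1/I0.
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Parametric k-sample comparison of circular mean angles (Zar's
#' formulation with the `1 + 3/(8 kappa)` correction). The test assumes
#' adequate, homogeneous concentration; when the weighted mean resultant
#' length falls below 0.45, or group concentrations look heterogeneous,
#' the result is flagged and a nonparametric [watson_u2()] comparison is
#' recommended instead.
#'
#' @param groups List of angle vectors (radians), each with at least 5
#'   observations; at least two groups.
#' @return An `osc_circtest` with an F statistic, p-value and assumption
#'   flags (`"low_concentration"`, `"heterogeneous_concentration"`,
#'   `"recommend_watson_u2"`).
#' @export
watson_williams <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 5)) stop("each group needs at least 5 angles", call. = FALSE)
  k <- length(groups)
  N <- sum(ns)
  cms <- lapply(groups, circ_mean)
  Ri <- vapply(seq_len(k), function(i) ns[i] * cms[[i]]$r, numeric(1))
  pooled <- circ_mean(unlist(groups))
  R <- N * pooled$r
  rw <- sum(Ri) / N
  kappa <- a1inv(rw)
  flags <- character()
  if (rw < 0.45) flags <- c(flags, "low_concentration")
  rbars <- vapply(cms, `[[`, numeric(1), "r")
  kap_g <- vapply(rbars, a1inv, numeric(1))
  if (max(kap_g) > 2 * max(min(kap_g), 1e-6)) {
    flags <- c(flags, "heterogeneous_concentration")
  }
  if (length(flags)) flags <- c(flags, "recommend_watson_u2")
  correction <- 1 + 3 / (8 * kappa)
  f <- correction * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  f <- max(f, 0)
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  circ_result("Watson-Williams test for equal circular means", f, "F", p,
              pooled$mean, pooled$r, ns, flags,
              extra = list(df = c(k - 1, N - k), kappa = kappa))
}

# Two-sample Watson U^2 statistic, cumulative-fraction form with tie
# handling: at each distinct combined value, d = F1 - F2 and the squared
# deviations are weighted by the tie multiplicity, so identical samples
# give exactly 0.
u2_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  N <- n1 + n2
  vals <- c(a, b)
  step <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  ord <- order(vals)
  v <- vals[ord]
  d <- cumsum(step[ord])
  last <- c(v[-1] != v[-N], TRUE)   # last index within each tie group
  dk <- d[last]
  tk <- diff(c(0L, which(last)))    # tie multiplicities
  dbar <- sum(tk * dk) / N
  n1 * n2 / N^2 * sum(tk * (dk - dbar)^2)
}

#' Watson's U2 two-sample test with a permutation null
#'
#' Nonparametric comparison of two circular samples via Watson's U-squared
#' statistic on the ranked circular CDFs, with a permutation p-value
#' `p = (1 + #{permuted U2 >= observed}) / (n_permutations + 1)`. When the
#' samples are paired (equal lengths, `paired = TRUE` by default in that
#' case) permutation swaps condition labels within each pair, matching a
#' within-participant design; otherwise labels are reshuffled over the
#' pooled sample.
#'
#' @param angles_a,angles_b Angle vectors in radians (nonempty).
#' @param n_permutations Number of label permutations (default 5000).
#' @param seed Integer seed for the permutation draw.
#' @param paired Swap labels within pairs (requires equal lengths).
#' @return An `osc_circtest` with statistic `U2` and the permutation
#'   p-value (never below `1 / (n_permutations + 1)`).
#' @export
watson_u2 <- function(angles_a, angles_b, n_permutations = 5000, seed = NULL,
                      paired = length(angles_a) == length(angles_b)) {
  if (!length(angles_a) || !length(angles_b)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (paired && length(angles_a) != length(angles_b)) {
    stop("paired permutation requires equal sample sizes", call. = FALSE)
  }
  obs <- u2_stat(angles_a, angles_b)
  n1 <- length(angles_a)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      if (paired) {
        sw <- stats::runif(n1) < 0.5
        a <- ifelse(sw, angles_b, angles_a)
        b <- ifelse(sw, angles_a, angles_b)
      } else {
        pool <- c(angles_a, angles_b)
        pick <- sample.int(length(pool), n1)
        a <- pool[pick]; b <- pool[-pick]
      }
      u2_stat(a, b)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs - 1e-15)) / (n_permutations + 1)
  circ_result("Watson's U2 two-sample test (permutation null)", obs, "U2",
              p, NA_real_, NA_real_, c(length(angles_a), length(angles_b)),
              extra = list(n_permutations = n_permutations, paired = paired))
}
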