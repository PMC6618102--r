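# Connected-component labelling of time-frequency bins. `idx` holds
# column-major bin indices into an nf x nt grid; returns one integer label
# per element of idx (labels are arbitrary but consecutive from 1).
label_components <- function(idx, nf, nt, connectivity = 8) {
  m <- length(idx)
  if (!m) return(integer(0))
  r <- ((idx - 1L) %% nf) + 1L
  cc <- ((idx - 1L) %/% nf) + 1L
  offs <- if (connectivity == 8) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  } else if (connectivity == 4) {
    list(c(1L, 0L), c(0L, 1L))
  } else stop("connectivity must be 4 or 8", call. = FALSE)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in offs) {
    nr <- r + o[1]; ncl <- cc + o[2]
    ok <- nr >= 1L & nr <= nf & ncl >= 1L & ncl <= nt
    j <- match(nr[ok] + (ncl[ok] - 1L) * nf, idx)
    from <- which(ok)[!is.na(j)]
    to <- j[!is.na(j)]
    for (e in seq_along(from)) {
      a <- find(from[e]); b <- find(to[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# Signed max cluster mass of one statistic map (vector over bins) given
# suprathreshold masks; returns 0 when nothing is suprathreshold.
max_cluster_mass <- function(stat, supra_pos, supra_neg, nf, nt, connectivity) {
  best <- 0
  for (sgn in 1:2) {
    supra <- if (sgn == 1) supra_pos else supra_neg
    idx <- which(supra)
    if (!length(idx)) next
    lab <- label_components(idx, nf, nt, connectivity)
    masses <- abs(as.vector(tapply(stat[idx], lab, sum)))
    best <- max(best, masses)
  }
  best
}

# Inventory of clusters from an observed map: data frame + member lists.
cluster_inventory <- function(stat, supra_pos, supra_neg, nf, nt, connectivity,
                              freqs = NULL, times = NULL) {
  rows <- list(); members <- list()
  for (sgn in 1:2) {
    supra <- if (sgn == 1) supra_pos else supra_neg
    idx <- which(supra)
    if (!length(idx)) next
    lab <- label_components(idx, nf, nt, connectivity)
    for (l in unique(lab)) {
      mem <- idx[lab == l]
      fr <- ((mem - 1L) %% nf) + 1L
      tc <- ((mem - 1L) %/% nf) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn == 1) "positive" else "negative",
        n_bins = length(mem), mass = sum(stat[mem]),
        freq_min = if (!is.null(freqs)) min(freqs[fr]) else min(fr),
        freq_max = if (!is.null(freqs)) max(freqs[fr]) else max(fr),
        time_min = if (!is.null(times)) min(times[tc]) else min(tc),
        time_max = if (!is.null(times)) max(times[tc]) else max(tc))
      members[[length(members) + 1L]] <- mem
    }
  }
  if (!length(rows)) {
    return(list(table = data.frame(sign = character(), n_bins = integer(),
                                   mass = numeric(), freq_min = numeric(),
                                   freq_max = numeric(), time_min = numeric(),
                                   time_max = numeric()),
                members = list()))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-abs(tab$mass))
  tab <- tab[ord, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab[, c("id", setdiff(names(tab), "id"))], members = members[ord])
}

# Per-bin paired t with an optional fixed per-bin Chauvenet mask.
# D: participants x bins difference matrix. Returns t, df and the mask.
masked_t <- function(D, criterion = 0.5) {
  n <- nrow(D); B <- ncol(D)
  keep <- matrix(TRUE, n, B)
  if (!is.null(criterion) && n >= 3) {
    m <- colMeans(D)
    s <- sqrt(pmax(colSums(D^2) - n * m^2, 0) / (n - 1))
    z <- abs(sweep(D, 2, m)) / rep(pmax(s, .Machine$double.eps), each = n)
    keep <- (2 * stats::pnorm(-z) * n) >= criterion
    keep[, s == 0] <- TRUE
  }
  nb <- colSums(keep)
  Dm <- D * keep
  ssq <- colSums(D^2 * keep)
  mu <- colSums(Dm) / pmax(nb, 1)
  v <- (ssq - nb * mu^2) / pmax(nb - 1, 1)
  tt <- ifelse(nb >= 2 & v > 0, mu / sqrt(v / pmax(nb, 1)), 0)
  list(t = tt, df = pmax(nb - 1, 1), nb = nb, keep = keep, Dm = Dm, ssq = ssq)
}

#' Maximum-cluster-mass permutation test on time-frequency maps
#'
#' Family-wise-error-controlled comparison of two paired sets of
#' time-frequency maps. A per-bin statistic is computed (paired t with
#' one-shot per-bin Chauvenet exclusion for `"paired_t"` and
#' `"plv_diff_t"`; Watson's U-squared on per-participant mean angles for
#' `"watson_u2"`), thresholded at `alpha_inclusion` (two-tailed t critical
#' value, or the per-bin permutation quantile for U-squared), connected
#' components are formed under 8-way (or 4-way) adjacency over time and
#' frequency, and each observed cluster's summed statistic is compared to
#' the permutation null of the maximum cluster mass (sign flips within
#' participants for t statistics; within-participant condition-label swaps
#' for U-squared). Cluster p-values use the `+1` correction.
#'
#' @param condition_a_maps,condition_b_maps Arrays
#'   `[participant, frequency, time]` on a common grid; amplitudes (or PLV)
#'   for the t statistics, phase angles in radians for `"watson_u2"`.
#' @param statistic `"paired_t"`, `"plv_diff_t"` or `"watson_u2"`.
#' @param n_permutations Permutations for the null (default 1000).
#' @param alpha_inclusion Per-bin inclusion threshold (default 0.05).
#' @param connectivity 8 (default) or 4.
#' @param seed Integer seed for the permutation draw.
#' @param freqs,times Optional axes (Hz, seconds) for cluster extents.
#' @param chauvenet_criterion Per-bin Chauvenet criterion for t maps
#'   (default 0.5; `NULL` disables). Computed once on the observed data,
#'   not within permutations.
#' @return An `osc_clusters` list: `clusters` (data frame with id, sign,
#'   n_bins, mass, extents, p), `members` (bin index lists), `stat_map`
#'   (frequency x time), `null_max` (permutation max-mass distribution),
#'   `settings`, `freqs`, `times`.
#' @export
cluster_permutation <- function(condition_a_maps, condition_b_maps,
                                statistic = c("paired_t", "plv_diff_t", "watson_u2"),
                                n_permutations = 1000, alpha_inclusion = 0.05,
                                connectivity = 8, seed = NULL,
                                freqs = NULL, times = NULL,
                                chauvenet_criterion = 0.5) {
  statistic <- match.arg(statistic)
  da <- dim(condition_a_maps); db <- dim(condition_b_maps)
  if (length(da) != 3 || !all(da == db)) {
    stop("grid mismatch: condition maps must share participant x frequency x time dimensions",
         call. = FALSE)
  }
  n <- da[1]; nf <- da[2]; nt <- da[3]
  B <- nf * nt
  out <- with_seed(seed, {
    if (statistic %in% c("paired_t", "plv_diff_t")) {
      D <- matrix(condition_a_maps - condition_b_maps, n, B)
      mt <- masked_t(D, chauvenet_criterion)
      thr <- stats::qt(1 - alpha_inclusion / 2, mt$df)
      supra_pos <- mt$t > thr & mt$nb >= 2
      supra_neg <- mt$t < -thr & mt$nb >= 2
      inv <- cluster_inventory(mt$t, supra_pos, supra_neg, nf, nt,
                               connectivity, freqs, times)
      # inclusion threshold indexed by retained count + 1 (df < 1 -> Inf)
      tcrit <- c(Inf, Inf, stats::qt(1 - alpha_inclusion / 2, seq_len(n - 1)))
      # Chauvenet exclusion: drop when 2 n Phi(-z) < criterion
      z_star <- if (is.null(chauvenet_criterion) || n < 3) Inf else
        stats::qnorm(1 - chauvenet_criterion / (2 * n))
      ssq_all <- colSums(D^2)                 # sign-invariant
      D2 <- D^2
      null_max <- numeric(n_permutations)
      chunk <- max(1L, min(n_permutations, floor(4e6 / B)))
      done <- 0L
      while (done < n_permutations) {
        m <- min(chunk, n_permutations - done)
        S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
        MU0 <- (S %*% D) / n
        SD0 <- sqrt(pmax(rep(ssq_all, each = m) - n * MU0^2, 0) / (n - 1))
        if (is.finite(z_star)) {
          # per-permutation Chauvenet: drop flips with |s d - mean| > z* sd
          lim <- z_star * SD0
          CNT <- matrix(0L, m, B); SUM <- matrix(0, m, B); SSQ <- matrix(0, m, B)
          for (i in seq_len(n)) {
            Mi <- S[, i] %o% D[i, ]
            keep_i <- abs(Mi - MU0) <= lim | SD0 == 0
            CNT <- CNT + keep_i
            SUM <- SUM + Mi * keep_i
            SSQ <- SSQ + keep_i * rep(D2[i, ], each = m)
          }
          nb <- pmax(CNT, 1L)
          MU <- SUM / nb
          V <- (SSQ - nb * MU^2) / pmax(nb - 1, 1)
          TP <- MU / sqrt(V / nb)
          TP[!is.finite(TP) | CNT < 2] <- 0
          THR <- matrix(tcrit[pmin(CNT, n) + 1L], m, B)
        } else {
          V <- SD0^2
          TP <- MU0 / sqrt(V / n)
          TP[!is.finite(TP)] <- 0
          THR <- matrix(tcrit[n + 1L], m, B)
        }
        for (i in seq_len(m)) {
          tp <- TP[i, ]
          null_max[done + i] <- max_cluster_mass(
            tp, tp > THR[i, ], tp < -THR[i, ], nf, nt, connectivity)
        }
        done <- done + m
      }
      list(stat = mt$t, inv = inv, null_max = null_max,
           extra = list(df = mt$df, n_excluded = n - mt$nb))
    } else {
      A <- matrix(condition_a_maps, n, B)
      Bm <- matrix(condition_b_maps, n, B)
      N2 <- 2L * n
      L <- matrix(0, N2, N2)
      L[lower.tri(L, diag = TRUE)] <- 1
      M <- cbind(1, matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                           n, n_permutations))
      U <- matrix(0, B, n_permutations + 1L)
      cond <- rep(c(0L, 1L), each = n)          # 0 = a, 1 = b
      pid <- rep(seq_len(n), 2L)
      base_sign <- 1 - 2 * cond                 # +1/-1 step direction
      for (b in seq_len(B)) {
        ang <- c(A[, b], Bm[, b])
        ord <- order(ang)
        sgn <- base_sign[ord] * M[pid[ord], , drop = FALSE]
        d <- (L %*% sgn) / n
        U[b, ] <- 0.25 * (colSums(d^2) - N2 * colMeans(d)^2)
      }
      obs <- U[, 1]
      perm <- U[, -1, drop = FALSE]
      kk <- max(1L, floor(alpha_inclusion * (n_permutations + 1)))
      thr_b <- apply(perm, 1, function(v) sort(v, decreasing = TRUE)[kk])
      p_bin <- (1 + rowSums(perm >= obs)) / (n_permutations + 1)
      supra_obs <- p_bin <= alpha_inclusion
      inv <- cluster_inventory(obs, supra_obs, rep(FALSE, B), nf, nt,
                               connectivity, freqs, times)
      null_max <- vapply(seq_len(n_permutations), function(j) {
        max_cluster_mass(perm[, j], perm[, j] >= thr_b, rep(FALSE, B),
                         nf, nt, connectivity)
      }, numeric(1))
      list(stat = obs, inv = inv, null_max = null_max,
           extra = list(bin_threshold = thr_b))
    }
  })
  tab <- out$inv$table
  tab$p <- if (nrow(tab)) {
    vapply(tab$mass, function(m)
      (1 + sum(out$null_max >= abs(m))) / (n_permutations + 1), numeric(1))
  } else numeric(0)
  structure(list(statistic = statistic, clusters = tab,
                 members = out$inv$members,
                 stat_map = matrix(out$stat, nf, nt),
                 null_max = out$null_max,
                 settings = list(n_permutations = n_permutations,
                                 alpha_inclusion = alpha_inclusion,
                                 connectivity = connectivity, seed = seed,
                                 chauvenet_criterion = chauvenet_criterion),
                 freqs = freqs, times = times, extra = out$extra),
            class = "osc_clusters")
}

#' @export
print.osc_clusters <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %d permutations, %d-way connectivity)\n",
              x$statistic, x$settings$n_permutations, x$settings$connectivity))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    df <- utils::head(x$clusters, 10)
    df$mass <- signif(df$mass, 4)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.osc_clusters <- function(x, alpha = 0.05, ...) {
  fr <- if (!is.null(x$freqs)) x$freqs else seq_len(nrow(x$stat_map))
  tm <- if (!is.null(x$times)) x$times else seq_len(ncol(x$stat_map))
  graphics::image(tm, fr, t(x$stat_map), xlab = "time (s)",
                  ylab = "frequency (Hz)", main = paste("statistic:", x$statistic),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  sig <- which(x$clusters$p <= alpha)
  for (i in sig) {
    mem <- x$members[[i]]
    nfr <- nrow(x$stat_map)
    graphics::points(tm[((mem - 1) %/% nfr) + 1], fr[((mem - 1) %% nfr) + 1],
                     pch = ".", cex = 2)
  }
  invisible(x)
}
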