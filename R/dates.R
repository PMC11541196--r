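#' Weighted ancestry-covariance decay curve
#'
#' The dating statistic: per site `s` the weight is the source frequency
#' difference `w_s = pA_s - pB_s`, and per target individual `i` the residual
#' is `r_{s,i} = g_{s,i}/2 - pbar_s` (allele dose minus the target mean
#' frequency). For every intra-chromosomal site pair at genetic distance `d`
#' the quantity `mean_i(w_s w_t r_{s,i} r_{t,i})` is accumulated into the
#' distance bin containing `d` (bin width 0.001 Morgans by default). After a
#' single admixture pulse `n` generations ago, the binned curve decays as
#' `A exp(-n d) + c`, which [fit_decay()] inverts. The statistic is invariant
#' under swapping the source labels.
#'
#' @param gm A [genotype_matrix()] with a genetic map.
#' @param target Group label of the admixed target (>= 2 individuals).
#' @param pa,pb Per-site allele frequencies of the two sources, aligned to
#'   `gm$sites` (numeric vectors; `NA` sites are dropped).
#' @param bin_morgans Bin width in Morgans (default 0.001).
#' @param max_morgans Largest pair distance retained (default 1).
#' @return An object of class `decay_curve`: data.frame `bins` (`mid`,
#'   `covariance`, `n_pairs`) plus per-chromosome accumulators for the
#'   chromosome jackknife.
#' @export
ancestry_covariance <- function(gm, target, pa, pb, bin_morgans = 0.001,
                                max_morgans = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (all(is.na(gm$sites$gen_pos)) || all(gm$sites$gen_pos == 0))
    stop("ancestry_covariance requires a genetic map")
  cols <- which(gm$individuals$group == target)
  if (length(cols) < 2)
    stop("ancestry covariance needs at least 2 target individuals")
  if (length(pa) != nrow(gm$sites) || length(pb) != nrow(gm$sites))
    stop("source frequency vectors must align with the site table")
  n_bins <- ceiling(max_morgans / bin_morgans)
  chroms <- unique(gm$sites$chrom)
  sums <- matrix(0, n_bins, length(chroms), dimnames = list(NULL, chroms))
  counts <- matrix(0, n_bins, length(chroms), dimnames = list(NULL, chroms))
  for (ci in seq_along(chroms)) {
    sel <- which(gm$sites$chrom == chroms[ci] & !is.na(pa) & !is.na(pb))
    if (length(sel) < 2) next
    w <- pa[sel] - pb[sel]
    Gc <- gm$codes[sel, cols, drop = FALSE] / 2
    obs <- !is.na(Gc)
    pbar <- rowMeans(Gc, na.rm = TRUE)
    R <- Gc - pbar
    R[!obs] <- 0
    A <- R * w           # rows scaled by w_s
    P <- tcrossprod(A)   # P[s,t] = sum_i w_s w_t r_si r_ti
    Npair <- tcrossprod(obs * 1)  # individuals observed at both sites
    Z <- P / pmax(Npair, 1)
    d <- abs(outer(gm$sites$gen_pos[sel], gm$sites$gen_pos[sel], "-")) / 100
    bin <- floor(d / bin_morgans) + 1
    ut <- upper.tri(d)
    ok <- ut & bin <= n_bins & Npair > 0
    agg <- rowsum(Z[ok], bin[ok])
    idx <- as.integer(rownames(agg))
    sums[idx, ci] <- sums[idx, ci] + agg[, 1]
    cnt <- rowsum(rep(1, sum(ok)), bin[ok])
    counts[idx, ci] <- counts[idx, ci] + cnt[, 1]
  }
  mids <- (seq_len(n_bins) - 0.5) * bin_morgans
  tot_counts <- rowSums(counts)
  bins <- data.frame(mid = mids,
                     covariance = ifelse(tot_counts > 0,
                                         rowSums(sums) / tot_counts, NA_real_),
                     n_pairs = tot_counts)
  structure(list(bins = bins, sums = sums, counts = counts,
                 bin_morgans = bin_morgans, target = target),
            class = "decay_curve")
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Weighted nonlinear least squares of `A exp(-n d) + c` over the bin means
#' (weights = pair counts) inside the fit window. The fitted rate `n` is the
#' number of generations since admixture; it is converted to years with the
#' per-generation constant (default 29 years) and, when the sampled
#' individuals are themselves ancient, shifted by their age to years before
#' present. The rate standard error comes from a delete-one-chromosome
#' jackknife.
#'
#' The default window starts at 0.005 Morgans, excluding the shortest bins
#' where unmodelled background linkage disequilibrium dominates; the affine
#' offset `c` absorbs residual long-range background covariance.
#'
#' @param curve An [ancestry_covariance()] result, or a data.frame with
#'   columns `mid`, `covariance`, `n_pairs` (no jackknife then).
#' @param fit_window `(d_min, d_max)` in Morgans.
#' @param years_per_generation Conversion constant (default 29).
#' @param sample_age_years_bp Age of the sampled individuals (years bp).
#' @return An object of class `decay_fit`: list with `amplitude`,
#'   `generations`, `offset`, `se_generations`, `years_before_sampling`,
#'   `years_bp`, `n_bins_fit`, `decay_detected`.
#' @export
fit_decay <- function(curve, fit_window = c(0.005, 1.0),
                      years_per_generation = 29, sample_age_years_bp = 0) {
  bins <- if (inherits(curve, "decay_curve")) curve$bins else
    as.data.frame(curve)
  sel <- bins$mid >= fit_window[1] & bins$mid <= fit_window[2] &
    bins$n_pairs > 0 & !is.na(bins$covariance)
  if (sum(sel) < 10)
    stop("fewer than 10 populated bins inside the fit window")
  d <- bins$mid[sel]; y <- bins$covariance[sel]; wt <- bins$n_pairs[sel]
  fit1 <- function(d, y, wt) {
    c0 <- stats::weighted.mean(utils::tail(y, max(3, length(y) %/% 5)),
                               utils::tail(wt, max(3, length(y) %/% 5)))
    a0 <- max(y[1] - c0, 1e-9)
    pos <- which(y - c0 > 0)
    n0 <- if (length(pos) >= 3) {
      sl <- stats::coef(stats::lm(log(y[pos] - c0) ~ d[pos],
                                  weights = wt[pos]))[2]
      max(min(-sl, 2000), 1)
    } else 50
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-n * d) + c,
        start = list(A = a0, n = n0, c = c0),
        weights = wt,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) return(c(A = 0, n = -1, c = c0))  # no decay signal
    stats::coef(fit)
  }
  cf <- fit1(d, y, wt)
  se_gen <- NA_real_
  if (inherits(curve, "decay_curve") && ncol(curve$sums) > 1) {
    chroms <- colnames(curve$sums)
    loo_n <- rep(NA_real_, length(chroms))
    tot_s <- rowSums(curve$sums); tot_c <- rowSums(curve$counts)
    for (k in seq_along(chroms)) {
      s <- tot_s - curve$sums[, k]
      cnt <- tot_c - curve$counts[, k]
      selk <- sel & cnt > 0
      yk <- s[selk] / cnt[selk]
      nk <- tryCatch(fit1(bins$mid[selk], yk, cnt[selk])["n"],
                     error = function(e) NA_real_)
      loo_n[k] <- if (!is.na(nk) && nk > 0) nk else NA_real_
    }
    loo_n <- loo_n[!is.na(loo_n)]
    g <- length(loo_n)
    if (g >= 2)
      se_gen <- sqrt((g - 1) / g * sum((loo_n - mean(loo_n))^2))
  }
  n_hat <- unname(cf["n"])
  decay <- n_hat > 0 && cf["A"] > 0
  if (!decay)
    warning("no decay detected (non-positive fitted rate or amplitude)")
  structure(list(amplitude = unname(cf["A"]), generations = n_hat,
                 offset = unname(cf["c"]), se_generations = se_gen,
                 years_per_generation = years_per_generation,
                 years_before_sampling = n_hat * years_per_generation,
                 years_bp = n_hat * years_per_generation + sample_age_years_bp,
                 n_bins_fit = sum(sel), decay_detected = decay),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: n = %.2f generations (se %.2f)\n", x$generations,
              x$se_generations))
  cat(sprintf("  amplitude %.3g, offset %.3g, %d bins\n", x$amplitude,
              x$offset, x$n_bins_fit))
  cat(sprintf("  date: %.0f years before sampling (%.0f yr/gen); %.0f years bp\n",
              x$years_before_sampling, x$years_per_generation, x$years_bp))
  invisible(x)
}

#' One-call admixture dating
#'
#' [ancestry_covariance()] followed by [fit_decay()].
#'
#' @inheritParams ancestry_covariance
#' @inheritParams fit_decay
#' @return A [fit_decay()] result with the curve attached as `curve`.
#' @export
date_admixture <- function(gm, target, pa, pb, bin_morgans = 0.001,
                           fit_window = c(0.005, 1.0),
                           years_per_generation = 29,
                           sample_age_years_bp = 0) {
  curve <- ancestry_covariance(gm, target, pa, pb, bin_morgans,
                               max_morgans = fit_window[2])
  fit <- fit_decay(curve, fit_window, years_per_generation,
                   sample_age_years_bp)
  fit$curve <- curve
  fit
}
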