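#' F-statistics with block-jackknife standard errors
#'
#' `f2(A, B)` estimates the squared allele-frequency distance between two
#' populations, `f3(C; A, B)` the covariance of C's frequency offsets to A
#' and B (negative values diagnose C as an admixture of A- and B-related
#' sources; with a distant outgroup as C it measures shared drift between A
#' and B), `f4(A, B; C, D)` the classic four-population test of treeness, and
#' `fst(A, B)` Hudson's fixation index as a ratio of sums. A positive
#' `f4(Outgroup, X; Pop1, Pop2)` indicates excess affinity between X and
#' Pop2, a negative value affinity between X and Pop1; |Z| > 3 is the usual
#' significance convention. Standard errors come from a weighted
#' delete-one-block jackknife over [partition_blocks()] blocks (5 cM by
#' default).
#'
#' In `site_mode = "allsnps"` each statistic uses every site at which all of
#' its own populations are defined; `"intersection"` restricts to sites
#' defined in every group of the frequency table, so that statistics computed
#' on the same table share one site set and the algebraic identities among
#' f-statistics hold exactly.
#'
#' The small-sample bias corrections subtract `p(1-p)/(n-1)` terms with `n`
#' the observed allele count; sites where any corrected group has `n < 2` are
#' dropped from the corrected statistic.
#'
#' @param freqs A [group_frequencies()] table.
#' @param A,B,C,D Group labels.
#' @param blocks A [partition_blocks()] result for the same sites.
#' @param corrected Apply the sampling-bias correction (f2: both groups;
#'   f3: target C only). f4 needs no correction.
#' @param site_mode `"intersection"` (default for standalone statistics) or
#'   `"allsnps"`.
#' @param inbreed For `fst`: use per-site individual counts rather than
#'   allele counts in the correction (haploid accounting, appropriate for
#'   pseudohaploid or inbred data).
#' @return An object of class `fstat`: list with `statistic`, `pops`,
#'   `estimate`, `se`, `z`, `n_blocks`, `n_snps`, `site_mode`.
#' @name fstats
NULL

fstat_result <- function(statistic, pops, jk, site_mode) {
  structure(list(statistic = statistic, pops = pops,
                 estimate = jk$estimate, se = jk$se,
                 z = jk$estimate / jk$se, n_blocks = jk$n_blocks,
                 n_snps = jk$n_sites, site_mode = site_mode),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("%s(%s): %.6g  se %.3g  Z %.2f  (%d SNPs, %d blocks, %s)\n",
              x$statistic, paste(x$pops, collapse = ", "), x$estimate,
              x$se, x$z, x$n_snps, x$n_blocks, x$site_mode))
  invisible(x)
}

fstat_compute <- function(freqs, pops, blocks, num, den, use, statistic,
                          site_mode) {
  if (!any(use)) stop(statistic, ": no usable sites for populations ",
                      paste(pops, collapse = ", "))
  sb <- site_block_index(blocks)
  if (length(sb) != nrow(freqs$freq))
    stop("block partition does not match the frequency table's site count")
  jk <- block_jackknife_ratio(num[use], den[use], sb[use])
  if (jk$n_blocks < 2)
    warning(statistic, ": fewer than 2 blocks with data; SE undefined")
  fstat_result(statistic, pops, jk, site_mode)
}

#' @rdname fstats
#' @export
f2 <- function(freqs, A, B, blocks, corrected = TRUE,
               site_mode = c("intersection", "allsnps")) {
  site_mode <- match.arg(site_mode)
  use <- usable_sites(freqs, c(A, B), site_mode)
  pA <- freqs$freq[, A]; pB <- freqs$freq[, B]
  nA <- freqs$n_tot[, A]; nB <- freqs$n_tot[, B]
  num <- (pA - pB)^2
  if (corrected) {
    use <- use & nA >= 2 & nB >= 2
    num <- num - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  }
  fstat_compute(freqs, c(A, B), blocks, num, rep(1, length(num)), use,
                "F2", site_mode)
}

#' @rdname fstats
#' @export
f3 <- function(freqs, C, A, B, blocks, corrected = TRUE,
               site_mode = c("intersection", "allsnps")) {
  site_mode <- match.arg(site_mode)
  use <- usable_sites(freqs, c(C, A, B), site_mode)
  pC <- freqs$freq[, C]; pA <- freqs$freq[, A]; pB <- freqs$freq[, B]
  num <- (pC - pA) * (pC - pB)
  if (corrected) {
    nC <- freqs$n_tot[, C]
    use <- use & nC >= 2
    num <- num - pC * (1 - pC) / (nC - 1)
  }
  fstat_compute(freqs, c(C, A, B), blocks, num, rep(1, length(num)), use,
                "F3", site_mode)
}

#' @rdname fstats
#' @export
f4 <- function(freqs, A, B, C, D, blocks,
               site_mode = c("intersection", "allsnps")) {
  site_mode <- match.arg(site_mode)
  use <- usable_sites(freqs, c(A, B, C, D), site_mode)
  p <- freqs$freq
  num <- (p[, A] - p[, B]) * (p[, C] - p[, D])
  fstat_compute(freqs, c(A, B, C, D), blocks, num, rep(1, length(num)), use,
                "F4", site_mode)
}

#' @rdname fstats
#' @export
fst <- function(freqs, A, B, blocks, inbreed = FALSE,
                site_mode = c("intersection", "allsnps")) {
  site_mode <- match.arg(site_mode)
  use <- usable_sites(freqs, c(A, B), site_mode)
  pA <- freqs$freq[, A]; pB <- freqs$freq[, B]
  nA <- if (inbreed) freqs$n_ind[, A] else freqs$n_tot[, A]
  nB <- if (inbreed) freqs$n_ind[, B] else freqs$n_tot[, B]
  use <- use & nA >= 2 & nB >= 2
  if (!any(use))
    stop("fst: no site has at least 2 observed alleles in both groups")
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  fstat_compute(freqs, c(A, B), blocks, num, den, use, "FST", site_mode)
}

#' Pairwise matrix of outgroup-f3 or FST values
#'
#' Computes all unordered pairs among `groups` and returns the symmetric
#' matrix together with a Ward-linkage ordering of the rows for heat-map
#' display (as used for shared-drift matrices of ancient individuals).
#'
#' @param freqs A [group_frequencies()] table.
#' @param groups Character vector of group labels (>= 2).
#' @param statistic `"outgroupF3"` or `"FST"`.
#' @param outgroup Outgroup label (required for `"outgroupF3"`).
#' @param blocks A [partition_blocks()] result.
#' @param ... Passed to [f3()] / [fst()].
#' @return List with `matrix` (estimates; diagonal `NA` for outgroup-f3, 0
#'   for FST), `se` matrix, `order` (Ward ordering), and `hclust`.
#' @export
pairwise_matrix <- function(freqs, groups, statistic = c("outgroupF3", "FST"),
                            outgroup = NULL, blocks, ...) {
  statistic <- match.arg(statistic)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (statistic == "outgroupF3" && is.null(outgroup))
    stop("outgroupF3 requires an outgroup label")
  G <- length(groups)
  est <- se <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  for (i in seq_len(G - 1)) {
    for (j in seq(i + 1, G)) {
      r <- tryCatch(
        if (statistic == "outgroupF3")
          f3(freqs, outgroup, groups[i], groups[j], blocks, ...)
        else fst(freqs, groups[i], groups[j], blocks, ...),
        error = function(e) NULL)
      if (is.null(r)) next
      est[i, j] <- est[j, i] <- r$estimate
      se[i, j] <- se[j, i] <- r$se
    }
  }
  if (statistic == "FST") diag(est) <- 0
  # Ward ordering: outgroup-f3 is a similarity, convert to a distance.
  d <- if (statistic == "outgroupF3") {
    m <- est
    diag(m) <- max(est, na.rm = TRUE)
    stats::as.dist(max(m, na.rm = TRUE) - m)
  } else {
    m <- est
    stats::as.dist(m)
  }
  hc <- stats::hclust(d, method = "ward.D2")
  list(matrix = est, se = se, order = hc$order, hclust = hc,
       statistic = statistic)
}
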