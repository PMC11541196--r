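#' Pseudohaploid genotype calling from a read pileup
#'
#' For each individual and site, reads failing the quality thresholds are
#' dropped; then, depending on `mode`:
#' * `"standard"`: reads whose base lies within `trim_bp` of a read end are
#'   dropped (the usual two-base clip for damage-trimmed double-stranded
#'   libraries);
#' * `"single_strand"`: at C/T polymorphisms reads aligning to the forward
#'   strand are ignored, and at G/A polymorphisms reads aligning to the
#'   reverse strand, which removes post-mortem deamination products from
#'   non-UDG single-stranded libraries.
#'
#' Among surviving reads whose base matches the site's ref or alt allele, one
#' is drawn uniformly at random and the call is the matching homozygous code
#' (0 for ref, 2 for alt); a site with no surviving read is missing.
#'
#' @param pileup data.frame as produced by [simulate_pileups()] (columns
#'   `individual`, `chrom`, `pos`, `base`, `strand`, `dist_end`, `baseq`,
#'   `mapq`), or read from a tab-separated file with those headers.
#' @param sites Site table (data.frame with `site_id`, `chrom`, `phys_pos`,
#'   `gen_pos`, `ref`, `alt`), e.g. `gm$sites`.
#' @param mode `"standard"` or `"single_strand"`.
#' @param trim_bp Terminal bases to ignore in standard mode (default 2).
#' @param min_baseq,min_mapq Quality thresholds (defaults 30/30).
#' @param seed Optional integer seed for the random read draw.
#' @return A [genotype_matrix()] of pseudohaploid calls, one column per
#'   individual present in the pileup.
#' @export
call_pseudohaploid <- function(pileup, sites, mode = c("standard", "single_strand"),
                               trim_bp = 2L, min_baseq = 30, min_mapq = 30,
                               seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pileup <- as.data.frame(pileup)
  sites <- as.data.frame(sites)
  site_key <- paste(sites$chrom, sites$phys_pos, sep = ":")
  read_site <- match(paste(pileup$chrom, pileup$pos, sep = ":"), site_key)
  keep <- !is.na(read_site) & pileup$baseq >= min_baseq & pileup$mapq >= min_mapq
  ref <- sites$ref[read_site]; alt <- sites$alt[read_site]
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  if (mode == "single_strand") {
    affected <- keep & pair %in% c("C T", "A G")
    if (any(affected & (is.na(pileup$strand) | !pileup$strand %in% c("+", "-"))))
      stop("single_strand mode requires strand information for reads at C/T and G/A sites")
    keep <- keep & !(pair == "C T" & pileup$strand == "+")
    keep <- keep & !(pair == "A G" & pileup$strand == "-")
  } else if (trim_bp > 0) {
    keep <- keep & pileup$dist_end >= trim_bp
  }
  keep <- keep & (pileup$base == ref | pileup$base == alt)
  keep[is.na(keep)] <- FALSE
  pu <- pileup[keep, , drop = FALSE]
  rs <- read_site[keep]
  inds <- unique(pileup$individual)
  codes <- matrix(NA_integer_, nrow(sites), length(inds))
  if (nrow(pu) > 0) {
    # draw one read uniformly per (individual, site): random key, take max
    u <- stats::runif(nrow(pu))
    cell <- paste(match(pu$individual, inds), rs, sep = ":")
    pick <- tapply(seq_len(nrow(pu)), cell, function(i) i[which.max(u[i])])
    pick <- unlist(pick, use.names = FALSE)
    is_alt <- pu$base[pick] == sites$alt[rs[pick]]
    codes[cbind(rs[pick], match(pu$individual[pick], inds))] <-
      2L * as.integer(is_alt)
  }
  individuals <- data.frame(individual_id = inds, group = inds,
                            sex = "UNKNOWN", ploidy = "pseudohaploid",
                            stringsAsFactors = FALSE)
  genotype_matrix(sites, codes, individuals)
}

#' Merge two genotype call sets for the same individual
#'
#' Used to combine calls from multiple libraries of one sample: the primary
#' call is kept wherever non-missing and the fill call is used only at
#' primary-missing sites (e.g. single-stranded calls filled with trimmed
#' double-stranded calls). Conflicting non-missing calls are never
#' overwritten; their count is reported via a message.
#'
#' @param primary,fill Integer code vectors on the same site list (`NA` =
#'   missing).
#' @return The merged code vector.
#' @export
merge_libraries <- function(primary, fill) {
  if (length(primary) != length(fill))
    stop("primary and fill columns cover different site lists")
  conflict <- !is.na(primary) & !is.na(fill) & primary != fill
  if (any(conflict))
    message(sum(conflict), " site(s) with conflicting non-missing calls; ",
            "primary call kept")
  out <- primary
  out[is.na(primary)] <- fill[is.na(primary)]
  out
}

#' Genetic sex from relative X and Y coverage
#'
#' Normalizes the per-site read counts on X and Y by the autosomal per-site
#' coverage. XX individuals are expected at (x_rate, y_rate) = (1, 0), XY
#' individuals at (0.5, 0.5). A call is made when both rates lie within
#' `n_se` standard errors of one model and outside `n_se` standard errors of
#' the other; anything else is `UNKNOWN`. Standard errors use Poisson
#' propagation on the observed read counts (with a one-read floor so a zero
#' count retains a finite interval).
#'
#' @param n_aut_sites,aut_reads Covered autosomal site count and total reads.
#' @param n_x_sites,x_reads Same for the X chromosome.
#' @param n_y_sites,y_reads Same for the Y chromosome.
#' @param n_se Tolerance multiplier (default 3).
#' @details Model consistency is judged against the Poisson standard error
#'   *implied by the model being tested* (expected reads = model rate x
#'   autosomal coverage x site count, with a one-read floor), not the
#'   observed-count SE: an unluckily low read count would otherwise shrink
#'   its own error bar and reject the true model. The reported
#'   `x_rate_se`/`y_rate_se` are observed-count SEs with the autosomal
#'   denominator error propagated, suitable for plotting.
#' @return An object of class `sex_typing`: list with `x_rate`, `y_rate`,
#'   `x_rate_se`, `y_rate_se`, `call`.
#' @export
determine_sex <- function(n_aut_sites, aut_reads, n_x_sites, x_reads,
                          n_y_sites, y_reads, n_se = 3) {
  if (n_aut_sites < 1 || aut_reads <= 0)
    stop("sex typing needs at least one covered autosomal site")
  aut_cov <- aut_reads / n_aut_sites
  rate <- function(reads, n_sites) (reads / n_sites) / aut_cov
  rate_se <- function(reads, n_sites)  # observed-based, for reporting
    sqrt(max(reads, 1) / n_sites^2 + (reads / n_sites)^2 / aut_reads) / aut_cov
  model_se <- function(m, n_sites)     # under the tested model
    sqrt(max(m * aut_cov * n_sites, 1) / n_sites^2 +
           (m * aut_cov)^2 / aut_reads) / aut_cov
  x_rate <- rate(x_reads, n_x_sites); x_se <- rate_se(x_reads, n_x_sites)
  y_rate <- rate(y_reads, n_y_sites); y_se <- rate_se(y_reads, n_y_sites)
  fits <- function(mx, my)
    abs(x_rate - mx) <= n_se * model_se(mx, n_x_sites) &&
      abs(y_rate - my) <= n_se * model_se(my, n_y_sites)
  is_xx <- fits(1, 0)
  is_xy <- fits(0.5, 0.5)
  call <- if (is_xx && !is_xy) "XX" else if (is_xy && !is_xx) "XY" else "UNKNOWN"
  structure(list(x_rate = x_rate, y_rate = y_rate, x_rate_se = x_se,
                 y_rate_se = y_se, call = call),
            class = "sex_typing")
}

#' @export
print.sex_typing <- function(x, ...) {
  cat(sprintf("sex_typing: x_rate %.3f (se %.3f), y_rate %.3f (se %.3f) -> %s\n",
              x$x_rate, x$x_rate_se, x$y_rate, x$y_rate_se, x$call))
  invisible(x)
}

haploidize_column <- function(codes) {
  het <- which(!is.na(codes) & codes == 1L)
  if (length(het) > 0)
    codes[het] <- 2L * stats::rbinom(length(het), 1, 0.5)
  codes
}

#' Pairwise mismatch rate between two individuals
#'
#' The fraction of sites, non-missing in both individuals, at which their
#' haploidized genotypes disagree. Heterozygous diploid codes are resolved by
#' one random allele draw per site, making diploid and pseudohaploid columns
#' comparable. Duplicate samples of one individual show about half the
#' mismatch rate of an unrelated pair from the same population, which is the
#' basis of duplicate/kinship screening.
#'
#' @param gm A [genotype_matrix()].
#' @param id1,id2 Individual identifiers.
#' @param seed Optional seed for the haploidization draws.
#' @param transversions_only Restrict to transversion SNPs (damage-robust).
#' @return An object of class `pairwise_mismatch`: list with `pair`,
#'   `overlapping_sites`, `mismatches`, `rate` (`NA` with a flag when there
#'   is no overlap).
#' @export
pairwise_mismatch <- function(gm, id1, id2, seed = NULL,
                              transversions_only = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  j1 <- match(id1, gm$individuals$individual_id)
  j2 <- match(id2, gm$individuals$individual_id)
  if (is.na(j1) || is.na(j2)) stop("unknown individual id")
  g1 <- haploidize_column(gm$codes[, j1])
  g2 <- haploidize_column(gm$codes[, j2])
  use <- !is.na(g1) & !is.na(g2)
  if (transversions_only) {
    pair <- paste(pmin(gm$sites$ref, gm$sites$alt),
                  pmax(gm$sites$ref, gm$sites$alt))
    use <- use & !pair %in% c("C T", "A G")
  }
  n <- sum(use)
  mism <- sum(g1[use] != g2[use])
  structure(list(pair = c(id1, id2), overlapping_sites = n,
                 mismatches = mism,
                 rate = if (n > 0) mism / n else NA_real_,
                 defined = n > 0),
            class = "pairwise_mismatch")
}

#' @export
print.pairwise_mismatch <- function(x, ...) {
  cat(sprintf("pairwise_mismatch %s vs %s: %d/%d = %s\n", x$pair[1], x$pair[2],
              x$mismatches, x$overlapping_sites,
              if (x$defined) sprintf("%.4f", x$rate) else "undefined (no overlap)"))
  invisible(x)
}

#' Conditional nucleotide diversity of a group
#'
#' The pairwise mismatch rate for every unordered pair of individuals within
#' a group on the ascertained SNP panel, reported per pair (box-plot ready)
#' together with the group mean. A comparative, not absolute, diversity
#' measure: populations with more genetic drift show lower values.
#'
#' @param gm A [genotype_matrix()].
#' @param group Group label with at least two individuals.
#' @param seed Optional seed for the haploidization draws.
#' @param ... Passed to [pairwise_mismatch()].
#' @return List with `pairs` (data.frame `id1`, `id2`, `overlapping_sites`,
#'   `rate`) and `mean_cnd`.
#' @export
conditional_nucleotide_diversity <- function(gm, group, seed = NULL, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- gm$individuals$individual_id[gm$individuals$group == group]
  if (length(ids) < 2)
    stop("conditional nucleotide diversity needs >= 2 individuals in group ",
         group)
  if (!is.null(seed)) set.seed(seed)
  cmb <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    r <- pairwise_mismatch(gm, cmb[1, k], cmb[2, k], seed = NULL, ...)
    data.frame(id1 = cmb[1, k], id2 = cmb[2, k],
               overlapping_sites = r$overlapping_sites, rate = r$rate,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, mean_cnd = mean(pairs$rate, na.rm = TRUE))
}

#' Autosomal heterozygosity of a diploid individual
#'
#' The fraction of heterozygous calls over all non-missing autosomal calls.
#' Undefined for pseudohaploid individuals (which carry no heterozygous
#' codes by construction) - requesting one is an error.
#'
#' @param gm A [genotype_matrix()].
#' @param id Individual identifier (must be diploid).
#' @return Numeric fraction in `[0, 1]`.
#' @export
heterozygosity <- function(gm, id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(id, gm$individuals$individual_id)
  if (is.na(j)) stop("unknown individual id: ", id)
  if (gm$individuals$ploidy[j] != "diploid")
    stop("heterozygosity is undefined for pseudohaploid individual ", id)
  aut <- gm$sites$chrom %in% as.character(1:22)
  g <- gm$codes[aut, j]
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("no non-missing autosomal calls for ", id)
  mean(g == 1L)
}
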