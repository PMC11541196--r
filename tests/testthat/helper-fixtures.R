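# Shared fixture builders and independent (naive) oracles for the test suite.

# minimal genotype matrix from explicit pieces
make_gm <- function(codes, gen_pos, chrom = "1", ploidy = "diploid",
                    group = NULL, ref = "A", alt = "G",
                    phys_pos = NULL) {
  codes <- as.matrix(codes)
  S <- nrow(codes); N <- ncol(codes)
  if (is.null(phys_pos)) phys_pos <- round(gen_pos * 1e6) + 1
  sites <- data.frame(site_id = paste0("s", seq_len(S)),
                      chrom = rep_len(chrom, S), phys_pos = phys_pos,
                      gen_pos = gen_pos, ref = rep_len(ref, S),
                      alt = rep_len(alt, S), stringsAsFactors = FALSE)
  if (is.null(group)) group <- paste0("g", seq_len(N))
  inds <- data.frame(individual_id = paste0("i", seq_len(N)),
                     group = rep_len(group, N), sex = "UNKNOWN",
                     ploidy = rep_len(ploidy, N), stringsAsFactors = FALSE)
  genotype_matrix(sites, codes, inds)
}

# group_freq object built directly from a frequency matrix (uniform counts)
make_freqs <- function(freq, n_tot = 20, gen_pos = NULL, chrom = "1") {
  freq <- as.matrix(freq)
  S <- nrow(freq)
  if (is.null(gen_pos)) gen_pos <- seq(0, 100, length.out = S)
  sites <- data.frame(site_id = paste0("s", seq_len(S)),
                      chrom = rep_len(chrom, S),
                      phys_pos = round(gen_pos * 1e6) + 1, gen_pos = gen_pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  cnt <- matrix(n_tot, S, ncol(freq), dimnames = dimnames(freq))
  structure(list(freq = freq, n_alt = freq * cnt, n_tot = cnt,
                 n_ind = cnt / 2, sites = sites, groups = colnames(freq)),
            class = "group_freq")
}

blocks_for_freqs <- function(freqs, width_cm = 5) {
  gm <- make_gm(matrix(0L, nrow(freqs$sites), 1),
                gen_pos = freqs$sites$gen_pos, chrom = freqs$sites$chrom)
  partition_blocks(gm, width_cm)
}

# study system: default tree plus an admixed target leaf
admixed_config <- function(seed, n_sites = 50000, alpha = 0.3, n_per_group = 10,
                           n_target = 20, n_chrom = 10, chrom_length_cm = 100,
                           x_fraction = 0, sf = NA, sm = NA,
                           mean_coverage = Inf) {
  sim_config(
    seed = seed, n_sites = n_sites, n_chrom = n_chrom,
    chrom_length_cm = chrom_length_cm, x_fraction = x_fraction,
    admixture_events = data.frame(target = "Tgt", source_a = "SrcA",
                                  source_b = "SrcB", alpha = alpha,
                                  generations_ago = 10, sf = sf, sm = sm),
    samples = rbind(
      data.frame(leaf = c("Out", "R1", "R2", "R3", "SrcA", "SrcB"),
                 n_diploid = 0L, n_pseudohaploid = n_per_group,
                 mean_coverage = mean_coverage, damage_rate = 0),
      data.frame(leaf = "Tgt", n_diploid = 0L, n_pseudohaploid = n_target,
                 mean_coverage = mean_coverage, damage_rate = 0)))
}

RIGHTS <- c("Out", "R1", "R2", "R3")

# ---- naive per-site-loop oracles for the f-statistics ----------------------

naive_use <- function(freqs, pops, site_mode) {
  cols <- if (site_mode == "intersection") freqs$groups else pops
  apply(freqs$freq[, cols, drop = FALSE], 1, function(r) !any(is.na(r)))
}

naive_f2 <- function(freqs, A, B, corrected = TRUE,
                     site_mode = "intersection") {
  use <- naive_use(freqs, c(A, B), site_mode)
  tot <- 0; n <- 0
  for (s in which(use)) {
    pA <- freqs$freq[s, A]; pB <- freqs$freq[s, B]
    nA <- freqs$n_tot[s, A]; nB <- freqs$n_tot[s, B]
    if (corrected && (nA < 2 || nB < 2)) next
    term <- (pA - pB)^2
    if (corrected)
      term <- term - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    tot <- tot + term; n <- n + 1
  }
  unname(tot / n)
}

naive_f3 <- function(freqs, C, A, B, corrected = TRUE,
                     site_mode = "intersection") {
  use <- naive_use(freqs, c(C, A, B), site_mode)
  tot <- 0; n <- 0
  for (s in which(use)) {
    pC <- freqs$freq[s, C]
    nC <- freqs$n_tot[s, C]
    if (corrected && nC < 2) next
    term <- (pC - freqs$freq[s, A]) * (pC - freqs$freq[s, B])
    if (corrected) term <- term - pC * (1 - pC) / (nC - 1)
    tot <- tot + term; n <- n + 1
  }
  unname(tot / n)
}

naive_f4 <- function(freqs, A, B, C, D, site_mode = "intersection") {
  use <- naive_use(freqs, c(A, B, C, D), site_mode)
  tot <- 0; n <- 0
  for (s in which(use)) {
    tot <- tot + (freqs$freq[s, A] - freqs$freq[s, B]) *
      (freqs$freq[s, C] - freqs$freq[s, D])
    n <- n + 1
  }
  unname(tot / n)
}

naive_fst <- function(freqs, A, B, inbreed = FALSE,
                      site_mode = "intersection") {
  use <- naive_use(freqs, c(A, B), site_mode)
  num <- 0; den <- 0
  for (s in which(use)) {
    pA <- freqs$freq[s, A]; pB <- freqs$freq[s, B]
    nA <- if (inbreed) freqs$n_ind[s, A] else freqs$n_tot[s, A]
    nB <- if (inbreed) freqs$n_ind[s, B] else freqs$n_tot[s, B]
    if (nA < 2 || nB < 2) next
    num <- num + (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    den <- den + pA * (1 - pB) + pB * (1 - pA)
  }
  unname(num / den)
}

# naive quadruple-loop oracle for the dating statistic
naive_ancestry_covariance <- function(gm, target, pa, pb, bin_morgans,
                                      max_morgans = 1) {
  cols <- which(gm$individuals$group == target)
  n_bins <- ceiling(max_morgans / bin_morgans)
  sums <- numeric(n_bins); counts <- numeric(n_bins)
  for (ch in unique(gm$sites$chrom)) {
    sel <- which(gm$sites$chrom == ch & !is.na(pa) & !is.na(pb))
    w <- pa[sel] - pb[sel]
    G <- gm$codes[sel, cols, drop = FALSE] / 2
    pbar <- rowMeans(G, na.rm = TRUE)
    for (s in seq_along(sel)) for (t in seq_along(sel)) {
      if (t <= s) next
      d <- abs(gm$sites$gen_pos[sel[t]] - gm$sites$gen_pos[sel[s]]) / 100
      b <- floor(d / bin_morgans) + 1
      if (b > n_bins) next
      vals <- c()
      for (i in seq_along(cols)) {
        if (is.na(G[s, i]) || is.na(G[t, i])) next
        vals <- c(vals, w[s] * w[t] * (G[s, i] - pbar[s]) * (G[t, i] - pbar[t]))
      }
      if (length(vals) == 0) next
      sums[b] <- sums[b] + mean(vals)
      counts[b] <- counts[b] + 1
    }
  }
  data.frame(mid = (seq_len(n_bins) - 0.5) * bin_morgans,
             covariance = ifelse(counts > 0, sums / counts, NA),
             n_pairs = counts)
}
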