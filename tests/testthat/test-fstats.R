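set.seed(101)
fx_freq <- matrix(runif(1000 * 5, 0.02, 0.98), 1000, 5,
                  dimnames = list(NULL, c("A", "B", "C", "D", "E")))
fx_freq[sample(length(fx_freq), 200)] <- NA  # scattered undefined cells
fx <- make_freqs(fx_freq, n_tot = 18)
fx_bl <- blocks_for_freqs(fx)

test_that("vectorized estimates equal the naive per-site loop", {
  for (mode in c("intersection", "allsnps")) {
    for (corr in c(TRUE, FALSE)) {
      expect_equal(f2(fx, "A", "B", fx_bl, corrected = corr,
                      site_mode = mode)$estimate,
                   naive_f2(fx, "A", "B", corrected = corr, site_mode = mode),
                   tolerance = 1e-12)
      expect_equal(f3(fx, "C", "A", "B", fx_bl, corrected = corr,
                      site_mode = mode)$estimate,
                   naive_f3(fx, "C", "A", "B", corrected = corr,
                            site_mode = mode),
                   tolerance = 1e-12)
    }
    expect_equal(f4(fx, "A", "B", "C", "D", fx_bl, site_mode = mode)$estimate,
                 naive_f4(fx, "A", "B", "C", "D", site_mode = mode),
                 tolerance = 1e-12)
    expect_equal(fst(fx, "A", "B", fx_bl, site_mode = mode)$estimate,
                 naive_fst(fx, "A", "B", site_mode = mode),
                 tolerance = 1e-12)
  }
})

test_that("f-statistic algebraic identities hold exactly in intersection mode", {
  # f3(C; A, A) = f2(A, C), uncorrected
  expect_equal(f3(fx, "C", "A", "A", fx_bl, corrected = FALSE)$estimate,
               f2(fx, "A", "C", fx_bl, corrected = FALSE)$estimate,
               tolerance = 1e-14)
  # f3(C; A, B) = [f2(A,C) + f2(B,C) - f2(A,B)] / 2
  lhs <- f3(fx, "C", "A", "B", fx_bl, corrected = FALSE)$estimate
  rhs <- (f2(fx, "A", "C", fx_bl, corrected = FALSE)$estimate +
            f2(fx, "B", "C", fx_bl, corrected = FALSE)$estimate -
            f2(fx, "A", "B", fx_bl, corrected = FALSE)$estimate) / 2
  expect_equal(lhs, rhs, tolerance = 1e-14)
  # f4(A, A; C, D) = 0
  expect_identical(f4(fx, "A", "A", "C", "D", fx_bl)$estimate, 0)
  # antisymmetry
  x <- f4(fx, "A", "B", "C", "D", fx_bl)$estimate
  expect_equal(f4(fx, "B", "A", "C", "D", fx_bl)$estimate, -x,
               tolerance = 1e-14)
  expect_equal(f4(fx, "A", "B", "D", "C", fx_bl)$estimate, -x,
               tolerance = 1e-14)
  # additivity over the third slot
  expect_equal(x, f4(fx, "A", "B", "C", "E", fx_bl)$estimate +
                 f4(fx, "A", "B", "E", "D", fx_bl)$estimate,
               tolerance = 1e-14)
})

test_that("degenerate frequency configurations hit the exact endpoints", {
  fixed <- make_freqs(cbind(A = rep(0, 50), B = rep(1, 50)), n_tot = 10)
  bl <- blocks_for_freqs(fixed)
  expect_equal(f2(fixed, "A", "B", bl, corrected = FALSE)$estimate, 1)
  expect_equal(fst(fixed, "A", "B", bl)$estimate, 1)
  same <- make_freqs(cbind(A = runif(50), B = runif(50)))
  same$freq[, "B"] <- same$freq[, "A"]
  expect_equal(f2(same, "A", "B", blocks_for_freqs(same),
                  corrected = FALSE)$estimate, 0)
})

test_that("errors and flags for unusable inputs", {
  allna <- make_freqs(cbind(A = rep(NA_real_, 10), B = runif(10)))
  expect_error(f2(allna, "A", "B", blocks_for_freqs(allna)), "no usable sites")
  one_block <- make_freqs(cbind(A = runif(10), B = runif(10)),
                          gen_pos = seq(0, 1, length.out = 10))
  expect_warning(r <- f2(one_block, "A", "B", blocks_for_freqs(one_block)),
                 "fewer than 2 blocks")
  expect_true(is.na(r$se))
  lowcount <- make_freqs(cbind(A = runif(10), B = runif(10)), n_tot = 1)
  expect_error(fst(lowcount, "A", "B", blocks_for_freqs(lowcount)),
               "2 observed alleles")
})

test_that("corrected f2 and FST recover Balding-Nichols drift expectations", {
  Fd <- 0.05
  tree <- data.frame(parent = c("root", "root"), child = c("P1", "P2"), F = Fd)
  cfg <- sim_config(seed = 21, tree = tree, n_sites = 50000, n_chrom = 5,
                    chrom_length_cm = 50,
                    samples = data.frame(leaf = c("P1", "P2"), n_diploid = 10L,
                                         n_pseudohaploid = 0L,
                                         mean_coverage = Inf,
                                         damage_rate = 0))
  st <- simulate_study(cfg)
  fr <- group_frequencies(st$genotypes)
  bl <- partition_blocks(st$genotypes, 5)
  pred_f2 <- 2 * Fd * mean(st$freqs$p0 * (1 - st$freqs$p0))
  r2 <- f2(fr, "P1", "P2", bl, corrected = TRUE)
  expect_lt(abs(r2$estimate - pred_f2), 2 * r2$se)
  rf <- fst(fr, "P1", "P2", bl)
  expect_lt(abs(rf$estimate - Fd), 2 * rf$se)
})

test_that("block-jackknife SE matches the analytic SE on independent sites", {
  set.seed(5)
  S <- 10000
  pa <- runif(S, 0.4, 0.6); pb <- runif(S, 0.4, 0.6)
  fr <- make_freqs(cbind(A = pa, B = pb),
                   gen_pos = seq(0, 500 - 1e-9, length.out = S))
  bl <- blocks_for_freqs(fr)  # 100 blocks of 5 cM
  expect_equal(n_blocks(bl), 100)
  r <- f2(fr, "A", "B", bl, corrected = FALSE)
  terms <- (pa - pb)^2
  analytic <- sd(terms) / sqrt(S)
  expect_lt(abs(r$se / analytic - 1), 0.15)
})

test_that("allsnps mode never uses fewer sites than intersection mode", {
  for (st in list(f2(fx, "A", "B", fx_bl, site_mode = "allsnps"),
                  f4(fx, "A", "B", "C", "D", fx_bl, site_mode = "allsnps"))) {
    inter <- if (st$statistic == "F2")
      f2(fx, "A", "B", fx_bl, site_mode = "intersection") else
        f4(fx, "A", "B", "C", "D", fx_bl, site_mode = "intersection")
    expect_gte(st$n_snps, inter$n_snps)
  }
})

test_that("pairwise matrices are symmetric and Ward-ordered", {
  # two sister pairs: (S1a, S1b) and (S2a, S2b)
  tree <- data.frame(
    parent = c("root", "root", "root", "a", "a", "b", "b"),
    child = c("Og", "a", "b", "S1a", "S1b", "S2a", "S2b"),
    F = c(0.5, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05))
  cfg <- sim_config(seed = 31, tree = tree, n_sites = 20000, n_chrom = 4,
                    chrom_length_cm = 25,
                    samples = data.frame(
                      leaf = c("Og", "S1a", "S1b", "S2a", "S2b"),
                      n_diploid = 0L, n_pseudohaploid = 8L,
                      mean_coverage = Inf, damage_rate = 0))
  st <- simulate_study(cfg)
  fr <- group_frequencies(st$genotypes)
  bl <- partition_blocks(st$genotypes, 5)
  groups <- c("S1a", "S2a", "S1b", "S2b")
  m <- pairwise_matrix(fr, groups, "outgroupF3", outgroup = "Og", blocks = bl)
  expect_true(isSymmetric(m$matrix[groups, groups], tol = 1e-12))
  ord <- groups[m$order]
  s1 <- match(c("S1a", "S1b"), ord)
  s2 <- match(c("S2a", "S2b"), ord)
  expect_equal(abs(diff(s1)), 1)  # sisters adjacent under Ward ordering
  expect_equal(abs(diff(s2)), 1)
  mf <- pairwise_matrix(fr, groups, "FST", blocks = bl)
  expect_true(all(diag(mf$matrix[groups, groups]) == 0))
  # two groups: one mirrored off-diagonal value
  m2 <- pairwise_matrix(fr, c("S1a", "S2a"), "FST", blocks = bl)
  expect_equal(m2$matrix["S1a", "S2a"], m2$matrix["S2a", "S1a"])
})

test_that("admixture f3 of a half-half mixture is significantly negative", {
  cfg <- admixed_config(seed = 41, n_sites = 100000, alpha = 0.5,
                        n_target = 20)
  st <- simulate_study(cfg)
  fr <- group_frequencies(st$genotypes)
  bl <- partition_blocks(st$genotypes, 5)
  r <- f3(fr, "Tgt", "SrcA", "SrcB", bl, corrected = TRUE)
  expect_lt(r$estimate, 0)
  expect_lt(r$z, -3)
})

test_that("f4 expectations follow the overlapping-drift-path rule of the tree", {
  cfg <- sim_config(seed = 55, n_sites = 50000,
                    samples = default_sim_samples())
  sf <- simulate_frequencies(cfg)
  fr <- make_freqs(sf$freq, n_tot = 1e6, gen_pos = sf$sites$gen_pos,
                   chrom = sf$sites$chrom)
  bl <- blocks_for_freqs(fr)
  # disjoint drift paths (SrcA,R2 split below n3; SrcB,R3 below n4): f4 ~ 0
  r0 <- f4(fr, "SrcA", "R2", "SrcB", "R3", bl)
  expect_lt(abs(r0$estimate), 3 * r0$se)
  # paths SrcA->R1 and SrcB->R1 share the branches n1->n2 and n1->R1, both
  # traversed towards R1: f4 = (F(n1->n2) + F(n1->R1)) * E[p(1-p) at n1]
  r1 <- f4(fr, "SrcA", "R1", "SrcB", "R1", bl)
  pred <- (0.05 + 0.05) * mean(sf$p0 * (1 - sf$p0)) * (1 - 0.05)
  expect_lt(abs(r1$estimate - pred), 3 * r1$se)
})

test_that("the f4-ratio recovers the simulated mixture proportion", {
  cfg <- admixed_config(seed = 56, n_sites = 100000, alpha = 0.3)
  st <- simulate_study(cfg)
  fr <- group_frequencies(st$genotypes)
  bl <- partition_blocks(st$genotypes, 5)
  # alpha = [f4(Out,Tgt;R2,R3) - f4(Out,SrcB;R2,R3)] /
  #         [f4(Out,SrcA;R2,R3) - f4(Out,SrcB;R2,R3)], jackknifed via the
  # leave-one-block replicates of the f4 system
  fm <- build_f4_matrix(fr, c("Out", "Tgt", "SrcA", "SrcB"), c("R2", "R3"),
                        bl, site_mode = "intersection")
  ratio_of <- function(x) (x[1] - x[3]) / (x[2] - x[3])
  est <- ratio_of(fm$x)
  loo <- apply(fm$loo, 1, ratio_of)
  g <- length(loo)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_lt(abs(est - 0.3), 2 * se)
  expect_lt(se, 0.05)
})
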