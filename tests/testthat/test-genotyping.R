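pileup_row <- function(ind, chrom, pos, ref, alt, base, strand, dist = 10,
                       baseq = 37, mapq = 60) {
  data.frame(individual = ind, chrom = chrom, pos = pos, ref = ref, alt = alt,
             base = base, strand = strand, dist_end = dist, baseq = baseq,
             mapq = mapq, stringsAsFactors = FALSE)
}

ct_site <- data.frame(site_id = "s1", chrom = "1", phys_pos = 100,
                      gen_pos = 0.1, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)

test_that("single-strand mode drops forward reads at C/T sites", {
  pu <- rbind(pileup_row("i1", "1", 100, "C", "T", "T", "+"),
              pileup_row("i1", "1", 100, "C", "T", "C", "-"))
  gm <- call_pseudohaploid(pu, ct_site, mode = "single_strand", seed = 1)
  expect_identical(unname(gm$codes[1, 1]), 0L)  # only the reverse C survives
  # reverse-strand reads dropped at G/A sites
  ga_site <- ct_site; ga_site$ref <- "G"; ga_site$alt <- "A"
  pu2 <- rbind(pileup_row("i1", "1", 100, "G", "A", "A", "-"),
               pileup_row("i1", "1", 100, "G", "A", "G", "+"))
  gm2 <- call_pseudohaploid(pu2, ga_site, mode = "single_strand", seed = 1)
  expect_identical(unname(gm2$codes[1, 1]), 0L)
  # missing strand at an affected site is an input error
  pu3 <- pileup_row("i1", "1", 100, "C", "T", "T", NA)
  expect_error(call_pseudohaploid(pu3, ct_site, mode = "single_strand"),
               "strand")
})

test_that("quality, trimming and allele filters leave MISSING when empty", {
  pu <- rbind(pileup_row("i1", "1", 100, "C", "T", "T", "+", baseq = 20),
              pileup_row("i1", "1", 100, "C", "T", "G", "+"),      # non-allele
              pileup_row("i1", "1", 100, "C", "T", "C", "+", dist = 1))
  gm <- call_pseudohaploid(pu, ct_site, mode = "standard", trim_bp = 2,
                           seed = 1)
  expect_true(is.na(gm$codes[1, 1]))
  # trim_bp = 0 lets the terminal C through
  gm2 <- call_pseudohaploid(pu, ct_site, mode = "standard", trim_bp = 0,
                            seed = 1)
  expect_identical(unname(gm2$codes[1, 1]), 0L)
})

test_that("the random read draw is uniform over surviving reads", {
  # 10,000 independent draws from reads {A, A, A, G} at an A/G site:
  # the A-call frequency estimates 0.75
  site <- data.frame(site_id = "s1", chrom = "1", phys_pos = 100,
                     gen_pos = 0.1, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  n_rep <- 10000
  pu <- do.call(rbind, lapply(c("A", "A", "A", "G"), function(b)
    pileup_row(paste0("rep", seq_len(n_rep)), "1", 100, "A", "G", b, "+")))
  gm <- call_pseudohaploid(pu, site, mode = "standard", trim_bp = 0, seed = 42)
  frac_a <- mean(gm$codes[1, ] == 0L)
  expect_lt(abs(frac_a - 0.75), 0.02)
})

test_that("library merging keeps primary calls and fills gaps only", {
  primary <- c(NA, 0L, NA, 2L)
  fill <- c(2L, 2L, NA, 0L)
  expect_message(merged <- merge_libraries(primary, fill), "conflicting")
  expect_identical(merged, c(2L, 0L, NA, 2L))
  expect_error(merge_libraries(1:3, 1:4), "different site lists")
})

test_that("sex typing matches the coverage-rate expectations", {
  # female: X rate 1, Y rate 0
  r <- determine_sex(1000, 2000, 300, 600, 300, 0)
  expect_equal(r$x_rate, 1)
  expect_equal(r$y_rate, 0)
  expect_equal(r$call, "XX")
  # male: 0.5 / 0.5
  r <- determine_sex(1000, 2000, 300, 300, 300, 295)
  expect_equal(r$x_rate, 0.5)
  expect_equal(r$call, "XY")
  # X rate 0.75 sits between both models -> UNKNOWN
  r <- determine_sex(200, 800, 200, 600, 200, 10)
  expect_equal(r$x_rate, 0.75)
  expect_equal(r$call, "UNKNOWN")
  expect_error(determine_sex(0, 0, 10, 10, 10, 10), "autosomal")
})

test_that("sex typing is reliable at 200+ covered sex-chromosome sites", {
  set.seed(31)
  calls <- replicate(150, {
    is_female <- runif(1) < 0.5
    aut <- rpois(1, 1000 * 2)
    x <- rpois(1, 250 * 2 * (if (is_female) 1 else 0.5))
    y <- rpois(1, 250 * 2 * (if (is_female) 0 else 0.5))
    got <- determine_sex(1000, aut, 250, x, 250, y)$call
    got == (if (is_female) "XX" else "XY")
  })
  expect_gte(mean(calls), 0.99)
})

test_that("pairwise mismatch counts overlapping haploidized disagreements", {
  gm <- make_gm(cbind(rep(0L, 10), c(rep(0L, 8), 2L, 2L)),
                gen_pos = 1:10, ploidy = "pseudohaploid")
  r <- pairwise_mismatch(gm, "i1", "i2")
  expect_equal(r$overlapping_sites, 10)
  expect_equal(r$mismatches, 2)
  expect_equal(r$rate, 0.2)
  same <- pairwise_mismatch(gm, "i1", "i1")
  expect_equal(same$rate, 0)
  # zero overlap is flagged, not silently zero
  gm2 <- make_gm(cbind(c(0L, NA), c(NA, 0L)), gen_pos = 1:2,
                 ploidy = "pseudohaploid")
  r2 <- pairwise_mismatch(gm2, "i1", "i2")
  expect_false(r2$defined)
  expect_true(is.na(r2$rate))
})

test_that("duplicate pairs show about half the unrelated mismatch rate", {
  set.seed(7)
  S <- 40000
  p <- runif(S, 0.05, 0.95)
  g1 <- rbinom(S, 2, p)  # one diploid individual, sampled twice
  g2 <- rbinom(S, 2, p)  # an unrelated individual
  draw <- function(g) 2L * rbinom(length(g), 1, g / 2)
  gm <- make_gm(cbind(draw(g1), draw(g1), draw(g2)), gen_pos = seq_len(S) / 100,
                ploidy = "pseudohaploid")
  dup <- pairwise_mismatch(gm, "i1", "i2")$rate
  unrel <- pairwise_mismatch(gm, "i1", "i3")$rate
  expect_lt(abs(dup / unrel - 0.5), 0.05)
})

test_that("conditional nucleotide diversity enumerates pairs and tracks drift", {
  gm <- make_gm(matrix(0L, 5, 3), gen_pos = 1:5, ploidy = "pseudohaploid",
                group = "pop")
  r <- conditional_nucleotide_diversity(gm, "pop")
  expect_equal(nrow(r$pairs), 3)  # 3 choose 2
  expect_equal(r$mean_cnd, 0)
  expect_error(conditional_nucleotide_diversity(
    subset_genotypes(gm, individuals = 1), "pop"), ">= 2")
  # stronger drift (lower diversity) -> lower CND
  tree <- data.frame(parent = c("root", "root"), child = c("Lo", "Hi"),
                     F = c(0.02, 0.5))
  cfg <- sim_config(seed = 12, tree = tree, n_sites = 20000,
                    samples = data.frame(leaf = c("Lo", "Hi"), n_diploid = 0L,
                                         n_pseudohaploid = 5L,
                                         mean_coverage = Inf,
                                         damage_rate = 0))
  gm2 <- simulate_study(cfg)$genotypes
  set.seed(1)
  cnd_lo <- conditional_nucleotide_diversity(gm2, "Lo")$mean_cnd
  cnd_hi <- conditional_nucleotide_diversity(gm2, "Hi")$mean_cnd
  expect_gt(cnd_lo, cnd_hi)
})

test_that("heterozygosity is the autosomal heterozygote fraction of diploids", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 1L)), gen_pos = 1:4)
  expect_equal(heterozygosity(gm, "i1"), 0.5)
  gm_hom <- make_gm(cbind(c(0L, 2L, 0L, NA)), gen_pos = 1:4)
  expect_equal(heterozygosity(gm_hom, "i1"), 0)
  gm_ph <- make_gm(cbind(c(0L, 2L)), gen_pos = 1:2, ploidy = "pseudohaploid")
  expect_error(heterozygosity(gm_ph, "i1"), "pseudohaploid")
  # X sites are excluded
  gm_x <- make_gm(cbind(c(0L, 1L, 1L, 1L)), gen_pos = c(1, 2, 1, 2),
                  chrom = c("1", "1", "X", "X"))
  expect_equal(heterozygosity(gm_x, "i1"), 0.5)
  # diploids at p = 0.5 sites have heterozygosity ~ 0.5
  set.seed(2)
  gm5 <- make_gm(cbind(rbinom(20000, 2, 0.5)), gen_pos = seq_len(20000) / 100)
  expect_lt(abs(heterozygosity(gm5, "i1") - 0.5), 0.02)
})

test_that("single-strand calling is immune to terminal deamination", {
  cfg <- sim_config(seed = 13, n_sites = 4000, n_chrom = 2,
                    chrom_length_cm = 50,
                    samples = data.frame(leaf = "SrcA", n_diploid = 0L,
                                         n_pseudohaploid = 3L,
                                         mean_coverage = Inf,
                                         damage_rate = 0))
  st <- simulate_study(cfg)
  truth <- st$genotypes
  pu <- simulate_pileups(truth, mean_coverage = 4, damage_rate = 1, seed = 14)
  calls <- call_pseudohaploid(pu, truth$sites, mode = "single_strand",
                              seed = 15)
  pair <- paste(pmin(truth$sites$ref, truth$sites$alt),
                pmax(truth$sites$ref, truth$sites$alt))
  prone <- pair %in% c("C T", "A G")
  jj <- match(truth$individuals$individual_id, calls$individuals$individual_id)
  mismatches <- 0L
  for (k in seq_along(jj)) {
    g <- truth$codes[prone, k]
    cc <- calls$codes[prone, jj[k]]
    ok <- !is.na(cc)  # pseudohaploid truth is homozygous: calls must agree
    mismatches <- mismatches + sum(cc[ok] != g[ok])
  }
  expect_identical(mismatches, 0L)
})

test_that("mismatch rates order duplicates, parent-offspring and unrelated", {
  set.seed(17)
  S <- 40000
  p <- runif(S, 0.05, 0.95)
  parent <- rbinom(S, 2, p)
  # child inherits one parental allele plus one population allele
  child <- rbinom(S, 1, parent / 2) + rbinom(S, 1, p)
  unrelated <- rbinom(S, 2, p)
  draw <- function(g) 2L * rbinom(length(g), 1, g / 2)
  gm <- make_gm(cbind(draw(parent), draw(parent), draw(child),
                      draw(unrelated)),
                gen_pos = seq_len(S) / 100, ploidy = "pseudohaploid")
  dup <- pairwise_mismatch(gm, "i1", "i2")$rate
  po <- pairwise_mismatch(gm, "i1", "i3")$rate
  unrel <- pairwise_mismatch(gm, "i1", "i4")$rate
  expect_lt(dup, po)
  expect_lt(po, unrel)
})
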