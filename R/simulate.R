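#' Simulation configuration for synthetic test data
#'
#' Describes a population system for the frequency-level simulator: a rooted
#' drift tree (Balding-Nichols diffusion along each branch, parameter `F` in
#' (0,1)), optional admixture pulses between leaves (with proportion `alpha`
#' and, for sex-biased pulses, female/male source-side contributions
#' `sf`/`sm`), and a sampling design per leaf (numbers of diploid and
#' pseudohaploid individuals, mean sequencing coverage driving missingness,
#' terminal-damage rate for pileup realism).
#'
#' A sex-biased pulse with female contribution `sf` and male contribution
#' `sm` produces expected source-A ancestry `(sf + sm)/2` on the autosomes
#' and `(2*sf + sm)/3` on the X chromosome; `alpha` must equal `(sf + sm)/2`.
#'
#' @param seed Integer seed; all simulator output is reproducible from it.
#' @param tree data.frame with columns `parent`, `child`, `F` describing a
#'   rooted topology; the root is the unique parent that is never a child.
#' @param n_sites Total number of simulated SNPs.
#' @param n_chrom Number of autosomes the sites are spread over.
#' @param chrom_length_cm Genetic length of each chromosome.
#' @param x_fraction Fraction of sites placed on the X chromosome (label
#'   `"X"`); 0 disables X simulation.
#' @param admixture_events data.frame with columns `target`, `source_a`,
#'   `source_b`, `alpha` (proportion from source A), `generations_ago`, and
#'   optionally `sf`, `sm` (NA = sex-balanced).
#' @param samples data.frame with columns `leaf`, `n_diploid`,
#'   `n_pseudohaploid`, `mean_coverage` (Inf = complete data),
#'   `damage_rate`.
#' @param sex_ratio Probability a sampled individual is XX.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, tree = default_sim_tree(), n_sites = 50000,
                       n_chrom = 10, chrom_length_cm = 100, x_fraction = 0,
                       admixture_events = NULL, samples = default_sim_samples(),
                       sex_ratio = 0.5) {
  tree <- as.data.frame(tree)
  stopifnot(all(c("parent", "child", "F") %in% names(tree)))
  if (any(tree$F <= 0 | tree$F >= 1))
    stop("branch drift parameters F must lie strictly in (0, 1)")
  if (chrom_length_cm <= 0) stop("chromosome length must be positive")
  if (n_sites < 1) stop("n_sites must be at least 1")
  if (!is.null(admixture_events)) {
    admixture_events <- as.data.frame(admixture_events)
    stopifnot(all(c("target", "source_a", "source_b", "alpha") %in%
                    names(admixture_events)))
    if (is.null(admixture_events$generations_ago))
      admixture_events$generations_ago <- 10
    if (is.null(admixture_events$sf)) admixture_events$sf <- NA_real_
    if (is.null(admixture_events$sm)) admixture_events$sm <- NA_real_
    if (any(admixture_events$alpha < 0 | admixture_events$alpha > 1))
      stop("admixture proportions alpha must lie in [0, 1]")
    sb <- !is.na(admixture_events$sf)
    if (any(sb)) {
      ev <- admixture_events[sb, ]
      if (any(ev$sf < 0 | ev$sf > 1 | ev$sm < 0 | ev$sm > 1))
        stop("sf and sm must lie in [0, 1]")
      if (any(ev$sf == 0 & ev$sm == 0 & ev$alpha > 0))
        stop("sf = sm = 0 is inconsistent with alpha > 0")
      if (any(abs(ev$alpha - (ev$sf + ev$sm) / 2) > 1e-8))
        stop("sex-biased events require alpha = (sf + sm)/2")
    }
  }
  samples <- as.data.frame(samples)
  stopifnot(all(c("leaf", "n_diploid", "n_pseudohaploid") %in% names(samples)))
  if (is.null(samples$mean_coverage)) samples$mean_coverage <- Inf
  if (is.null(samples$damage_rate)) samples$damage_rate <- 0
  if (any(samples$damage_rate < 0 | samples$damage_rate > 1))
    stop("damage rates must lie in [0, 1]")
  structure(list(seed = as.integer(seed), tree = tree, n_sites = n_sites,
                 n_chrom = n_chrom, chrom_length_cm = chrom_length_cm,
                 x_fraction = x_fraction, admixture_events = admixture_events,
                 samples = samples, sex_ratio = sex_ratio),
            class = "sim_config")
}

#' Default drift tree used by the shipped simulations
#'
#' A deep basal outgroup `Out` (drift 0.4, emulating a deeply diverged
#' lineage), a right-set leaf `R1` splitting early, and two source clades:
#' `SrcA` with sister right-leaf `R2`, and `SrcB` with sister right-leaf
#' `R3`. Internal drifts of 0.05 give clearly resolvable structure at typical
#' test panel sizes.
#'
#' @return data.frame with columns `parent`, `child`, `F`.
#' @export
default_sim_tree <- function() {
  data.frame(
    parent = c("root", "root", "n1",  "n1", "n2",  "n2", "n3",   "n3", "n4",   "n4"),
    child  = c("Out",  "n1",   "R1",  "n2", "n3",  "n4", "SrcA", "R2", "SrcB", "R3"),
    F      = c(0.4,    0.05,   0.05,  0.05, 0.05,  0.05, 0.05,   0.05, 0.05,   0.05),
    stringsAsFactors = FALSE)
}

#' Default sampling design: ten pseudohaploid individuals per default-tree leaf
#' @return data.frame with one row per leaf of [default_sim_tree()].
#' @export
default_sim_samples <- function() {
  leaves <- c("Out", "R1", "R2", "R3", "SrcA", "SrcB")
  data.frame(leaf = leaves, n_diploid = 0L, n_pseudohaploid = 10L,
             mean_coverage = Inf, damage_rate = 0, stringsAsFactors = FALSE)
}

sim_tree_leaves <- function(tree) setdiff(tree$child, tree$parent)

sim_site_table <- function(config) {
  n_x <- round(config$n_sites * config$x_fraction)
  n_auto <- config$n_sites - n_x
  per <- diff(round(seq(0, n_auto, length.out = config$n_chrom + 1)))
  chrom <- rep(as.character(seq_len(config$n_chrom)), per)
  gen_pos <- unlist(lapply(per, function(k)
    seq(0, config$chrom_length_cm, length.out = max(k, 2))[seq_len(k)]),
    use.names = FALSE)
  if (n_x > 0) {
    chrom <- c(chrom, rep("X", n_x))
    gen_pos <- c(gen_pos,
                 seq(0, config$chrom_length_cm, length.out = max(n_x, 2))[seq_len(n_x)])
  }
  alleles <- c("A", "C", "G", "T")
  n <- length(chrom)
  ref_idx <- sample.int(4, n, replace = TRUE)
  alt_idx <- (ref_idx - 1 + sample.int(3, n, replace = TRUE)) %% 4 + 1
  data.frame(site_id = paste0("snp", seq_len(n)), chrom = chrom,
             phys_pos = round(gen_pos * 1e6) + 1, gen_pos = gen_pos,
             ref = alleles[ref_idx], alt = alleles[alt_idx],
             stringsAsFactors = FALSE)
}

#' Simulate per-leaf allele frequencies along a drift tree
#'
#' Ancestral frequencies are drawn Uniform(0.05, 0.95); along each branch
#' with drift `F` the child frequency is Beta(p(1-F)/F, (1-p)(1-F)/F)
#' (Balding-Nichols), so that E(child) = p and Var(child) = F p(1-p).
#' Admixture events then set the target leaf's frequency to
#' `alpha * pA + (1 - alpha) * pB`; for sex-biased events the X-chromosome
#' sites use the X-specific expected proportion `(2 sf + sm)/3`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_freqs`: list with `freq` (sites x leaves
#'   matrix), `p0` (ancestral frequencies), `sites` (site table) and the
#'   config.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- sim_site_table(config)
  S <- nrow(sites)
  p0 <- stats::runif(S, 0.05, 0.95)
  node_freq <- list(root = p0)
  tree <- config$tree
  remaining <- seq_len(nrow(tree))
  while (length(remaining) > 0) {
    ready <- remaining[tree$parent[remaining] %in% names(node_freq)]
    if (length(ready) == 0)
      stop("tree is not connected to the root")
    for (i in ready) {
      p <- node_freq[[tree$parent[i]]]
      F <- tree$F[i]
      if (F < 1e-12) {
        node_freq[[tree$child[i]]] <- p
      } else {
        node_freq[[tree$child[i]]] <-
          stats::rbeta(S, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      }
    }
    remaining <- setdiff(remaining, ready)
  }
  leaves <- sim_tree_leaves(tree)
  freq <- do.call(cbind, node_freq[leaves])
  colnames(freq) <- leaves
  ev <- config$admixture_events
  if (!is.null(ev)) {
    on_x <- sites$chrom == "X"
    for (i in seq_len(nrow(ev))) {
      pa <- freq[, ev$source_a[i]]
      pb <- freq[, ev$source_b[i]]
      a_auto <- ev$alpha[i]
      a_x <- if (!is.na(ev$sf[i])) (2 * ev$sf[i] + ev$sm[i]) / 3 else a_auto
      mixed <- a_auto * pa + (1 - a_auto) * pb
      mixed[on_x] <- a_x * pa[on_x] + (1 - a_x) * pb[on_x]
      if (ev$target[i] %in% colnames(freq)) {
        freq[, ev$target[i]] <- mixed
      } else {
        freq <- cbind(freq, mixed)
        colnames(freq)[ncol(freq)] <- ev$target[i]
      }
    }
  }
  structure(list(freq = freq, p0 = p0, sites = sites, config = config),
            class = "sim_freqs")
}

#' Sample genotypes from simulated leaf frequencies
#'
#' Diploid genotypes are Binomial(2, p); pseudohaploid genotypes are a single
#' Bernoulli(p) allele recorded as homozygous (codes 0/2). A site is missing
#' for an individual when a Poisson(mean_coverage) draw is zero.
#'
#' @param sim A [simulate_frequencies()] result.
#' @param config Optional [sim_config()] overriding `sim$config` (e.g. to
#'   change the sampling design without re-simulating frequencies).
#' @return A [genotype_matrix()] whose groups are the sampled leaf names.
#' @export
simulate_genotypes <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_freqs"))
  set.seed(config$seed + 1L)
  S <- nrow(sim$sites)
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(config$samples))) {
    row <- config$samples[i, ]
    if (!row$leaf %in% colnames(sim$freq))
      stop("no simulated frequencies for leaf ", row$leaf)
    p <- sim$freq[, row$leaf]
    n_total <- row$n_diploid + row$n_pseudohaploid
    if (n_total == 0) next
    for (k in seq_len(n_total)) {
      dip <- k <= row$n_diploid
      g <- if (dip) stats::rbinom(S, 2, p) else 2L * stats::rbinom(S, 1, p)
      if (is.finite(row$mean_coverage))
        g[stats::rpois(S, row$mean_coverage) == 0] <- NA_integer_
      cols[[length(cols) + 1]] <- g
      meta[[length(meta) + 1]] <- data.frame(
        individual_id = sprintf("%s_%s%d", row$leaf, if (dip) "d" else "p",
                                if (dip) k else k - row$n_diploid),
        group = row$leaf,
        sex = if (stats::runif(1) < config$sex_ratio) "XX" else "XY",
        ploidy = if (dip) "diploid" else "pseudohaploid",
        stringsAsFactors = FALSE)
    }
  }
  genotype_matrix(sim$sites, do.call(cbind, cols), do.call(rbind, meta))
}

#' One-call study simulation
#'
#' Convenience wrapper: [simulate_frequencies()] followed by
#' [simulate_genotypes()].
#'
#' @param config A [sim_config()].
#' @return List with elements `freqs` (`sim_freqs`) and `genotypes`
#'   ([genotype_matrix()]).
#' @export
simulate_study <- function(config) {
  sf <- simulate_frequencies(config)
  list(freqs = sf, genotypes = simulate_genotypes(sf))
}

#' Simulate ancestry tract paintings after an admixture pulse
#'
#' Ancestry along each haploid chromosome copy is a two-state Markov process:
#' switch points occur as a Poisson process with rate `generations_ago` per
#' Morgan, and at the origin and at every switch point the state is source A
#' with probability `alpha`. The expected number of tracts per chromosome is
#' therefore `1 + generations_ago * length_in_Morgans`.
#'
#' @param config A [sim_config()] (supplies chromosome number/length and the
#'   seed).
#' @param event One row of `config$admixture_events` (default: the first).
#' @param n_haplotypes Number of haploid chromosome copies to paint.
#' @return data.frame with columns `hap`, `chrom`, `start_cm`, `end_cm`,
#'   `source` (`"A"`/`"B"`); intervals tile each chromosome.
#' @export
simulate_tracts <- function(config, event = NULL, n_haplotypes = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(event)) {
    if (is.null(config$admixture_events))
      stop("config has no admixture events")
    event <- config$admixture_events[1, ]
  }
  if (event$generations_ago < 1) stop("generations_ago must be >= 1")
  if (config$chrom_length_cm <= 0) stop("zero-length chromosome")
  set.seed(config$seed + 2L)
  L <- config$chrom_length_cm
  rate_per_cm <- event$generations_ago / 100
  out <- vector("list", n_haplotypes * config$n_chrom)
  k <- 0
  for (h in seq_len(n_haplotypes)) {
    for (ch in seq_len(config$n_chrom)) {
      n_sw <- stats::rpois(1, rate_per_cm * L)
      breaks <- sort(stats::runif(n_sw, 0, L))
      starts <- c(0, breaks)
      ends <- c(breaks, L)
      src <- ifelse(stats::runif(length(starts)) < event$alpha, "A", "B")
      k <- k + 1
      out[[k]] <- data.frame(hap = h, chrom = as.character(ch),
                             start_cm = starts, end_cm = ends, source = src,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a dating benchmark dataset
#'
#' Builds a complete pipeline input for admixture-date estimation: two source
#' populations diverged by Balding-Nichols drift, a target of diploid
#' individuals whose haplotypes are painted by [simulate_tracts()] at a known
#' pulse age, and alleles drawn from the source-specific frequency of the
#' tract covering each site.
#'
#' @param seed Integer seed.
#' @param generations_ago True pulse age in generations.
#' @param alpha Proportion of source-A ancestry.
#' @param n_individuals Number of diploid target individuals.
#' @param n_chrom,chrom_length_cm,n_sites_per_chrom Map layout.
#' @param source_divergence_f Drift of each source from their shared
#'   ancestor; controls the informativeness of the frequency weights.
#' @return List: `genotypes` (target [genotype_matrix()]), `pa`, `pb`
#'   (per-site source frequencies), `generations_ago`, `alpha`.
#' @export
simulate_dating_dataset <- function(seed = 1, generations_ago = 40,
                                    alpha = 0.3, n_individuals = 20,
                                    n_chrom = 30, chrom_length_cm = 100,
                                    n_sites_per_chrom = 600,
                                    source_divergence_f = 0.2) {
  set.seed(seed)
  S <- n_chrom * n_sites_per_chrom
  gen_one <- seq(0, chrom_length_cm, length.out = n_sites_per_chrom)
  sites <- data.frame(
    site_id = paste0("snp", seq_len(S)),
    chrom = rep(as.character(seq_len(n_chrom)), each = n_sites_per_chrom),
    phys_pos = rep(round(gen_one * 1e6) + 1, n_chrom),
    gen_pos = rep(gen_one, n_chrom),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  p0 <- stats::runif(S, 0.05, 0.95)
  Fd <- source_divergence_f
  pa <- stats::rbeta(S, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  pb <- stats::rbeta(S, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
  rate_per_cm <- generations_ago / 100
  codes <- matrix(0L, S, n_individuals)
  for (i in seq_len(n_individuals)) {
    g <- integer(S)
    for (hap in 1:2) {
      for (ch in seq_len(n_chrom)) {
        idx <- ((ch - 1) * n_sites_per_chrom + 1):(ch * n_sites_per_chrom)
        n_sw <- stats::rpois(1, rate_per_cm * chrom_length_cm)
        breaks <- sort(stats::runif(n_sw, 0, chrom_length_cm))
        seg_src <- stats::runif(length(breaks) + 1) < alpha  # TRUE = A
        seg_of_site <- findInterval(gen_one, breaks) + 1
        is_a <- seg_src[seg_of_site]
        p_site <- ifelse(is_a, pa[idx], pb[idx])
        g[idx] <- g[idx] + stats::rbinom(n_sites_per_chrom, 1, p_site)
      }
    }
    codes[, i] <- g
  }
  inds <- data.frame(individual_id = paste0("T", seq_len(n_individuals)),
                     group = "Target", sex = "UNKNOWN", ploidy = "diploid",
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(sites, codes, inds), pa = pa, pb = pb,
       generations_ago = generations_ago, alpha = alpha)
}

#' Simulate per-individual ancestry under a sex-biased pulse
#'
#' Draws realized autosomal and X-chromosome ancestry proportions around the
#' single-pulse expectations `(sf + sm)/2` (autosomes) and `(2 sf + sm)/3`
#' (X), using a Beta distribution with the given concentration.
#'
#' @param config A [sim_config()].
#' @param event One row of `config$admixture_events` with `sf`, `sm` set.
#' @param n_individuals Number of individuals to draw.
#' @param concentration Beta concentration controlling individual scatter.
#' @return data.frame with `individual`, `autosomal_ancestry`, `x_ancestry`;
#'   attributes `expected_autosomal` and `expected_x` carry the truth.
#' @export
simulate_sex_biased_event <- function(config, event = NULL,
                                      n_individuals = 50,
                                      concentration = 200) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(event)) event <- config$admixture_events[1, ]
  if (is.na(event$sf) || is.na(event$sm))
    stop("event must specify sf and sm")
  if (event$sf == 0 && event$sm == 0 && event$alpha > 0)
    stop("sf = sm = 0 is inconsistent with alpha > 0")
  set.seed(config$seed + 3L)
  mu_a <- (event$sf + event$sm) / 2
  mu_x <- (2 * event$sf + event$sm) / 3
  draw <- function(mu) {
    if (mu <= 0 || mu >= 1) return(rep(mu, n_individuals))
    stats::rbeta(n_individuals, mu * concentration, (1 - mu) * concentration)
  }
  out <- data.frame(individual = paste0("ind", seq_len(n_individuals)),
                    autosomal_ancestry = draw(mu_a), x_ancestry = draw(mu_x),
                    stringsAsFactors = FALSE)
  attr(out, "expected_autosomal") <- mu_a
  attr(out, "expected_x") <- mu_x
  out
}

#' Simulate a per-site read pileup with terminal deamination damage
#'
#' For every individual and non-missing site, a Poisson(`mean_coverage`)
#' number of reads is drawn from the individual's true alleles. With
#' probability `damage_rate`, a read carrying C on the forward strand (or G
#' on the reverse strand) within 3 bp of a read end is flipped C->T (G->A)
#' and flagged as damaged; flips are applied only where the damage product is
#' the site's other allele, so observed bases stay within \{ref, alt\}.
#'
#' @param gm A [genotype_matrix()] holding the truth genotypes.
#' @param mean_coverage Mean reads per site.
#' @param damage_rate Deamination probability `delta` in `[0, 1]`.
#' @param seed Integer seed.
#' @param baseq,mapq Constant qualities written to the table.
#' @return data.frame with columns `individual`, `chrom`, `pos`, `ref`,
#'   `alt`, `base`, `strand`, `dist_end`, `baseq`, `mapq`, `damaged`.
#' @export
simulate_pileups <- function(gm, mean_coverage = 2, damage_rate = 0,
                             seed = 1, baseq = 37L, mapq = 60L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (damage_rate < 0 || damage_rate > 1)
    stop("damage_rate must lie in [0, 1]")
  set.seed(seed)
  S <- nrow(gm$sites)
  out <- vector("list", ncol(gm$codes))
  for (j in seq_len(ncol(gm$codes))) {
    g <- gm$codes[, j]
    depth <- stats::rpois(S, mean_coverage)
    depth[is.na(g)] <- 0L
    tot <- sum(depth)
    if (tot == 0) next
    site_idx <- rep.int(seq_len(S), depth)
    dose <- g[site_idx] / 2
    base <- ifelse(stats::runif(tot) < dose, gm$sites$alt[site_idx],
                   gm$sites$ref[site_idx])
    strand <- ifelse(stats::runif(tot) < 0.5, "+", "-")
    dist_end <- sample(0:19, tot, replace = TRUE)
    other <- ifelse(base == gm$sites$ref[site_idx], gm$sites$alt[site_idx],
                    gm$sites$ref[site_idx])
    can_ct <- base == "C" & strand == "+" & other == "T"
    can_ga <- base == "G" & strand == "-" & other == "A"
    hit <- (can_ct | can_ga) & dist_end <= 3 &
      stats::runif(tot) < damage_rate
    base[hit & can_ct] <- "T"
    base[hit & can_ga] <- "A"
    out[[j]] <- data.frame(
      individual = gm$individuals$individual_id[j],
      chrom = gm$sites$chrom[site_idx], pos = gm$sites$phys_pos[site_idx],
      ref = gm$sites$ref[site_idx], alt = gm$sites$alt[site_idx],
      base = base, strand = strand, dist_end = dist_end,
      baseq = baseq, mapq = mapq, damaged = hit,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Construct an IBD fixture with planted gaps and discordances
#'
#' Plants known post-merge ("truth") IBD segments for `n_pairs` individual
#' pairs, then emits a raw segment table in which some segments are split by
#' gaps: a clean gap narrower than 0.6 cM (should be re-merged), a gap of
#' 0.7 cM (should stay split), a narrow gap containing two discordant
#' homozygote sites (should stay split), an intact segment, and a sub-1 cM
#' fragment (should be removed by the length filter). A genotype matrix with
#' the planted discordant homozygotes is returned for the gap rule.
#'
#' @param seed Integer seed (layout is deterministic; the seed selects which
#'   scenario each pair receives).
#' @param n_pairs Number of individual pairs.
#' @return List: `segments` (raw table), `truth` (expected post-processing
#'   segments), `truth_pairs` (expected per-pair summaries), `genotypes`
#'   ([genotype_matrix()] for the discordance counts).
#' @export
simulate_ibd_fixture <- function(seed = 1, n_pairs = 5) {
  set.seed(seed)
  scen <- rep_len(c("clean_gap", "wide_gap", "discordant_gap", "intact",
                    "short_fragment"), n_pairs)
  scen <- sample(scen)  # order varies with seed, composition fixed
  gen_pos <- seq(0.025, 30, by = 0.05)
  sites <- data.frame(site_id = paste0("m", seq_along(gen_pos)), chrom = "1",
                      phys_pos = round(gen_pos * 1e6) + 1, gen_pos = gen_pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  n_ind <- 2 * n_pairs
  codes <- matrix(0L, nrow(sites), n_ind)
  inds <- data.frame(individual_id = sprintf("I%02d", seq_len(n_ind)),
                     group = "fixture", sex = "UNKNOWN", ploidy = "diploid",
                     stringsAsFactors = FALSE)
  seg <- list(); truth <- list()
  add <- function(lst, id1, id2, s, e)
    c(lst, list(data.frame(id1 = id1, id2 = id2, chrom = "1", start_cm = s,
                           end_cm = e, stringsAsFactors = FALSE)))
  for (p in seq_len(n_pairs)) {
    id1 <- inds$individual_id[2 * p - 1]
    id2 <- inds$individual_id[2 * p]
    if (scen[p] == "clean_gap") {
      seg <- add(seg, id1, id2, 10, 15); seg <- add(seg, id1, id2, 15.4, 22)
      truth <- add(truth, id1, id2, 10, 22)
    } else if (scen[p] == "wide_gap") {
      seg <- add(seg, id1, id2, 10, 15); seg <- add(seg, id1, id2, 15.7, 22)
      truth <- add(truth, id1, id2, 10, 15)
      truth <- add(truth, id1, id2, 15.7, 22)
    } else if (scen[p] == "discordant_gap") {
      seg <- add(seg, id1, id2, 10, 15); seg <- add(seg, id1, id2, 15.4, 22)
      truth <- add(truth, id1, id2, 10, 15)
      truth <- add(truth, id1, id2, 15.4, 22)
      inside <- which(gen_pos > 15.05 & gen_pos < 15.35)[1:2]
      codes[inside, 2 * p - 1] <- 0L
      codes[inside, 2 * p] <- 2L
    } else if (scen[p] == "intact") {
      seg <- add(seg, id1, id2, 10, 22)
      truth <- add(truth, id1, id2, 10, 22)
    } else {  # short_fragment
      seg <- add(seg, id1, id2, 10, 22); seg <- add(seg, id1, id2, 25, 25.8)
      truth <- add(truth, id1, id2, 10, 22)
    }
  }
  segments <- do.call(rbind, seg)
  segments$length_cm <- segments$end_cm - segments$start_cm
  truth <- do.call(rbind, truth)
  truth$length_cm <- truth$end_cm - truth$start_cm
  truth_pairs <- aggregate_pairs(ibd_segments(truth))
  list(segments = ibd_segments(segments), truth = ibd_segments(truth),
       truth_pairs = truth_pairs, scenarios = scen,
       genotypes = genotype_matrix(sites, codes, inds))
}
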