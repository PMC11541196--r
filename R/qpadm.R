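#' Matrix of f4 statistics between a left and a right population set
#'
#' Builds the (|left|-1) x (|right|-1) matrix `X[i, j] = f4(left_1, left_{i+1};
#' right_1, right_{j+1})` together with its per-block leave-one-out jackknife
#' replicates, the substrate for rank (multi-wave) tests and
#' admixture-proportion estimation. The rank of the expectation of X equals
#' the number of independent ancestry waves relating the left to the right
#' set (rank 0 for two left populations means they form a clade with respect
#' to the rights).
#'
#' @param freqs A [group_frequencies()] table.
#' @param left,right Disjoint character vectors of group labels (each >= 2).
#' @param blocks A [partition_blocks()] result.
#' @param site_mode `"allsnps"` (default: each f4 uses every site where its
#'   own four populations are defined) or `"intersection"` (all left and
#'   right populations defined).
#' @return An object of class `f4_matrix`: list with `X` (estimate matrix),
#'   `x` (its column-major vectorization), `loo` (blocks x entries matrix of
#'   leave-one-block-out replicates), `n_snps` per entry, `left`, `right`,
#'   `g` (block count).
#' @export
build_f4_matrix <- function(freqs, left, right, blocks,
                            site_mode = c("allsnps", "intersection")) {
  site_mode <- match.arg(site_mode)
  if (length(left) < 2 || length(right) < 2)
    stop("left and right sets each need at least 2 populations")
  shared <- intersect(left, right)
  if (length(shared) > 0)
    stop("left and right sets share label(s): ", paste(shared, collapse = ", "))
  p <- freqs$freq
  missing_pop <- setdiff(c(left, right), colnames(p))
  if (length(missing_pop) > 0)
    stop("group(s) not in frequency table: ", paste(missing_pop, collapse = ", "))
  sb <- site_block_index(blocks)
  g <- nrow(blocks)
  L1 <- length(left) - 1
  R1 <- length(right) - 1
  q <- L1 * R1
  inter_mask <- if (site_mode == "intersection")
    rowSums(is.na(p[, c(left, right), drop = FALSE])) == 0 else NULL
  X <- matrix(NA_real_, L1, R1,
              dimnames = list(left[-1], right[-1]))
  loo <- num_blocks <- den_blocks <- matrix(NA_real_, g, q)
  n_snps <- integer(q)
  dl0 <- p[, left[1]]
  dr0 <- p[, right[1]]
  for (i in seq_len(L1)) {
    dl <- dl0 - p[, left[i + 1]]
    for (j in seq_len(R1)) {
      ent <- (j - 1) * L1 + i  # column-major position in vec(X)
      num <- dl * (dr0 - p[, right[j + 1]])
      use <- if (site_mode == "intersection") inter_mask else !is.na(num)
      use <- use & !is.na(num)
      if (!any(use))
        stop("no usable sites for f4(", left[1], ", ", left[i + 1], "; ",
             right[1], ", ", right[j + 1], ")")
      num_b <- den_b <- numeric(g)
      agg <- rowsum(cbind(num[use], 1), sb[use])
      rows <- as.integer(rownames(agg))
      num_b[rows] <- agg[, 1]
      den_b[rows] <- agg[, 2]
      N <- sum(num_b); D <- sum(den_b)
      X[i, j] <- N / D
      loo[, ent] <- (N - num_b) / (D - den_b)
      num_blocks[, ent] <- num_b
      den_blocks[, ent] <- den_b
      n_snps[ent] <- D
    }
  }
  structure(list(X = X, x = as.vector(X), loo = loo,
                 num_blocks = num_blocks, den_blocks = den_blocks,
                 n_snps = n_snps, left = left, right = right, g = g,
                 site_mode = site_mode),
            class = "f4_matrix")
}

# p-value for a jackknife-covariance quadratic form. The covariance of the
# f4 vector is itself estimated from g blocks, so the quadratic form follows
# a Hotelling-type scaled F distribution rather than the asymptotic
# chi-square; both calibrations are returned and the F-based one is used as
# the headline p-value.
quadform_pvalues <- function(chi_square, df, g) {
  p_chisq <- stats::pchisq(chi_square, df, lower.tail = FALSE)
  if (g > df + 1) {
    fstat <- chi_square * (g - df) / (df * (g - 1))
    p <- stats::pf(fstat, df, g - df, lower.tail = FALSE)
  } else {
    p <- p_chisq
  }
  list(p_value = p, p_chisq = p_chisq)
}

#' Rank test on an f4 matrix (multi-wave / clade test)
#'
#' Tests whether the expectation of the f4 matrix has rank at most `rank`.
#' The covariance of the vectorized matrix is estimated from the block
#' jackknife replicates; the best rank-`rank` approximation `A B'` is fitted
#' by alternating generalized least squares under that covariance, and the
#' residual quadratic form is referred to its null distribution with
#' `df = (|left|-1-rank) * (|right|-1-rank)` degrees of freedom. For
#' `rank = 0` the statistic is simply `x' Q^{-1} x`. With `left` a pair of
#' populations, the rank-0 test is the clade/continuity test: the pair is
#' consistent with forming a clade relative to the right set when `p > 0.01`.
#'
#' Because Q is itself a g-block jackknife estimate, p-values use a
#' Hotelling-style F calibration (exactly accounting for the finite number of
#' blocks); the asymptotic chi-square p-value is also reported as `p_chisq`.
#'
#' @param fm An [build_f4_matrix()] result.
#' @param rank Tested rank (>= 0; `df` must stay >= 1).
#' @return An object of class `rank_test`: list with `left`, `right`,
#'   `tested_rank`, `chi_square`, `df`, `p_value`, `p_chisq`, `fitted`.
#' @export
rank_test <- function(fm, rank = 0) {
  stopifnot(inherits(fm, "f4_matrix"))
  L1 <- length(fm$left) - 1
  R1 <- length(fm$right) - 1
  df <- (L1 - rank) * (R1 - rank)
  if (df < 1) stop("rank ", rank, " leaves no degrees of freedom")
  Q <- jackknife_covariance(fm$loo)
  x <- fm$x
  if (rank == 0) {
    fitted <- matrix(0, L1, R1)
    resid <- x
  } else {
    sv <- svd(fm$X, nu = rank, nv = rank)
    A <- sv$u %*% diag(sqrt(sv$d[seq_len(rank)]), rank)
    B <- sv$v %*% diag(sqrt(sv$d[seq_len(rank)]), rank)
    # commutation matrix: vec(X') = K vec(X)
    K <- matrix(0, L1 * R1, L1 * R1)
    for (i in seq_len(L1)) for (j in seq_len(R1))
      K[(i - 1) * R1 + j, (j - 1) * L1 + i] <- 1
    Qt <- K %*% Q %*% t(K)
    xt <- as.vector(t(fm$X))
    chi_old <- Inf
    for (iter in seq_len(300)) {
      M <- kronecker(B, diag(L1))
      QiM <- apply(M, 2, function(col) solve_psd(Q, col))
      A <- matrix(solve(crossprod(M, QiM), crossprod(QiM, x)), L1, rank)
      Mt <- kronecker(A, diag(R1))
      QiMt <- apply(Mt, 2, function(col) solve_psd(Qt, col))
      B <- matrix(solve(crossprod(Mt, QiMt), crossprod(QiMt, xt)), R1, rank)
      resid <- x - as.vector(A %*% t(B))
      chi_new <- sum(resid * solve_psd(Q, resid))
      if (abs(chi_old - chi_new) < 1e-10) break
      chi_old <- chi_new
    }
    fitted <- A %*% t(B)
    resid <- x - as.vector(fitted)
  }
  chi_square <- sum(resid * solve_psd(Q, resid))
  pv <- quadform_pvalues(chi_square, df, fm$g)
  structure(list(left = fm$left, right = fm$right, tested_rank = rank,
                 chi_square = chi_square, df = df, p_value = pv$p_value,
                 p_chisq = pv$p_chisq, fitted = fitted, g = fm$g),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("rank_test: rank %d, chi2 %.3f, df %d, p %.4g\n",
              x$tested_rank, x$chi_square, x$df, x$p_value))
  cat("  left:", paste(x$left, collapse = ", "), "\n")
  cat("  right:", paste(x$right, collapse = ", "), "\n")
  invisible(x)
}

# one constrained GLS weight solve: minimize a' W a subject to sum(a) = 1,
# where W = Xm V^{-1} Xm' and Xm is the sources x (R-1) matrix of f4 rows.
solve_weights <- function(Xm, Vinv_chol) {
  XtV <- t(backsolve(Vinv_chol, forwardsolve(t(Vinv_chol), t(Xm))))
  W <- XtV %*% t(Xm)
  one <- rep(1, nrow(W))
  Wi1 <- tryCatch(solve(W, one), error = function(e) {
    solve(W + diag(1e-10 * mean(diag(W)), nrow(W)), one)
  })
  a <- Wi1 / sum(Wi1)
  list(a = a, chi_square = drop(t(a) %*% W %*% a))
}

chol_psd <- function(V, ridge = 1e-6) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    lambda <- ridge * mean(diag(V))
    message("covariance numerically singular; ridge-regularizing with lambda = ",
            format(lambda))
    ch <- chol(V + diag(lambda, nrow(V)))
  }
  ch
}

#' Estimate admixture proportions from a system of f4 statistics
#'
#' Models the target as a mixture of 1-3 source populations constrained by
#' f4 relationships to a right (outgroup) set: writing `y_j(P) = f4(P,
#' right_1; right_{j+1}, right_1)`, the mixture model `y(target) = sum_i a_i
#' y(source_i)` with `sum a_i = 1` is solved by generalized least squares
#' under the block-jackknife covariance of the f4 system (iterating between
#' the weight estimate and the residual covariance it implies). Weight
#' standard errors come from delete-one-block re-estimation; the residual
#' chi-square with `df = (|right|-1) - (|sources|-1)` gives the model fit
#' p-value. A 1-source model reduces to the rank-0 clade test of target with
#' the source.
#'
#' @param freqs A [group_frequencies()] table.
#' @param target Target group label.
#' @param sources 1-3 source group labels.
#' @param right Right-set (outgroup) labels; needs
#'   `length(right) - 1 >= length(sources)` so `df >= 1`.
#' @param blocks A [partition_blocks()] result.
#' @param site_mode Passed to [build_f4_matrix()] (`"allsnps"` default).
#' @return An object of class `admixture_model`: list with `target`,
#'   `sources`, `right`, `weights` (named, summing to 1), `weight_se`,
#'   `chi_square`, `df`, `p_value`, `p_chisq`, `feasible`, `n_blocks`.
#' @export
estimate_admixture <- function(freqs, target, sources, right, blocks,
                               site_mode = c("allsnps", "intersection")) {
  site_mode <- match.arg(site_mode)
  S <- length(sources)
  if (S < 1 || S > 3) stop("between 1 and 3 sources are supported")
  df <- (length(right) - 1) - (S - 1)
  if (df < 1)
    stop("right set too small: need |right| - 1 >= |sources| for df >= 1")
  fm <- build_f4_matrix(freqs, c(target, sources), right, blocks, site_mode)
  g <- fm$g
  R1 <- length(right) - 1
  if (S == 1) {
    rt <- rank_test(fm, 0)
    return(structure(list(target = target, sources = sources, right = right,
                          weights = stats::setNames(1, sources),
                          weight_se = stats::setNames(0, sources),
                          chi_square = rt$chi_square, df = rt$df,
                          p_value = rt$p_value, p_chisq = rt$p_chisq,
                          feasible = TRUE, n_blocks = g,
                          n_snps = fm$n_snps),
                     class = "admixture_model"))
  }
  # rows of X: X[i, j] = f4(target, source_i; right_1, right_{j+1});
  # residual r_j(a) = sum_i a_i X[i, j] should vanish under the model.
  Tmat <- function(a) kronecker(diag(R1), t(a))  # r = Tmat(a) %*% vec(X)
  solve_system <- function(Xm, Q, a0) {
    a <- a0
    fit <- NULL
    for (iter in seq_len(50)) {
      Tm <- Tmat(a)
      V <- Tm %*% Q %*% t(Tm)
      fit <- solve_weights(Xm, chol_psd(V))
      if (max(abs(fit$a - a)) < 1e-12) { a <- fit$a; break }
      a <- fit$a
    }
    fit
  }
  Q <- jackknife_covariance(fm$loo)
  fit <- solve_system(fm$X, Q, rep(1 / S, S))
  a <- fit$a
  # weight SEs by delete-one-block re-estimation of the full procedure:
  # each replicate rebuilds the f4 matrix, its jackknife covariance and the
  # GLS solve from the remaining blocks, so the SE also reflects the
  # variability of the estimated covariance.
  loo_w <- matrix(NA_real_, g, S)
  for (b in seq_len(g)) {
    Nb <- colSums(fm$num_blocks[-b, , drop = FALSE])
    Db <- colSums(fm$den_blocks[-b, , drop = FALSE])
    Xb <- matrix(Nb / Db, S, R1)
    loo2 <- (matrix(Nb, g - 1, length(Nb), byrow = TRUE) -
               fm$num_blocks[-b, , drop = FALSE]) /
      (matrix(Db, g - 1, length(Db), byrow = TRUE) -
         fm$den_blocks[-b, , drop = FALSE])
    Qb <- jackknife_covariance(loo2)
    loo_w[b, ] <- solve_system(Xb, Qb, a)$a
  }
  weight_se <- jackknife_se_vec(loo_w)
  pv <- quadform_pvalues(fit$chi_square, df, g)
  structure(list(target = target, sources = sources, right = right,
                 weights = stats::setNames(a, sources),
                 weight_se = stats::setNames(weight_se, sources),
                 chi_square = fit$chi_square, df = df, p_value = pv$p_value,
                 p_chisq = pv$p_chisq,
                 feasible = all(a >= 0 & a <= 1), n_blocks = g,
                 n_snps = fm$n_snps),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("admixture_model: %s = %s\n", x$target,
              paste(sprintf("%.3f (se %.3f) %s", x$weights, x$weight_se,
                            x$sources), collapse = " + ")))
  cat(sprintf("  chi2 %.3f, df %d, p %.4g, feasible %s\n", x$chi_square,
              x$df, x$p_value, x$feasible))
  invisible(x)
}

#' Model selection ladder over 1-, 2- and 3-source admixture models
#'
#' Evaluates every 1-source model, then every 2-source model, then every
#' 3-source model from the candidate list, and returns the first complexity
#' level containing a fitting model (p above the threshold with feasible
#' weights); within that level the highest-p model wins. The full ladder of
#' evaluated models is always returned.
#'
#' @param freqs A [group_frequencies()] table.
#' @param target Target group label.
#' @param candidate_sources Candidate source labels (non-empty).
#' @param right Right-set labels.
#' @param blocks A [partition_blocks()] result.
#' @param p_threshold Acceptance threshold on the fit p-value (default 0.01).
#' @param max_sources Largest model size to consider (<= 3).
#' @param ... Passed to [estimate_admixture()].
#' @return List with `model` (the chosen [estimate_admixture()] result, or
#'   `NULL` when no model fits at any level) and `ladder` (data.frame logging
#'   every evaluated model).
#' @export
model_selection_ladder <- function(freqs, target, candidate_sources, right,
                                   blocks, p_threshold = 0.01,
                                   max_sources = 3, ...) {
  if (length(candidate_sources) == 0) stop("candidate source list is empty")
  ladder <- list(); fits <- list()
  chosen <- NULL
  for (k in seq_len(min(max_sources, length(candidate_sources)))) {
    combos <- utils::combn(candidate_sources, k, simplify = FALSE)
    level_models <- list()
    for (srcs in combos) {
      m <- tryCatch(estimate_admixture(freqs, target, srcs, right, blocks, ...),
                    error = function(e) NULL)
      if (is.null(m)) next
      level_models[[length(level_models) + 1]] <- m
      ladder[[length(ladder) + 1]] <- data.frame(
        n_sources = k, sources = paste(srcs, collapse = "+"),
        weights = paste(sprintf("%.4f", m$weights), collapse = ","),
        p_value = m$p_value, feasible = m$feasible,
        stringsAsFactors = FALSE)
    }
    ok <- vapply(level_models, function(m)
      m$p_value > p_threshold && m$feasible, logical(1))
    if (any(ok) && is.null(chosen)) {
      cand <- level_models[ok]
      chosen <- cand[[which.max(vapply(cand, function(m) m$p_value, 0))]]
      break
    }
  }
  ladder <- if (length(ladder) > 0) do.call(rbind, ladder) else
    data.frame(n_sources = integer(), sources = character(),
               weights = character(), p_value = numeric(),
               feasible = logical())
  if (is.null(chosen))
    message("no fitting model at any complexity level (p <= ", p_threshold,
            " or infeasible weights throughout)")
  list(model = chosen, ladder = ladder)
}

#' Solve female/male source contributions from autosomal and X ancestry
#'
#' Under a single admixture pulse with female source-side contribution `sf`
#' and male contribution `sm`, the expected focal ancestry is
#' `pA = (sf + sm)/2` on the autosomes and `pX = (2 sf + sm)/3` on the X
#' chromosome. This inverts the system (`sf = 3 pX - 2 pA`,
#' `sm = 4 pA - 3 pX`) and computes the sex-bias Z statistic
#' `z = (pA - pX)/sqrt(sA^2 + sX^2)`; a negative z means more focal ancestry
#' on the X than the autosomes, i.e. female-biased admixture.
#'
#' @param pa,px Focal-ancestry proportions on autosomes and X.
#' @param sa,sx Their standard errors.
#' @return List with `z`, `sf`, `sm`, `sf_se`, `sm_se`, `ratio` (sf/sm),
#'   `ratio_se` (delta method) and `physical` (both contributions in [0,1]).
#' @export
solve_sex_contributions <- function(pa, px, sa = NA, sx = NA) {
  z <- (pa - px) / sqrt(sa^2 + sx^2)
  sf <- 3 * px - 2 * pa
  sm <- 4 * pa - 3 * px
  var_sf <- 9 * sx^2 + 4 * sa^2
  var_sm <- 16 * sa^2 + 9 * sx^2
  cov_fm <- -(9 * sx^2 + 8 * sa^2)
  ratio <- sf / sm
  ratio_se <- if (is.finite(var_sf) && sm != 0) {
    abs(ratio) * sqrt(var_sf / sf^2 + var_sm / sm^2 - 2 * cov_fm / (sf * sm))
  } else NA_real_
  list(z = z, sf = sf, sm = sm, sf_se = sqrt(var_sf), sm_se = sqrt(var_sm),
       ratio = ratio, ratio_se = ratio_se,
       physical = sf >= 0 && sf <= 1 && sm >= 0 && sm <= 1)
}

#' X-versus-autosome sex-biased admixture analysis
#'
#' Runs [estimate_admixture()] twice - on autosomal sites and on
#' X-chromosome sites, with jackknife blocks re-partitioned within each
#' subset - and compares the focal-source ancestry proportions: the Z
#' statistic for their difference, and the implied female (`sf`) and male
#' (`sm`) source-side contributions under a single-pulse model (see
#' [solve_sex_contributions()]). Non-physical solutions (sf or sm outside
#' [0, 1]) are flagged, never clamped.
#'
#' @param gm A [genotype_matrix()] whose site table contains X-chromosome
#'   sites (chromosome label `"X"` or `"23"`).
#' @param target Target group label.
#' @param sources Source labels; the first is the focal source whose
#'   proportion is compared between autosomes and X.
#' @param right Right-set labels.
#' @param width_cm Jackknife block width (cM).
#' @param min_x_sites Minimum number of X sites required (default 2000).
#' @param site_mode Passed to [estimate_admixture()].
#' @return An object of class `sex_bias_result`: list with `pa`, `pa_se`,
#'   `px`, `px_se`, `z`, `sf`, `sm`, `sf_se`, `sm_se`, `ratio`, `ratio_se`,
#'   `physical` and the two fitted models.
#' @export
sex_bias <- function(gm, target, sources, right, width_cm = 5,
                     min_x_sites = 2000,
                     site_mode = c("allsnps", "intersection")) {
  site_mode <- match.arg(site_mode)
  stopifnot(inherits(gm, "genotype_matrix"))
  on_x <- gm$sites$chrom %in% c("X", "23")
  n_x <- sum(on_x)
  if (n_x < min_x_sites)
    stop("only ", n_x, " X-chromosome sites; at least ", min_x_sites,
         " are required for the X-side fit")
  fit_subset <- function(mask) {
    sub <- subset_genotypes(gm, sites = which(mask))
    blocks <- partition_blocks(sub, width_cm)
    freqs <- group_frequencies(sub)
    estimate_admixture(freqs, target, sources, right, blocks, site_mode)
  }
  model_a <- fit_subset(!on_x)
  model_x <- fit_subset(on_x)
  focal <- sources[1]
  pa <- unname(model_a$weights[focal]); sa <- unname(model_a$weight_se[focal])
  px <- unname(model_x$weights[focal]); sx <- unname(model_x$weight_se[focal])
  sol <- solve_sex_contributions(pa, px, sa, sx)
  structure(c(list(pa = pa, pa_se = sa, px = px, px_se = sx,
                   focal_source = focal, model_autosomes = model_a,
                   model_x = model_x), sol),
            class = "sex_bias_result")
}

#' @export
print.sex_bias_result <- function(x, ...) {
  cat(sprintf("sex_bias (%s ancestry): autosomes %.3f (se %.3f), X %.3f (se %.3f)\n",
              x$focal_source, x$pa, x$pa_se, x$px, x$px_se))
  cat(sprintf("  z = %.2f (%s-biased), sf = %.3f, sm = %.3f, sf/sm = %.2f (se %.2f)%s\n",
              x$z, if (x$z < 0) "female" else "male", x$sf, x$sm, x$ratio,
              x$ratio_se, if (x$physical) "" else " [non-physical]"))
  invisible(x)
}
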