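#' Per-group allele frequencies
#'
#' Computes, per site and group, the alternate-allele count, the total number
#' of observed alleles and their ratio. Diploid individuals contribute two
#' alleles per non-missing site; pseudohaploid individuals contribute one
#' (their codes 0/2 represent a single sampled allele). Sites where a group
#' has zero observed alleles are `NA` (undefined) for that group.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Optional subset of group labels to tabulate (default: all).
#' @param assignments Optional character vector, one label per individual,
#'   overriding `gm$individuals$group` (e.g. an external group table).
#' @param site_mask Optional logical/integer index restricting the sites.
#' @return An object of class `group_freq`: list with matrices `freq`,
#'   `n_alt`, `n_tot`, `n_ind` (sites x groups) and the site table.
#' @export
group_frequencies <- function(gm, groups = NULL, assignments = NULL,
                              site_mask = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assign <- if (is.null(assignments)) gm$individuals$group else {
    if (length(assignments) != nrow(gm$individuals))
      stop("assignments must give one group label per individual")
    as.character(assignments)
  }
  wanted <- unique(assign)
  if (!is.null(groups)) {
    unknown <- setdiff(groups, assign)
    if (length(unknown) > 0)
      stop("unknown group label(s): ", paste(unknown, collapse = ", "))
    wanted <- groups
  }
  si <- if (is.null(site_mask)) seq_len(nrow(gm$sites)) else site_mask
  codes <- gm$codes[si, , drop = FALSE]
  sites <- gm$sites[si, , drop = FALSE]
  S <- nrow(sites)
  G <- length(wanted)
  n_alt <- n_tot <- n_ind <- matrix(0, S, G, dimnames = list(NULL, wanted))
  ph <- gm$individuals$ploidy == "pseudohaploid"
  for (g in seq_along(wanted)) {
    cols <- which(assign == wanted[g])
    if (length(cols) == 0) stop("group has no individuals: ", wanted[g])
    dip <- cols[!ph[cols]]
    hap <- cols[ph[cols]]
    if (length(dip) > 0) {
      m <- codes[, dip, drop = FALSE]
      obs <- !is.na(m)
      n_alt[, g] <- n_alt[, g] + rowSums(m, na.rm = TRUE)
      n_tot[, g] <- n_tot[, g] + 2 * rowSums(obs)
      n_ind[, g] <- n_ind[, g] + rowSums(obs)
    }
    if (length(hap) > 0) {
      m <- codes[, hap, drop = FALSE]
      obs <- !is.na(m)
      n_alt[, g] <- n_alt[, g] + rowSums(m, na.rm = TRUE) / 2
      n_tot[, g] <- n_tot[, g] + rowSums(obs)
      n_ind[, g] <- n_ind[, g] + rowSums(obs)
    }
  }
  freq <- n_alt / n_tot
  freq[n_tot == 0] <- NA_real_
  structure(list(freq = freq, n_alt = n_alt, n_tot = n_tot, n_ind = n_ind,
                 sites = sites, groups = wanted),
            class = "group_freq")
}

#' @export
print.group_freq <- function(x, ...) {
  cat("group_freq:", nrow(x$freq), "sites x", length(x$groups), "groups\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

# Logical mask of sites at which every population in `pops` has a defined
# frequency; with site_mode = "intersection" the mask additionally requires
# all groups in the table to be defined (so different statistics computed on
# the same table share one site set and algebraic identities hold exactly).
usable_sites <- function(freqs, pops, site_mode = c("allsnps", "intersection")) {
  site_mode <- match.arg(site_mode)
  cols <- if (site_mode == "intersection") freqs$groups else pops
  missing_pop <- setdiff(cols, colnames(freqs$freq))
  if (length(missing_pop) > 0)
    stop("group(s) not in frequency table: ", paste(missing_pop, collapse = ", "))
  rowSums(is.na(freqs$freq[, cols, drop = FALSE])) == 0
}
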