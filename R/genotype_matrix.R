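#' Construct a genotype matrix
#'
#' The central container of the package: a sites x individuals matrix of
#' alternate-allele dosage codes together with per-site map information and
#' per-individual metadata. Codes are 0, 1 or 2 copies of the alternate
#' allele; missing genotypes are `NA`. Individuals flagged as pseudohaploid
#' carry only codes 0 and 2 (a single sampled allele recorded as homozygous,
#' the EIGENSTRAT convention for low-coverage ancient samples) and contribute
#' one allele per non-missing site to group allele counts, while diploid
#' individuals contribute two.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `phys_pos`
#'   (1-based base pairs), `gen_pos` (centimorgans), `ref`, `alt`.
#' @param individuals data.frame with columns `individual_id`, `group`,
#'   `sex` (one of `"XX"`, `"XY"`, `"UNKNOWN"`), `ploidy` (one of
#'   `"diploid"`, `"pseudohaploid"`) and optionally `age_bp`.
#' @param codes integer matrix, `nrow(sites)` x `nrow(individuals)`, values
#'   in `c(0L, 1L, 2L, NA)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, codes, individuals) {
  sites <- as.data.frame(sites)
  individuals <- as.data.frame(individuals)
  required_site_cols <- c("site_id", "chrom", "phys_pos", "gen_pos", "ref", "alt")
  missing_cols <- setdiff(required_site_cols, names(sites))
  if (length(missing_cols) > 0)
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  required_ind_cols <- c("individual_id", "group", "sex", "ploidy")
  missing_cols <- setdiff(required_ind_cols, names(individuals))
  if (length(missing_cols) > 0)
    stop("individuals is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(individuals$age_bp)) individuals$age_bp <- NA_real_
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(sites) || ncol(codes) != nrow(individuals))
    stop("codes must be ", nrow(sites), " sites x ", nrow(individuals),
         " individuals, got ", nrow(codes), " x ", ncol(codes))
  if (any(!codes %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(individuals$group == "" | is.na(individuals$group)))
    stop("every individual needs a non-empty group label")
  if (any(sites$ref == sites$alt))
    stop("ref and alt alleles must differ at every site")
  if (any(sites$gen_pos < 0, na.rm = TRUE))
    stop("genetic positions must be non-negative")
  bad_ploidy <- !individuals$ploidy %in% c("diploid", "pseudohaploid")
  if (any(bad_ploidy))
    stop("ploidy must be 'diploid' or 'pseudohaploid'")
  ph <- individuals$ploidy == "pseudohaploid"
  if (any(ph) && any(codes[, ph, drop = FALSE] == 1L, na.rm = TRUE))
    stop("pseudohaploid individuals may only carry codes 0, 2 or NA")
  # positions must be non-decreasing within each chromosome
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (is.unsorted(sites$gen_pos[idx]) || is.unsorted(sites$phys_pos[idx]))
      stop("sites on chromosome ", ch,
           " are not sorted by position (non-decreasing required)")
  }
  rownames(codes) <- sites$site_id
  colnames(codes) <- individuals$individual_id
  structure(list(sites = sites, individuals = individuals, codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x",
      nrow(x$individuals), "individuals\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$individuals$group), collapse = ", "), "\n")
  n_ph <- sum(x$individuals$ploidy == "pseudohaploid")
  cat("  pseudohaploid individuals:", n_ph, "/", nrow(x$individuals), "\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param sites integer or logical index into the site table.
#' @param individuals integer or logical index into the individual table.
#' @return A `genotype_matrix` restricted to the requested sites/individuals.
#' @export
subset_genotypes <- function(gm, sites = NULL, individuals = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(gm$sites)) else sites
  ii <- if (is.null(individuals)) seq_len(nrow(gm$individuals)) else individuals
  genotype_matrix(gm$sites[si, , drop = FALSE],
                  gm$codes[si, ii, drop = FALSE],
                  gm$individuals[ii, , drop = FALSE])
}

#' Read an EIGENSTRAT genotype trio
#'
#' Reads the plain-text EIGENSTRAT format: a `.geno` file with one row per
#' site consisting of the characters 0/1/2/9 (9 = missing), a six-column
#' `.snp` file (site id, chromosome, genetic position in Morgans, physical
#' position, ref allele, alt allele) and a three-column `.ind` file
#' (individual id, sex coded M/F/U, group label). Genetic positions are
#' converted from Morgans to centimorgans on input; packed binary EIGENSTRAT
#' is not supported.
#'
#' @param geno_path,snp_path,ind_path Paths to the three files.
#' @param group_table Optional path to a two-column whitespace-separated file
#'   (individual_id, group_label) overriding the `.ind` group column.
#' @param ploidy Either a single value recycled to all individuals or a
#'   character vector (`"diploid"`/`"pseudohaploid"`) per individual.
#'   Defaults to `"diploid"`; individuals whose `.geno` column never shows a
#'   heterozygous code are left as declared, the flag is metadata.
#' @return A [genotype_matrix()].
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path,
                            group_table = NULL, ploidy = "diploid") {
  for (p in c(geno_path, snp_path, ind_path))
    if (!file.exists(p)) stop("file not found: ", p)
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("site_id", "chrom", "gen_m",
                                         "phys_pos", "ref", "alt"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("individual_id", "sex_code", "group"),
                           colClasses = "character")
  geno_lines <- readLines(geno_path)
  if (length(geno_lines) != nrow(snp))
    stop("format error in ", geno_path, ": ", length(geno_lines),
         " genotype rows but ", nrow(snp), " sites in ", snp_path)
  n_ind <- nrow(ind)
  widths <- nchar(geno_lines)
  bad <- which(widths != n_ind)
  if (length(bad) > 0)
    stop("format error in ", geno_path, " line ", bad[1], ": row width ",
         widths[bad[1]], " but ", n_ind, " individuals declared in ", ind_path)
  mat <- matrix(NA_integer_, nrow(snp), n_ind)
  chars <- strsplit(geno_lines, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    v <- chars[[i]]
    bad_char <- !v %in% c("0", "1", "2", "9")
    if (any(bad_char))
      stop("format error in ", geno_path, " line ", i,
           ": unexpected character '", v[which(bad_char)[1]], "'")
    row <- match(v, c("0", "1", "2")) - 1L
    mat[i, ] <- row  # '9' maps to NA via match miss
  }
  sites <- data.frame(site_id = snp$site_id, chrom = snp$chrom,
                      phys_pos = snp$phys_pos, gen_pos = snp$gen_m * 100,
                      ref = snp$ref, alt = snp$alt,
                      stringsAsFactors = FALSE)
  sex <- c(M = "XY", F = "XX", U = "UNKNOWN")[ind$sex_code]
  sex[is.na(sex)] <- "UNKNOWN"
  individuals <- data.frame(individual_id = ind$individual_id,
                            group = ind$group, sex = unname(sex),
                            ploidy = rep_len(ploidy, n_ind),
                            stringsAsFactors = FALSE)
  if (!is.null(group_table)) {
    gt <- utils::read.table(group_table, header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("individual_id", "group"),
                            colClasses = "character")
    m <- match(individuals$individual_id, gt$individual_id)
    hit <- !is.na(m)
    individuals$group[hit] <- gt$group[m[hit]]
  }
  genotype_matrix(sites, mat, individuals)
}

#' Write a genotype matrix as an EIGENSTRAT trio
#'
#' Inverse of [read_eigenstrat()]: genetic positions are written in Morgans,
#' missing codes as 9. Round-tripping reproduces codes, positions and alleles
#' exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; files `<prefix>.geno`, `<prefix>.snp`
#'   and `<prefix>.ind` are written.
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  codes <- gm$codes
  chr <- matrix("9", nrow(codes), ncol(codes))
  chr[!is.na(codes)] <- as.character(codes[!is.na(codes)])
  geno_path <- paste0(prefix, ".geno")
  snp_path <- paste0(prefix, ".snp")
  ind_path <- paste0(prefix, ".ind")
  writeLines(apply(chr, 1, paste0, collapse = ""), geno_path)
  snp <- gm$sites
  write(sprintf("%s\t%s\t%.10g\t%d\t%s\t%s", snp$site_id, snp$chrom,
                snp$gen_pos / 100, as.integer(snp$phys_pos), snp$ref, snp$alt),
        snp_path)
  sex_code <- c(XY = "M", XX = "F", UNKNOWN = "U")[gm$individuals$sex]
  sex_code[is.na(sex_code)] <- "U"
  write(sprintf("%s\t%s\t%s", gm$individuals$individual_id, unname(sex_code),
                gm$individuals$group),
        ind_path)
  invisible(c(geno = geno_path, snp = snp_path, ind = ind_path))
}
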