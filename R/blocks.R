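#' Partition sites into jackknife blocks
#'
#' Splits the genome into contiguous blocks of genetic length `width_cm`
#' (default 5 cM, the conventional width for block-jackknife standard errors
#' of f-statistics). Blocks never span chromosome boundaries. Within each
#' chromosome blocks are formed greedily left to right: a new block starts
#' when the next site lies more than `width_cm` beyond the current block's
#' first site, so the last block of a chromosome may be narrower.
#'
#' When the genetic map is absent (all genetic positions zero or `NA`) the
#' partition falls back to fixed 5 Mb windows on physical positions, with a
#' warning.
#'
#' @param gm A [genotype_matrix()] with sites sorted within chromosomes.
#' @param width_cm Target block width in centimorgans (> 0).
#' @return An object of class `block_partition`: a data.frame of blocks
#'   (`block`, `chrom`, `start_cm`, `end_cm`, `n_sites`) with an attribute
#'   `site_block` giving each site's block index.
#' @export
partition_blocks <- function(gm, width_cm = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (width_cm <= 0) stop("width_cm must be positive")
  sites <- gm$sites
  gp <- sites$gen_pos
  use_phys <- FALSE
  if (all(is.na(gp)) || all(gp == 0, na.rm = TRUE)) {
    warning("no genetic map available; falling back to fixed 5 Mb physical windows")
    gp <- sites$phys_pos / 1e6  # Mb treated as pseudo-cM units
    width_cm <- 5
    use_phys <- TRUE
  }
  site_block <- integer(nrow(sites))
  blocks <- list()
  b <- 0L
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- gp[idx]
    if (is.unsorted(pos))
      stop("sites on chromosome ", ch, " are not sorted by genetic position")
    start <- pos[1]
    b <- b + 1L
    cur_first <- 1L
    for (k in seq_along(idx)) {
      if (pos[k] > start + width_cm) {
        blocks[[b]] <- data.frame(block = b, chrom = ch,
                                  start_cm = start, end_cm = pos[k - 1],
                                  n_sites = k - cur_first,
                                  stringsAsFactors = FALSE)
        b <- b + 1L
        start <- pos[k]
        cur_first <- k
      }
      site_block[idx[k]] <- b
    }
    blocks[[b]] <- data.frame(block = b, chrom = ch, start_cm = start,
                              end_cm = pos[length(pos)],
                              n_sites = length(idx) - cur_first + 1L,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, site_block = site_block, width_cm = width_cm,
            physical_fallback = use_phys,
            class = c("block_partition", "data.frame"))
}

#' Number of blocks in a partition
#' @param blocks A [partition_blocks()] result.
#' @return Integer block count.
#' @export
n_blocks <- function(blocks) nrow(blocks)

site_block_index <- function(blocks) attr(blocks, "site_block")
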