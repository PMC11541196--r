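#' IBD segment tables
#'
#' Constructs/validates a table of identity-by-descent segments. Pairs are
#' canonicalized (id1 < id2 lexicographically) and `length_cm` recomputed as
#' `end_cm - start_cm`, which must be positive.
#'
#' @param df data.frame with columns `id1`, `id2`, `chrom`, `start_cm`,
#'   `end_cm`.
#' @return data.frame of class `ibd_segments`, sorted by pair, chromosome and
#'   start position.
#' @export
ibd_segments <- function(df) {
  df <- as.data.frame(df)
  req <- c("id1", "id2", "chrom", "start_cm", "end_cm")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("segment table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(df$end_cm <= df$start_cm))
      stop("every segment needs end_cm > start_cm")
    swap <- df$id1 > df$id2
    tmp <- df$id1[swap]; df$id1[swap] <- df$id2[swap]; df$id2[swap] <- tmp
    df <- df[order(df$id1, df$id2, df$chrom, df$start_cm), , drop = FALSE]
  }
  df$length_cm <- df$end_cm - df$start_cm
  rownames(df) <- NULL
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Read a RefinedIBD-style segment table
#'
#' Expects the tab-separated columns (id1, hap1, id2, hap2, chrom, start_bp,
#' end_bp, LOD, length_cM); haplotype and LOD columns are dropped after pair
#' canonicalization. Physical coordinates are converted to genetic positions
#' by linear interpolation on the map in `map` (a [genotype_matrix()] or a
#' data.frame with `chrom`, `phys_pos`, `gen_pos`); with `map = NULL` a
#' uniform 1 cM/Mb is assumed, with a message.
#'
#' @param path Path to the segment file.
#' @param map Optional genetic map for bp-to-cM conversion.
#' @return An [ibd_segments()] table.
#' @export
read_ibd_segments <- function(path, map = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id1", "hap1", "id2", "hap2",
                                         "chrom", "start_bp", "end_bp",
                                         "lod", "length_cm"))
  raw$chrom <- as.character(raw$chrom)
  if (is.null(map)) {
    message("no genetic map supplied; assuming 1 cM/Mb")
    raw$start_cm <- raw$start_bp / 1e6
    raw$end_cm <- raw$end_bp / 1e6
  } else {
    map_df <- if (inherits(map, "genotype_matrix")) map$sites else map
    raw$start_cm <- NA_real_; raw$end_cm <- NA_real_
    for (ch in unique(raw$chrom)) {
      m <- map_df[map_df$chrom == ch, ]
      if (nrow(m) < 2) stop("genetic map has fewer than 2 sites on chromosome ", ch)
      sel <- raw$chrom == ch
      raw$start_cm[sel] <- stats::approx(m$phys_pos, m$gen_pos,
                                         raw$start_bp[sel], rule = 2)$y
      raw$end_cm[sel] <- stats::approx(m$phys_pos, m$gen_pos,
                                       raw$end_bp[sel], rule = 2)$y
    }
  }
  ibd_segments(raw[, c("id1", "id2", "chrom", "start_cm", "end_cm")])
}

#' Minimum-length filter for IBD segments
#'
#' Removes segments shorter than `min_cm` (default 1 cM, the conventional
#' minimum for a segment to count as shared IBD). The threshold is closed:
#' a segment of exactly `min_cm` is kept.
#'
#' @param segments An [ibd_segments()] table.
#' @param min_cm Minimum genetic length in cM.
#' @return The filtered table, order preserved.
#' @export
filter_min_length <- function(segments, min_cm = 1.0) {
  stopifnot(inherits(segments, "ibd_segments"))
  out <- segments[segments$length_cm >= min_cm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count opposite-homozygote sites strictly inside (start, end) on `chrom`
# for the pair (id1, id2); heterozygous and missing sites never count.
count_discordant_homozygotes <- function(gm, id1, id2, chrom, start_cm, end_cm) {
  j1 <- match(id1, gm$individuals$individual_id)
  j2 <- match(id2, gm$individuals$individual_id)
  if (is.na(j1) || is.na(j2)) return(0L)
  sel <- gm$sites$chrom == chrom & gm$sites$gen_pos > start_cm &
    gm$sites$gen_pos < end_cm
  g1 <- gm$codes[sel, j1]; g2 <- gm$codes[sel, j2]
  sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L), na.rm = TRUE)
}

#' Merge IBD segments across short, concordant gaps
#'
#' Adjacent segments of the same pair on the same chromosome are merged when
#' the gap between them is strictly shorter than `max_gap_cm` AND the number
#' of discordant homozygote sites (the two individuals opposite homozygous)
#' strictly inside the gap is at most `max_discordant_hom`. Merging is
#' iterated left to right until stable, so chains of short gaps collapse; the
#' merged segment spans from the first start to the last end. The operation
#' is idempotent.
#'
#' @param segments An [ibd_segments()] table, sorted within pair/chromosome
#'   (as [ibd_segments()] guarantees); unsorted input is an error.
#' @param genotypes A [genotype_matrix()] used to count discordant
#'   homozygotes in gaps; with `NULL` gaps are treated as concordant (only
#'   the width rule applies), with a message.
#' @param max_gap_cm Strict upper bound on the gap width.
#' @param max_discordant_hom Maximum tolerated discordant homozygotes.
#' @return The merged [ibd_segments()] table.
#' @export
merge_gaps <- function(segments, genotypes = NULL, max_gap_cm = 0.6,
                       max_discordant_hom = 1) {
  stopifnot(inherits(segments, "ibd_segments"))
  if (nrow(segments) < 2) return(segments)
  if (is.null(genotypes))
    message("no genotypes supplied; gap discordance assumed 0")
  key <- paste(segments$id1, segments$id2, segments$chrom, sep = "\r")
  pieces <- split(seq_len(nrow(segments)), key)
  out <- list()
  for (idx in pieces) {
    s <- segments[idx, , drop = FALSE]
    if (is.unsorted(s$start_cm))
      stop("segments for pair ", s$id1[1], "/", s$id2[1], " chromosome ",
           s$chrom[1], " are not sorted by start position")
    repeat {
      merged_any <- FALSE
      k <- 1
      res <- s[1, , drop = FALSE]
      for (r in seq(2, length.out = nrow(s) - 1)) {
        gap <- s$start_cm[r] - res$end_cm[k]
        n_disc <- if (gap <= 0 || is.null(genotypes)) 0L else
          count_discordant_homozygotes(genotypes, s$id1[r], s$id2[r],
                                       s$chrom[r], res$end_cm[k],
                                       s$start_cm[r])
        # strict width rule, guarded against floating-point representation of
        # boundary gaps (a gap of exactly max_gap_cm must not merge)
        if (gap < max_gap_cm - 1e-9 && n_disc <= max_discordant_hom) {
          res$end_cm[k] <- max(res$end_cm[k], s$end_cm[r])
          merged_any <- TRUE
        } else {
          res <- rbind(res, s[r, , drop = FALSE])
          k <- k + 1
        }
      }
      s <- res
      if (!merged_any) break
    }
    out[[length(out) + 1]] <- s
  }
  ibd_segments(do.call(rbind, out))
}

#' Per-pair IBD summaries
#'
#' Aggregates a post-processed segment table into one row per individual
#' pair: the number of segments and their summed genetic length.
#'
#' @param segments An [ibd_segments()] table.
#' @return data.frame with columns `id1`, `id2`, `n_segments`, `total_cm`,
#'   one row per pair appearing in the input.
#' @export
aggregate_pairs <- function(segments) {
  stopifnot(inherits(segments, "ibd_segments"))
  if (nrow(segments) == 0)
    return(data.frame(id1 = character(), id2 = character(),
                      n_segments = integer(), total_cm = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(segments$id1, segments$id2, sep = "\r")
  agg <- lapply(split(segments, key), function(s)
    data.frame(id1 = s$id1[1], id2 = s$id2[1], n_segments = nrow(s),
               total_cm = sum(s$length_cm), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full IBD post-processing pipeline
#'
#' Applies the length filter then gap merging (in that order) and aggregates
#' per-pair summaries.
#'
#' @inheritParams merge_gaps
#' @inheritParams filter_min_length
#' @return List with `segments` (post-processed) and `pairs` (summaries).
#' @export
postprocess_ibd <- function(segments, genotypes = NULL, min_cm = 1.0,
                            max_gap_cm = 0.6, max_discordant_hom = 1) {
  kept <- filter_min_length(segments, min_cm)
  merged <- merge_gaps(kept, genotypes, max_gap_cm, max_discordant_hom)
  list(segments = merged, pairs = aggregate_pairs(merged))
}
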