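# Post-alignment cleanup: MAPQ filtering, PCR-duplicate removal with
# ENCODE-style library-complexity metrics, and organelle-contamination
# accounting.  This is pipeline step "generation of unique mapped reads".

#' Filtering configuration
#'
#' @param mapq_min minimum mapping quality kept; tags with mapq strictly
#'   below are dropped (default 5, i.e. "MAPQ < 5" removed).
#' @param drop_organelle also drop tags on organelle chromosomes
#'   (default FALSE: they are counted by [organelle_fraction] and dropped
#'   later by the caller's nuclear-only accounting).
#' @return a `filter_config` list.
#' @export
filter_config <- function(mapq_min = 5, drop_organelle = FALSE) {
  stopifnot(mapq_min >= 0)
  structure(list(mapq_min = mapq_min, drop_organelle = drop_organelle),
            class = "filter_config")
}

#' Filter tags on mapping quality and chromosome membership
#'
#' Keeps tags with `mapq >= mapq_min` on chromosomes present in
#' `chrom_sizes` (when provided).  Nothing errors: every dropped tag is
#' accounted for in the returned stats.
#'
#' @param tags tag data.frame.
#' @param config a [filter_config].
#' @param chrom_sizes optional [chrom_sizes]; tags on unknown chromosomes
#'   are dropped (counted, not an error, since scaffolds absent from the
#'   size table are routinely discarded).
#' @return list with `tags` (kept) and `stats` (named counts: input, kept,
#'   dropped_mapq, dropped_unknown_chrom, dropped_organelle).
#' @export
filter_tags <- function(tags, config = filter_config(), chrom_sizes = NULL) {
  n <- nrow(tags)
  keep <- tags$mapq >= config$mapq_min
  dropped_mapq <- sum(!keep)
  dropped_unknown <- 0L
  dropped_org <- 0L
  if (!is.null(chrom_sizes)) {
    known <- tags$chrom %in% chrom_sizes$chrom
    dropped_unknown <- sum(keep & !known)
    keep <- keep & known
    if (isTRUE(config$drop_organelle)) {
      org <- tags$chrom %in% chrom_sizes$chrom[chrom_sizes$organelle]
      dropped_org <- sum(keep & org)
      keep <- keep & !org
    }
  }
  list(tags = tags[keep, , drop = FALSE],
       stats = c(input = n, kept = sum(keep), dropped_mapq = dropped_mapq,
                 dropped_unknown_chrom = dropped_unknown,
                 dropped_organelle = dropped_org))
}

# strand-specific 5' cut coordinate of each tag: the Tn5 insertion point
cut_site <- function(tags) {
  ifelse(tags$strand == "+", tags$start, tags$end - 1)
}

#' Remove PCR duplicates and compute library complexity
#'
#' Duplicates are tags sharing the same (chromosome, strand, 5' cut
#' coordinate) — the Tn5 cut-site key that position-and-strand duplicate
#' markers use.  With `key = "interval"` the full (chrom, start, end,
#' strand) interval is the key instead (appropriate for fragment-derived
#' tags).  One representative per key is kept: the first in
#' (chrom, start, end, strand) sorted order.
#'
#' Library-complexity metrics are computed on the pre-deduplication
#' multiset, following the ENCODE definitions:
#' NRF = distinct/total, PBC1 = single-occurrence/distinct,
#' PBC2 = single-occurrence/double-occurrence (Inf when no position is
#' seen exactly twice).
#'
#' @param tags tag data.frame (already filtered).
#' @param key "cut" (default) or "interval".
#' @return list with `tags` (deduplicated, sorted) and `complexity`
#'   (named numeric: total_tags, distinct_positions, one_read_positions,
#'   two_read_positions, NRF, PBC1, PBC2).
#' @export
deduplicate <- function(tags, key = c("cut", "interval")) {
  key <- match.arg(key)
  ord <- order(tags$chrom, tags$start, tags$end, tags$strand)
  tags <- tags[ord, , drop = FALSE]
  k <- if (key == "cut") {
    paste(tags$chrom, tags$strand, cut_site(tags))
  } else {
    paste(tags$chrom, tags$start, tags$end, tags$strand)
  }
  total <- length(k)
  cnt <- tabulate(match(k, unique(k)))
  distinct <- length(cnt)
  one <- sum(cnt == 1)
  two <- sum(cnt == 2)
  complexity <- c(total_tags = total, distinct_positions = distinct,
                  one_read_positions = one, two_read_positions = two,
                  NRF = if (total) distinct / total else NA_real_,
                  PBC1 = if (distinct) one / distinct else NA_real_,
                  PBC2 = if (two) one / two else if (distinct) Inf
                         else NA_real_)
  out <- tags[!duplicated(k), , drop = FALSE]
  rownames(out) <- NULL
  list(tags = out, complexity = complexity)
}

#' Fraction of tags on organelle chromosomes
#'
#' Organelle DNA is nucleosome-free and cut indiscriminately by Tn5, so the
#' organelle tag fraction measures contamination (a well-prepared wheat
#' library shows about 5%).
#'
#' @param tags tag data.frame.
#' @param chrom_sizes [chrom_sizes] with organelle flags.
#' @return fraction in \[0, 1\]; 0 (with a warning) for an empty library.
#' @export
organelle_fraction <- function(tags, chrom_sizes) {
  if (!nrow(tags)) {
    warning("no tags; organelle fraction reported as 0")
    return(0)
  }
  org <- chrom_sizes$chrom[chrom_sizes$organelle]
  if (!length(org)) return(0)
  mean(tags$chrom %in% org)
}
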