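# Readers/writers for the on-disk formats the toolkit touches.  Internal
# coordinates are uniformly 0-based half-open; GFF3 (1-based inclusive) is
# converted at this boundary.  All text formats may be gzip-compressed
# (handled transparently by R's connection layer on read; ".gz" suffix
# triggers gzip on write).

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Construct a tag table
#'
#' Tags are single sequenced Tn5 insertion events: the unit of all counting
#' in the package.  One row per tag with 0-based half-open coordinates.
#'
#' @param chrom,start,end,strand,mapq per-tag fields; `strand` is "+" or
#'   "-", `mapq` a non-negative mapping quality.
#' @param validate check invariants (default TRUE).
#' @return data.frame with columns chrom, start, end, strand, mapq.
#' @export
tag_table <- function(chrom, start, end, strand, mapq = 255L,
                      validate = TRUE) {
  n <- max(length(chrom), length(start), length(end))
  if (!length(start)) n <- 0L
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   mapq = rep_len(as.numeric(mapq), n),
                   stringsAsFactors = FALSE)
  if (validate) validate_tags(df)
  df
}

validate_tags <- function(tags, cs = NULL) {
  bad <- which(!(tags$start >= 0 & tags$start < tags$end))
  if (length(bad))
    stop("invalid tag interval (need 0 <= start < end) at record ", bad[1])
  bad <- which(!tags$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand at record ", bad[1], " (must be + or -)")
  if (any(tags$mapq < 0)) stop("mapq must be >= 0")
  if (!is.null(cs)) {
    len <- chrom_length(cs, tags$chrom)
    bad <- which(tags$end > len)
    if (length(bad))
      stop("tag extends beyond chromosome end at record ", bad[1])
  }
  invisible(tags)
}

#' Read a tagAlign (BED6) file
#'
#' tagAlign carries one aligned read per line in BED6.  The format has no
#' dedicated MAPQ field; by convention the score column (5) holds the
#' mapping quality, controlled by `mapq_in_score`.
#'
#' @param path tagAlign path, optionally gzipped.
#' @param chrom_sizes optional [chrom_sizes]; when given, coordinates are
#'   validated against chromosome bounds and unknown chromosomes are an
#'   error.
#' @param mapq_in_score treat BED column 5 as MAPQ (default TRUE).  When
#'   FALSE, all tags get mapq = 255 (unknown).
#' @return tag data.frame (see [tag_table]) in file order.
#' @export
read_tagalign <- function(path, chrom_sizes = NULL, mapq_in_score = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(tag_table(character(), numeric(), numeric(), character(),
                     numeric()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(f)
  if (any(ncols < 6))
    stop("malformed tagAlign line ", which(ncols < 6)[1],
         ": expected >= 6 tab-separated columns")
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop("malformed tagAlign line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  mq <- if (mapq_in_score) suppressWarnings(as.numeric(m[, 5])) else 255
  if (anyNA(mq))
    stop("malformed tagAlign line ", which(is.na(mq))[1],
         ": non-numeric score/MAPQ column")
  tags <- tag_table(m[, 1], start, end, m[, 6], mq)
  if (!is.null(chrom_sizes)) validate_tags(tags, chrom_sizes)
  tags
}

#' Write a tagAlign (BED6) file
#' @param tags tag data.frame.
#' @param path output path; ".gz" gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_tagalign <- function(tags, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(tags$chrom, format_int(tags$start), format_int(tags$end),
                   "N", format_int(tags$mapq), tags$strand, sep = "\t"), con)
  invisible(path)
}

#' Read fragments from a BEDPE file
#'
#' Each line holds a properly paired read pair; the fragment spans
#' min(start1, start2) to max(end1, end2).  Pairs whose mates map to
#' different chromosomes cannot define a fragment and are skipped; the count
#' of skipped pairs is attached as attribute `n_skipped` (with a warning
#' when non-zero).
#'
#' @param path BEDPE path, optionally gzipped.
#' @param chrom_sizes optional [chrom_sizes] for bounds validation.
#' @return data.frame with columns chrom, start, end and attribute
#'   `n_skipped`.
#' @export
read_bedpe_fragments <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6))
    stop("malformed BEDPE line ", which(lengths(f) < 6)[1],
         ": expected >= 6 columns")
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6, byrow = TRUE)
  same <- m[, 1] == m[, 4]
  n_skipped <- sum(!same)
  if (n_skipped > 0)
    warning(n_skipped, " cross-chromosome pair(s) skipped")
  m <- m[same, , drop = FALSE]
  s1 <- as.numeric(m[, 2]); e1 <- as.numeric(m[, 3])
  s2 <- as.numeric(m[, 5]); e2 <- as.numeric(m[, 6])
  out <- data.frame(chrom = m[, 1], start = pmin(s1, s2),
                    end = pmax(e1, e2), stringsAsFactors = FALSE)
  if (any(out$end <= out$start))
    stop("non-positive fragment length at BEDPE record ",
         which(out$end <= out$start)[1])
  if (!is.null(chrom_sizes)) {
    len <- chrom_length(chrom_sizes, out$chrom)
    if (any(out$end > len))
      stop("fragment beyond chromosome end at record ",
           which(out$end > len)[1])
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write fragments as BEDPE
#' @param fragments fragment data.frame (chrom, start, end).
#' @param path output path; ".gz" gzip-compresses.
#' @param read_length mate length used to reconstruct the two BEDPE mate
#'   intervals (clipped to the fragment).
#' @return `path`, invisibly.
#' @export
write_bedpe_fragments <- function(fragments, path, read_length = 50) {
  con <- open_out(path)
  on.exit(close(con))
  len <- fragments$end - fragments$start
  rl <- pmin(read_length, len)
  writeLines(paste(fragments$chrom, format_int(fragments$start),
                   format_int(fragments$start + rl),
                   fragments$chrom, format_int(fragments$end - rl),
                   format_int(fragments$end),
                   "F", "0", "+", "-", sep = "\t"), con)
  invisible(path)
}

#' Construct a peak table
#'
#' Peaks use ENCODE narrowPeak semantics: 0-based half-open interval,
#' `signal` the pileup (or fold enrichment) at the summit, `pvalue` and
#' `qvalue` on the -log10 scale, `summit` the 0-based offset of the summit
#' from `start`.
#'
#' @param chrom,start,end,name,score,strand,signal,pvalue,qvalue,summit
#'   narrowPeak columns; `score` is the integer display score (0-1000).
#' @param idr optional per-peak global IDR values.
#' @return data.frame with the ten narrowPeak columns (+ optional `idr`).
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = 0L,
                       strand = ".", signal = 0, pvalue = 0, qvalue = 0,
                       summit = 0L, idr = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (!length(start)) n <- 0L
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character()
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   signal = rep_len(as.numeric(signal), n),
                   pvalue = rep_len(as.numeric(pvalue), n),
                   qvalue = rep_len(as.numeric(qvalue), n),
                   summit = rep_len(as.numeric(summit), n),
                   stringsAsFactors = FALSE)
  if (!is.null(idr)) df$idr <- as.numeric(idr)
  if (n) {
    stopifnot(all(df$start >= 0), all(df$end > df$start),
              all(df$summit >= 0), all(df$summit < df$end - df$start),
              all(df$pvalue >= 0), all(df$qvalue >= 0 | df$qvalue == -1))
  }
  df
}

#' Write peaks in ENCODE narrowPeak format
#'
#' Ten tab-separated columns: chrom, start, end, name, score, strand,
#' signalValue, -log10 p, -log10 q, summit offset.
#'
#' @param peaks peak data.frame (see [peak_table]).
#' @param path output path; ".gz" gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(peaks$chrom, format_int(peaks$start),
                   format_int(peaks$end), peaks$name,
                   format_int(round(peaks$score)), peaks$strand,
                   format_num(peaks$signal), format_num(peaks$pvalue),
                   format_num(peaks$qvalue),
                   format_int(peaks$summit), sep = "\t"), con)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#' @param path narrowPeak path, optionally gzipped.
#' @return peak data.frame (see [peak_table]).
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_table(character(), numeric(), numeric()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 10))
    stop("narrowPeak requires exactly 10 columns; line ",
         which(lengths(f) != 10)[1], " has ", lengths(f)[lengths(f) != 10][1])
  m <- matrix(unlist(f), ncol = 10, byrow = TRUE)
  peak_table(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), m[, 4],
             as.numeric(m[, 5]), m[, 6], as.numeric(m[, 7]),
             as.numeric(m[, 8]), as.numeric(m[, 9]), as.numeric(m[, 10]))
}

#' Read gene models from GFF3
#'
#' Keeps features of type "gene" only.  GFF3 1-based inclusive coordinates
#' are converted to the package's 0-based half-open convention, and
#' strand-aware TSS/TES single coordinates are derived: for a `+` gene
#' TSS = start and TES = end - 1; for a `-` gene TSS = end - 1 and
#' TES = start.
#'
#' @param path GFF3 path, optionally gzipped.
#' @param chrom_sizes optional [chrom_sizes] for bounds validation.
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   tss, tes.
#' @export
read_gff3_genes <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), tss = numeric(), tes = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9))
    stop("malformed GFF3 line ", lineno[which(lengths(f) != 9)[1]],
         ": expected 9 columns")
  m <- matrix(unlist(f), ncol = 9, byrow = TRUE)
  is_gene <- m[, 3] == "gene"
  if (!any(is_gene)) return(empty)
  m <- m[is_gene, , drop = FALSE]
  lineno <- lineno[is_gene]
  attrs <- paste0(";", gsub("; *", ";", m[, 9]))
  no_id <- !grepl(";ID=", attrs, fixed = TRUE)
  id <- sub(".*;ID=([^;]+).*", "\\1", attrs)
  if (any(no_id))
    stop("gene without ID attribute at GFF3 line ", lineno[no_id][1])
  start1 <- as.numeric(m[, 4]); end1 <- as.numeric(m[, 5])
  if (any(start1 < 1 | end1 < start1))
    stop("invalid GFF3 coordinates at line ",
         lineno[which(start1 < 1 | end1 < start1)[1]])
  strand <- m[, 7]
  if (any(!strand %in% c("+", "-")))
    stop("gene without +/- strand at GFF3 line ",
         lineno[which(!strand %in% c("+", "-"))[1]])
  start <- start1 - 1           # 0-based half-open
  end <- end1
  genes <- data.frame(gene_id = id, chrom = m[, 1], start = start, end = end,
                      strand = strand,
                      tss = ifelse(strand == "+", start, end - 1),
                      tes = ifelse(strand == "+", end - 1, start),
                      stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) {
    len <- chrom_length(chrom_sizes, genes$chrom)
    if (any(genes$end > len))
      stop("gene beyond chromosome end at GFF3 line ",
           lineno[which(genes$end > len)[1]])
  }
  genes
}

#' Write gene models as GFF3
#' @param genes gene data.frame (see [read_gff3_genes]).
#' @param path output path; ".gz" gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(genes$chrom, "polyatac", "gene",
                   format_int(genes$start + 1), format_int(genes$end),
                   ".", genes$strand, ".",
                   paste0("ID=", genes$gene_id), sep = "\t"), con)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal signal are collapsed to single bedGraph intervals;
#' zero-signal runs are omitted.
#'
#' @param track a `coverage_track` (see [pileup]).
#' @param path output path; ".gz" gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- open_out(path)
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(chrom, format_int(starts[keep]), format_int(ends[keep]),
                     format_num(r$values[keep], 10), sep = "\t"), con)
  }
  invisible(path)
}
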