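#' Chromosome-size table
#'
#' Builds the genome description used throughout the package: an ordered set
#' of chromosome names with lengths and a per-chromosome organelle flag.
#' Organelle chromosomes (mitochondrion, chloroplast) carry accessible-looking
#' Tn5 signal that is pure contamination in an ATAC-seq library, so they are
#' tracked explicitly and excluded from background-rate estimation.
#'
#' @param lengths named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (name, length).
#' @param organelle_regex case-insensitive regular expression identifying
#'   organelle chromosomes by name.  Default matches names containing "Mt"
#'   or "Pt", the common plant mitochondrion/plastid labels.
#' @param organelle optional logical vector overriding the regex.
#' @return A `chrom_sizes` data.frame with columns `chrom`, `length`,
#'   `organelle`.
#' @examples
#' cs <- chrom_sizes(c(chr1A = 2e6, chr2A = 2e6, chrMt = 1e5))
#' cs$organelle
#' @export
chrom_sizes <- function(lengths, organelle_regex = "Mt|Pt", organelle = NULL) {
  if (is.data.frame(lengths)) {
    stopifnot(ncol(lengths) >= 2)
    nm <- as.character(lengths[[1]])
    len <- as.numeric(lengths[[2]])
  } else {
    nm <- names(lengths)
    len <- as.numeric(lengths)
  }
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(organelle)) {
    organelle <- grepl(organelle_regex, nm, ignore.case = TRUE)
  } else {
    stopifnot(length(organelle) == length(nm), is.logical(organelle))
  }
  out <- data.frame(chrom = nm, length = len, organelle = organelle,
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_sizes", "data.frame")
  out
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a (possibly gzipped) whitespace-delimited file with
#'   columns chromosome name and length.
#' @inheritParams chrom_sizes
#' @return A [chrom_sizes] object.
#' @export
read_chrom_sizes <- function(path, organelle_regex = "Mt|Pt") {
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric"))
  chrom_sizes(setNames(df[[2]], df[[1]]), organelle_regex = organelle_regex)
}

#' Write a chrom.sizes file
#' @param cs a [chrom_sizes] object.
#' @param path output path (".gz" suffix triggers gzip).
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(cs, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(cs$chrom, format_int(cs$length), sep = "\t"), con)
  invisible(path)
}

chrom_length <- function(cs, chrom) {
  i <- match(chrom, cs$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  cs$length[i]
}

# total non-organelle genome length; the effective genome size used for the
# genome-wide Poisson background rate
nuclear_length <- function(cs) sum(cs$length[!cs$organelle])

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

# element-wise shortest decimal representation (no vector-common padding)
format_num <- function(x, digits = 15) {
  vapply(x, function(v) sprintf("%.*g", digits, v), character(1))
}
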