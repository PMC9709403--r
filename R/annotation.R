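# Peak-location classification relative to gene models, promoter-peak gene
# labelling, and the gene-level join with expression values.

#' Annotation configuration
#'
#' The promoter is defined in gene orientation as the window from
#' `upstream` bp before the TSS to `downstream` bp after it, both ends
#' inclusive.  The wheat-scale default (4 kb upstream, 1.5 kb downstream)
#' reflects the long-range promoter structure of large genomes.
#'
#' @param upstream promoter extent upstream of the TSS in bp (default
#'   4000).
#' @param downstream promoter extent downstream of the TSS in bp (default
#'   1500).
#' @return an `annotation_config` list.
#' @export
annotation_config <- function(upstream = 4000, downstream = 1500) {
  stopifnot(upstream >= 0, downstream >= 0)
  structure(list(upstream = upstream, downstream = downstream),
            class = "annotation_config")
}

#' Classify peak summits relative to gene models
#'
#' Each summit is assigned to its nearest gene by absolute summit-to-TSS
#' distance (ties broken toward the lexicographically smaller gene id) on
#' the same chromosome, then categorized with promoter precedence:
#' \enumerate{
#'   \item `promoter` — summit within \[TSS - upstream, TSS + downstream\]
#'     in gene orientation (inclusive at both ends);
#'   \item `genebody` — summit within the gene span;
#'   \item `intergenic_upstream` — summit beyond `upstream` bp upstream of
#'     the TSS;
#'   \item `intergenic_downstream` — otherwise (downstream of the TES).
#' }
#' Summits on chromosomes with no gene are reported `unassigned`.
#'
#' @param peaks peak data.frame; summit positions are `start + summit`.
#' @param genes gene data.frame (see [read_gff3_genes]).
#' @param config an [annotation_config].
#' @return data.frame: peak name, chrom, summit_pos, gene_id,
#'   distance_to_tss (signed, negative = upstream in gene orientation),
#'   category.
#' @export
classify_peaks <- function(peaks, genes, config = annotation_config()) {
  n <- nrow(peaks)
  summit_pos <- peaks$start + peaks$summit
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  category <- rep("unassigned", n)
  go <- genes[order(genes$gene_id), , drop = FALSE]
  for (i in seq_len(n)) {
    cand <- which(go$chrom == peaks$chrom[i])
    if (!length(cand)) next
    d_abs <- abs(summit_pos[i] - go$tss[cand])
    g <- cand[which.min(d_abs)]   # ties -> smallest gene_id (pre-sorted)
    # signed distance in gene orientation: negative = upstream
    d <- if (go$strand[g] == "+") summit_pos[i] - go$tss[g]
         else go$tss[g] - summit_pos[i]
    gene_id[i] <- go$gene_id[g]
    dist[i] <- d
    in_span <- summit_pos[i] >= go$start[g] && summit_pos[i] < go$end[g]
    category[i] <-
      if (d >= -config$upstream && d <= config$downstream) "promoter"
      else if (in_span) "genebody"
      else if (d < -config$upstream) "intergenic_upstream"
      else "intergenic_downstream"
  }
  data.frame(name = peaks$name, chrom = peaks$chrom,
             summit_pos = summit_pos, gene_id = gene_id,
             distance_to_tss = dist, category = category,
             stringsAsFactors = FALSE)
}

#' Label chromatin-accessibility-related genes
#'
#' A gene is labelled accessibility-related when at least one peak summit
#' falls in its promoter window (`upstream` bp before to `downstream` bp
#' after the TSS, gene orientation, inclusive).  Counting is per gene, so
#' a summit in the promoter windows of two overlapping genes counts for
#' both.
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame.
#' @param config an [annotation_config].
#' @return data.frame: gene_id, n_promoter_peaks, related (logical); one
#'   row per input gene.
#' @export
accessibility_related_genes <- function(peaks, genes,
                                        config = annotation_config()) {
  summit_pos <- peaks$start + peaks$summit
  counts <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    on_chr <- peaks$chrom == genes$chrom[g]
    if (!any(on_chr)) next
    d <- if (genes$strand[g] == "+") summit_pos[on_chr] - genes$tss[g]
         else genes$tss[g] - summit_pos[on_chr]
    counts[g] <- sum(d >= -config$upstream & d <= config$downstream)
  }
  data.frame(gene_id = genes$gene_id, n_promoter_peaks = counts,
             related = counts >= 1, stringsAsFactors = FALSE)
}

#' Category proportions of peak annotations
#'
#' @param annotations output of [classify_peaks].
#' @return list with `proportions` (named, over the four assigned
#'   categories, summing to 1) and `n_unassigned`.
#' @export
category_proportions <- function(annotations) {
  stopifnot(nrow(annotations) >= 1)
  cats <- c("promoter", "genebody", "intergenic_upstream",
            "intergenic_downstream")
  assigned <- annotations$category[annotations$category != "unassigned"]
  if (!length(assigned)) stop("no assigned annotations")
  prop <- vapply(cats, function(cc) mean(assigned == cc), numeric(1))
  list(proportions = prop,
       n_unassigned = sum(annotations$category == "unassigned"))
}

#' Join per-gene promoter-peak counts with expression values
#'
#' Inner-joins the gene table from [accessibility_related_genes] with an
#' expression table and summarizes expression by promoter-peak-count
#' group (0, 1, 2, >= 3), the standard view of the
#' accessibility-transcription relationship.
#'
#' @param gene_peaks output of [accessibility_related_genes].
#' @param expression data.frame with columns `gene_id` and a numeric
#'   expression value (second column, e.g. TPM).
#' @return list with `joined` (gene_id, n_promoter_peaks, expression,
#'   group) and `summary` (per group: n, median, q1, q3).  Warns when the
#'   join covers < 50% of genes.
#' @export
join_expression <- function(gene_peaks, expression) {
  stopifnot(ncol(expression) >= 2)
  names(expression)[1:2] <- c("gene_id", "expression")
  joined <- merge(gene_peaks[, c("gene_id", "n_promoter_peaks")],
                  expression[, c("gene_id", "expression")],
                  by = "gene_id")
  if (nrow(joined) < 0.5 * nrow(gene_peaks))
    warning("expression join covers < 50% of genes (",
            nrow(joined), "/", nrow(gene_peaks), ")")
  grp <- cut(joined$n_promoter_peaks, c(-Inf, 0, 1, 2, Inf),
             labels = c("0", "1", "2", ">=3"))
  joined$group <- as.character(grp)
  groups <- c("0", "1", "2", ">=3")
  summ <- do.call(rbind, lapply(groups, function(g) {
    x <- joined$expression[joined$group == g]
    data.frame(group = g, n = length(x),
               median = if (length(x)) median(x) else NA_real_,
               q1 = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
               q3 = if (length(x)) unname(quantile(x, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(joined = joined[order(joined$gene_id), , drop = FALSE],
       summary = summ)
}
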