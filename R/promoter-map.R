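#' Promoter coordinate map
#'
#' Anchors the negative-offset promoter coordinate system (offset -1 is the
#' base immediately upstream of the translation start) to genomic 1-based
#' coordinates. All offsets and sequences in this package live on the
#' *reporting strand*: the strand on which the mutant driver motif reads
#' `CCCCTTCCGG`. For a gene on the genomic minus strand (such as TERT),
#' upstream means higher genomic coordinate.
#'
#' @param contig Chromosome or contig name.
#' @param atg_anchor 1-based genomic coordinate of the base immediately
#'   downstream of offset -1 (the first base of the start codon in gene
#'   orientation).
#' @param gene_strand `"-"` (default; gene on the genomic minus strand) or
#'   `"+"`.
#' @param assembly_tag Free-text assembly label, e.g. `"hg19"`.
#' @return An object of class `promoter_map`.
#' @examples
#' m <- promoter_map()
#' offset_to_genomic(m, c(-124, -146))  # 1295228, 1295250
#' @export
promoter_map <- function(contig = "chr5", atg_anchor = 1295104L,
                         gene_strand = c("-", "+"), assembly_tag = "hg19") {
  gene_strand <- match.arg(gene_strand)
  stopifnot(length(atg_anchor) == 1L, atg_anchor == as.integer(atg_anchor),
            atg_anchor >= 1)
  structure(
    list(contig = contig, atg_anchor = as.integer(atg_anchor),
         gene_strand = gene_strand, assembly_tag = assembly_tag),
    class = "promoter_map"
  )
}

#' Map used for the bundled synthetic promoter
#'
#' The synthetic wild-type promoter ([build_reference_promoter()]) is a
#' 300 bp contig laid out left-to-right from offset -300 to -1 on its plus
#' strand, so the gene sits on the plus strand with the anchor just past the
#' right end.
#'
#' @param contig Contig name for the synthetic locus.
#' @return A `promoter_map`.
#' @export
synthetic_promoter_map <- function(contig = "TERTp_synth") {
  promoter_map(contig = contig, atg_anchor = 301L, gene_strand = "+",
               assembly_tag = "synthetic")
}

#' @export
print.promoter_map <- function(x, ...) {
  cat(sprintf("promoter_map: %s anchor=%d gene_strand=%s [%s]\n",
              x$contig, x$atg_anchor, x$gene_strand, x$assembly_tag))
  invisible(x)
}

#' Convert promoter offsets to genomic coordinates
#'
#' @param map A [promoter_map()].
#' @param offset Integer vector of strictly negative offsets.
#' @return Integer vector of 1-based genomic coordinates.
#' @export
offset_to_genomic <- function(map, offset) {
  stopifnot(inherits(map, "promoter_map"))
  if (any(offset >= 0)) {
    stop("promoter offsets must be strictly negative ",
         "(offset -1 is the base immediately upstream of the start codon)")
  }
  offset <- as.integer(offset)
  if (map$gene_strand == "-") map$atg_anchor - offset else map$atg_anchor + offset
}

#' Convert genomic coordinates to promoter offsets
#'
#' Inverse of [offset_to_genomic()].
#'
#' @param map A [promoter_map()].
#' @param pos Integer vector of 1-based genomic coordinates.
#' @return Integer vector of negative offsets.
#' @export
genomic_to_offset <- function(map, pos) {
  stopifnot(inherits(map, "promoter_map"))
  pos <- as.integer(pos)
  off <- if (map$gene_strand == "-") map$atg_anchor - pos else pos - map$atg_anchor
  if (any(off >= 0)) {
    stop("genomic position does not lie upstream of the anchor on the gene strand")
  }
  off
}
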