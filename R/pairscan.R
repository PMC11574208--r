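## Genome-wide paired ETS-site analysis: upstream-region extraction, motif
## scanning, same-strand pair enumeration, mutation-overlap classes,
## smoothed spacing distributions, ChIP co-occupancy and a helical-period
## score.

#' Read gene models from a TSV
#'
#' Columns: `gene_id`, `contig`, `strand`, `coding_start` (1-based genomic
#' position of the 5'-most coding transcript's start).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "strand", "coding_start")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("gene models missing columns: ",
                            paste(missing, collapse = ", "))
  d
}

#' Extract upstream regions of genes
#'
#' The region is `length` bp immediately 5' of the coding start on the
#' gene's strand, returned as 1-based inclusive genomic intervals on the
#' plus strand: `[start - length, start - 1]` for plus-strand genes,
#' `[start + 1, start + length]` for minus-strand genes. Regions running
#' past the contig start/end are truncated with a warning. Genes on
#' chromosomes X and Y are excluded when `drop_xy` is set.
#'
#' @param genes Gene model data frame (see [read_gene_models()]).
#' @param length Region length in bp (default 1000).
#' @param contig_lengths Named integer vector of contig lengths (for
#'   truncation at the 3' end); optional.
#' @param drop_xy Exclude chrX/chrY (and X/Y) genes (default TRUE).
#' @return Data frame `gene_id`, `contig`, `strand`, `start`, `end`.
#' @export
extract_upstream_regions <- function(genes, length = 1000,
                                     contig_lengths = NULL, drop_xy = TRUE) {
  g <- genes
  if (drop_xy) g <- g[!(g$contig %in% c("chrX", "chrY", "X", "Y")), , drop = FALSE]
  plus <- g$strand == "+"
  start <- ifelse(plus, g$coding_start - length, g$coding_start + 1L)
  end <- ifelse(plus, g$coding_start - 1L, g$coding_start + length)
  if (any(start < 1L)) {
    warning(sum(start < 1L), " region(s) truncated at the contig start")
    start <- pmax(start, 1L)
  }
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[g$contig]
    over <- !is.na(lim) & end > lim
    if (any(over)) {
      warning(sum(over), " region(s) truncated at the contig end")
      end[over] <- lim[over]
    }
  }
  keep <- end >= start
  data.frame(gene_id = g$gene_id[keep], contig = g$contig[keep],
             strand = g$strand[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), stringsAsFactors = FALSE)
}

#' Scan regions for the 7-mer ETS motif (NNTTCCK)
#'
#' All 7-mers whose positions 3-7 read `TTCCK` (K = G/T) on either strand,
#' requiring the two flanking prefix bases to lie inside the region (since
#' `NNTTCCG` is a subset of `NNTTCCK`, the union equals the `NNTTCCK`
#' scan). Positions are reported 1-based on the genomic plus strand as the
#' leftmost base of the 7-mer, with a strand flag; ambiguous bases never
#' match. Identical hits arising from overlapping regions are deduplicated.
#'
#' @param genome A named [Biostrings::DNAStringSet] of contig sequences.
#' @param regions Region data frame from [extract_upstream_regions()].
#' @return Data frame `contig`, `start` (leftmost plus-strand coordinate of
#'   the 7-mer), `strand`, `kmer`.
#' @export
scan_motifs <- function(genome, regions) {
  core <- Biostrings::DNAString("TTCCK")
  rc_core <- Biostrings::reverseComplement(core)
  hits <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctg <- regions$contig[i]
    sq <- Biostrings::subseq(genome[[ctg]], regions$start[i], regions$end[i])
    L <- length(sq)
    f <- BiocGenerics::start(Biostrings::matchPattern(core, sq, fixed = "subject"))
    f <- f[f >= 3L]                     # NN prefix must exist in the region
    r <- BiocGenerics::start(Biostrings::matchPattern(rc_core, sq, fixed = "subject"))
    r <- r[r + 6L <= L]                 # prefix on the minus strand
    if (length(f) + length(r) == 0) next
    s0 <- regions$start[i] - 1L
    hits[[i]] <- data.frame(
      contig = ctg,
      start = as.integer(s0 + c(f - 2L, r)),
      strand = rep(c("+", "-"), c(length(f), length(r))),
      stringsAsFactors = FALSE)
  }
  h <- do.call(rbind, hits)
  if (is.null(h)) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), kmer = character(0)))
  }
  h <- unique(h)
  h <- h[order(h$contig, h$start, h$strand), , drop = FALSE]
  h$kmer <- vapply(seq_len(nrow(h)), function(i) {
    k <- as.character(Biostrings::subseq(genome[[h$contig[i]]],
                                         h$start[i], h$start[i] + 6L))
    if (h$strand[i] == "-") revcomp(k) else k
  }, character(1))
  rownames(h) <- NULL
  h
}

#' Enumerate same-strand motif pairs within a spacing window
#'
#' All ordered same-strand pairs with start-to-start distance between
#' `min_dist` and `max_dist` (7..100 bp by default; the lower bound keeps
#' the 7-mers non-overlapping). A hit may participate in several pairs.
#'
#' @param hits Motif hit data frame from [scan_motifs()].
#' @param min_dist,max_dist Distance bounds, inclusive.
#' @return Data frame `contig`, `strand`, `start_a`, `start_b`
#'   (`start_a < start_b`), `distance`.
#' @export
enumerate_pairs <- function(hits, min_dist = 7, max_dist = 100) {
  out <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    s <- sort(unique(sub$start))
    if (length(s) < 2) next
    idx <- which(outer(s, s, function(a, b) {
      d <- b - a; d >= min_dist & d <= max_dist
    }), arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[key]] <- data.frame(contig = sub$contig[1], strand = sub$strand[1],
                             start_a = s[idx[, 1]], start_b = s[idx[, 2]],
                             distance = s[idx[, 2]] - s[idx[, 1]],
                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), strand = character(0),
               start_a = integer(0), start_b = integer(0),
               distance = integer(0))
  rownames(res) <- NULL
  res[order(res$contig, res$start_a, res$start_b), , drop = FALSE]
}

#' Count mutations overlapping motif footprints
#'
#' @param hits Motif hits.
#' @param mutations Data frame with `donor`, `contig`, `start`, `alt` (and
#'   optionally `span`); deduplicated per (donor, contig, start, alt).
#' @param snv_only Restrict to span-1 records when a `span` column exists.
#' @return Integer vector: mutations per hit 7-mer footprint.
#' @export
count_site_mutations <- function(hits, mutations, snv_only = TRUE) {
  m <- mutations
  if (snv_only && !is.null(m$span)) m <- m[m$span == 1L, , drop = FALSE]
  m <- unique(m[, intersect(c("donor", "contig", "start", "alt"), names(m)),
                drop = FALSE])
  if (!nrow(hits)) return(integer(0))
  gr_h <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start, hits$start + 6L))
  gr_m <- GenomicRanges::GRanges(m$contig, IRanges::IRanges(m$start, m$start))
  GenomicRanges::countOverlaps(gr_h, gr_m)
}

#' Classify motif pairs by per-site mutation load
#'
#' Classes: `ge2_per_site` when both sites of the pair carry at least two
#' overlapping mutations; `ge1_per_site` when both carry at least one (and
#' not ge2); `0` otherwise. With `per_site = FALSE`, the load is instead
#' summed over either site (non-default).
#'
#' @param pairs Pair data frame from [enumerate_pairs()].
#' @param hits Motif hits the pairs were built from.
#' @param mutations Mutation data frame (see [count_site_mutations()]).
#' @param snv_only Restrict to SNVs (default TRUE).
#' @param per_site Require the threshold at both sites (default TRUE).
#' @return `pairs` with added columns `mut_a`, `mut_b`, `mutation_class`.
#' @export
classify_pairs <- function(pairs, hits, mutations, snv_only = TRUE,
                           per_site = TRUE) {
  n_mut <- count_site_mutations(hits, mutations, snv_only)
  key <- paste(hits$contig, hits$start, hits$strand)
  lut <- stats::setNames(n_mut, key)
  pairs$mut_a <- unname(lut[paste(pairs$contig, pairs$start_a, pairs$strand)])
  pairs$mut_b <- unname(lut[paste(pairs$contig, pairs$start_b, pairs$strand)])
  cls <- if (per_site) {
    ifelse(pairs$mut_a >= 2 & pairs$mut_b >= 2, "ge2_per_site",
           ifelse(pairs$mut_a >= 1 & pairs$mut_b >= 1, "ge1_per_site", "0"))
  } else {
    tot <- pairs$mut_a + pairs$mut_b
    ifelse(tot >= 4, "ge2_per_site", ifelse(tot >= 2, "ge1_per_site", "0"))
  }
  pairs$mutation_class <- cls
  pairs
}

#' Smoothed, normalized spacing distribution
#'
#' Raw pair counts per start-to-start distance, smoothed with a centred
#' moving average of window 3 (edges averaged over the available
#' neighbours) and normalized by the total.
#'
#' @param distances Integer vector of pair distances.
#' @param min_dist,max_dist Distance support (default 7..100).
#' @return Data frame `distance`, `count`, `smoothed`, `normalized`; zero
#'   rows with attribute `empty = TRUE` when no pairs exist.
#' @export
spacing_distribution <- function(distances, min_dist = 7, max_dist = 100) {
  supp <- min_dist:max_dist
  counts <- as.numeric(table(factor(distances, levels = supp)))
  if (sum(counts) == 0) {
    out <- data.frame(distance = supp, count = counts, smoothed = counts,
                      normalized = counts)
    attr(out, "empty") <- TRUE
    return(out)
  }
  n <- length(counts)
  sm <- vapply(seq_len(n), function(i) {
    j <- max(1, i - 1):min(n, i + 1)
    mean(counts[j])
  }, numeric(1))
  data.frame(distance = supp, count = counts, smoothed = sm,
             normalized = sm / sum(sm))
}

#' Read ENCODE broadPeak files
#'
#' BED6+3: chrom, start, end, name, score, strand, signalValue, pValue,
#' qValue.
#'
#' @param path broadPeak file path.
#' @return A [GenomicRanges::GRanges] with `signalValue` metadata.
#' @export
read_broadpeak <- function(path) {
  rtracklayer::import(path, format = "bed",
                      extraCols = c(signalValue = "numeric",
                                    pValue = "numeric", qValue = "numeric"))
}

#' ChIP-peak co-occupancy of motif pairs
#'
#' Per experiment, peaks are filtered to the top quartile by enrichment
#' score (`signalValue`); a pair is co-occupied when both site starts fall
#' within one and the same retained peak, in at least one experiment.
#' Experiments with fewer than 4 peaks have no defined quartile and are
#' skipped with a warning.
#'
#' @param pairs Classified pair data frame.
#' @param peak_sets Named list of `GRanges` (one per experiment: cell line
#'   x replicate), each with a `signalValue` column.
#' @param top_quartile Apply the quartile filter (default TRUE).
#' @return List with `pairs` (added logical `chip_cooccupied`) and
#'   `by_class` (data frame `mutation_class`, `n_pairs`, `n_cooccupied`,
#'   `fraction`).
#' @export
chip_cooccupancy <- function(pairs, peak_sets, top_quartile = TRUE) {
  co <- rep(FALSE, nrow(pairs))
  span <- GenomicRanges::GRanges(pairs$contig,
                                 IRanges::IRanges(pairs$start_a, pairs$start_b))
  for (nm in names(peak_sets)) {
    pk <- peak_sets[[nm]]
    if (top_quartile) {
      if (length(pk) < 4) {
        warning("experiment ", nm, " has fewer than 4 peaks; skipped")
        next
      }
      thr <- stats::quantile(pk$signalValue, 0.75, names = FALSE)
      pk <- pk[pk$signalValue >= thr]
    }
    ov <- GenomicRanges::findOverlaps(span, pk, type = "within")
    co[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  pairs$chip_cooccupied <- co
  by_class <- do.call(rbind, lapply(sort(unique(pairs$mutation_class)), function(cl) {
    i <- pairs$mutation_class == cl
    data.frame(mutation_class = cl, n_pairs = sum(i),
               n_cooccupied = sum(co[i]), fraction = mean(co[i]))
  }))
  list(pairs = pairs, by_class = by_class)
}

#' Helical-period score of a spacing distribution
#'
#' Period estimated by maximizing the normalized autocorrelation of the
#' mean-subtracted smoothed distribution over lags 8-14 bp; the amplitude
#' is the autocorrelation at the chosen lag. A degenerate (single-distance
#' or empty) distribution returns `NA`s.
#'
#' @param dist Data frame from [spacing_distribution()].
#' @param lags Candidate period lags (default 8:14).
#' @return List `period`, `amplitude` (both `NA` when degenerate).
#' @export
periodicity_score <- function(dist, lags = 8:14) {
  v <- dist$smoothed
  if (sum(v > 0) <= 1) {
    return(list(period = NA_real_, amplitude = NA_real_))
  }
  if (stats::sd(v) == 0) {
    # perfectly uniform spacing: no periodic structure at any lag
    return(list(period = NA_real_, amplitude = 0))
  }
  v0 <- v - mean(v)
  denom <- sum(v0^2)
  ac <- vapply(lags, function(l) {
    n <- length(v0)
    if (l >= n) return(NA_real_)
    sum(v0[1:(n - l)] * v0[(1 + l):n]) / denom
  }, numeric(1))
  best <- which.max(ac)
  list(period = lags[best], amplitude = ac[best])
}
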