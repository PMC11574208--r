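## Simplified ultrasensitive amplicon analysis: UMI family grouping,
## >= 3-read consensus calling, indel-consensus filtering, and subclonal
## mutation calling phased against a driver allele.

#' Read UMI-tagged amplicon reads from FASTQ
#'
#' Each read is expected to start with a fixed-length UMI followed by the
#' amplicon sequence (locus-specific primer included).
#'
#' @param path FASTQ file path.
#' @param umi_length UMI length in bases (default 12).
#' @return Data frame `read_id`, `umi`, `bases`, `quals`; reads shorter
#'   than the UMI are dropped and counted in the `n_malformed` attribute.
#' @export
read_umi_fastq <- function(path, umi_length = 12) {
  rd <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seqs <- as.character(rd)
  quals <- as.character(S4Vectors::mcols(rd)$qualities)
  ok <- nchar(seqs) > umi_length
  out <- data.frame(read_id = names(rd)[ok],
                    umi = substr(seqs[ok], 1, umi_length),
                    bases = substr(seqs[ok], umi_length + 1, nchar(seqs[ok])),
                    quals = substr(quals[ok], umi_length + 1, nchar(seqs[ok])),
                    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Anchor amplicon reads by primer match
#'
#' The amplicon is located by matching `primer` at the start of the
#' (UMI-stripped) read, allowing up to `max_mismatch` substitutions; the
#' remainder of the read is the target window. A remainder whose length
#' differs from `window_length` indicates an insertion or deletion and is
#' flagged. Unanchored reads are dropped and counted.
#'
#' @param reads Data frame from [read_umi_fastq()].
#' @param primer Primer sequence immediately preceding the target window.
#' @param window_length Expected target window length.
#' @param max_mismatch Maximum primer mismatches (default 1).
#' @return `reads` subset with added columns `window` (trimmed to
#'   `window_length` where possible) and `indel` (logical); attribute
#'   `n_unanchored`.
#' @export
anchor_reads <- function(reads, primer, window_length, max_mismatch = 1) {
  plen <- nchar(primer)
  pm <- substr(reads$bases, 1, plen)
  mism <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                 pm, rep(primer, length(pm)), USE.NAMES = FALSE)
  mism[nchar(pm) < plen] <- plen
  ok <- mism <= max_mismatch
  out <- reads[ok, , drop = FALSE]
  rest <- substr(out$bases, plen + 1, nchar(out$bases))
  restq <- substr(out$quals, plen + 1, nchar(out$quals))
  out$indel <- nchar(rest) != window_length
  out$window <- substr(rest, 1, window_length)
  out$window_qual <- substr(restq, 1, window_length)
  attr(out, "n_unanchored") <- sum(!ok)
  out
}

#' Group reads into UMI families
#'
#' Exact-match grouping on the UMI string; optionally, UMIs at Hamming
#' distance 1 from a larger family's UMI are collapsed into it (off by
#' default, as hairpin-protected UMIs have low tag error).
#'
#' @param reads Anchored read data frame (needs a `umi` column).
#' @param collapse_1mm Collapse 1-mismatch UMIs into the larger family.
#' @return `reads` with an added `family` column (the family's UMI).
#' @export
group_families <- function(reads, collapse_1mm = FALSE) {
  reads$family <- reads$umi
  if (!collapse_1mm || !nrow(reads)) return(reads)
  sizes <- sort(table(reads$umi), decreasing = TRUE)
  canon <- stats::setNames(names(sizes), names(sizes))
  umis <- names(sizes)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (u in umis) assign(u, TRUE, envir = seen)
  for (u in umis) {
    if (canon[[u]] != u) next
    # absorb smaller 1-mismatch neighbours generated explicitly
    chars <- strsplit(u, "")[[1]]
    for (i in seq_along(chars)) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
        v <- chars; v[i] <- b; v <- paste(v, collapse = "")
        if (!is.null(seen[[v]]) && sizes[v] < sizes[u] && canon[[v]] == v) {
          canon[v] <- u
        }
      }
    }
  }
  reads$family <- unname(canon[reads$umi])
  reads
}

#' Call UMI-family consensus reads
#'
#' Families with fewer than `min_family` members yield no consensus. Per
#' position, the consensus base is the one reached by at least `agreement`
#' of the (non-indel) members, otherwise an `N` ambiguity mark. A family
#' whose members predominantly show an anchoring length deviation is
#' flagged `has_indel` (such consensus reads are removed downstream).
#'
#' @param reads Anchored, grouped read data frame (columns `family`,
#'   `window`, `indel`).
#' @param min_family Minimum raw reads per consensus (default 3).
#' @param agreement Fraction of members that must agree (default 2/3).
#' @return Data frame `umi`, `family_size`, `has_indel`, `genotype`
#'   (consensus window string, `NA` for indel families), one row per
#'   retained family.
#' @export
call_consensus <- function(reads, min_family = 3, agreement = 2 / 3) {
  if (!nrow(reads)) {
    return(data.frame(umi = character(0), family_size = integer(0),
                      has_indel = logical(0), genotype = character(0)))
  }
  fam_size <- table(reads$family)
  keep_fams <- names(fam_size)[fam_size >= min_family]
  r <- reads[reads$family %in% keep_fams, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(umi = character(0), family_size = integer(0),
                      has_indel = logical(0), genotype = character(0)))
  }
  indel_frac <- tapply(r$indel, r$family, mean)
  has_indel <- indel_frac[keep_fams] >= agreement
  # base consensus from length-consistent members only
  rc <- r[!r$indel, , drop = FALSE]
  geno <- stats::setNames(rep(NA_character_, length(keep_fams)), keep_fams)
  if (nrow(rc)) {
    wl <- nchar(rc$window[1])
    mat <- matrix(unlist(strsplit(rc$window, ""), use.names = FALSE),
                  nrow = nrow(rc), ncol = wl, byrow = TRUE)
    fam <- factor(rc$family)
    n_by_fam <- as.integer(table(fam))
    counts <- lapply(c("A", "C", "G", "T"), function(b)
      rowsum((mat == b) + 0L, fam))
    best <- counts[[1]]; best_base <- matrix("A", nrow(counts[[1]]), wl)
    for (k in 2:4) {
      better <- counts[[k]] > best
      best[better] <- counts[[k]][better]
      best_base[better] <- c("A", "C", "G", "T")[k]
    }
    ok <- best >= ceiling(agreement * n_by_fam - 1e-9)
    best_base[!ok] <- "N"
    g <- apply(best_base, 1, paste, collapse = "")
    geno[levels(fam)] <- g
  }
  out <- data.frame(umi = keep_fams,
                    family_size = as.integer(fam_size[keep_fams]),
                    has_indel = as.logical(has_indel),
                    genotype = unname(geno[keep_fams]),
                    stringsAsFactors = FALSE)
  out$genotype[out$has_indel] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Remove indel-containing consensus reads
#'
#' @param consensus Data frame from [call_consensus()].
#' @return Filtered data frame; the number removed is in the
#'   `n_indel_removed` attribute.
#' @export
filter_indel_consensus <- function(consensus) {
  out <- consensus[!consensus$has_indel & !is.na(consensus$genotype), ,
                   drop = FALSE]
  attr(out, "n_indel_removed") <- nrow(consensus) - nrow(out)
  out
}

#' Call subclonal mutations phased against the driver allele
#'
#' Consensus reads are partitioned by their base at the driver position
#' (reference vs any alternative; `N` excluded from both axes and counted).
#' Per position and alternative base, consensus-read support is tallied on
#' each axis; a site is reported when its total support exceeds
#' `min_consensus_reads`.
#'
#' @param consensus Indel-filtered consensus data frame.
#' @param window_offsets Integer vector of promoter offsets for the window
#'   columns (length = window length).
#' @param ref_window Reference (wild-type) window sequence.
#' @param driver_offset Offset of the driver base (default -146).
#' @param min_consensus_reads Report sites with support strictly greater
#'   than this (default 1, i.e. at least 2 consensus reads).
#' @return List with `calls` (data frame `offset`, `alt`,
#'   `driver_mut_support`, `driver_ref_support`, `total_support`),
#'   `n_driver_mut`, `n_driver_ref`, `n_driver_ambiguous`.
#' @export
call_subclonal <- function(consensus, window_offsets, ref_window,
                           driver_offset = -146L, min_consensus_reads = 1) {
  wl <- nchar(ref_window)
  stopifnot(length(window_offsets) == wl)
  di <- match(driver_offset, window_offsets)
  if (is.na(di)) stop("driver offset not inside the amplicon window")
  g <- consensus$genotype
  if (!length(g)) {
    return(list(calls = data.frame(offset = integer(0), alt = character(0),
                                   driver_mut_support = integer(0),
                                   driver_ref_support = integer(0),
                                   total_support = integer(0)),
                n_driver_mut = 0L, n_driver_ref = 0L, n_driver_ambiguous = 0L))
  }
  mat <- matrix(unlist(strsplit(g, ""), use.names = FALSE),
                nrow = length(g), ncol = wl, byrow = TRUE)
  ref <- strsplit(toupper(ref_window), "")[[1]]
  drv <- mat[, di]
  amb <- drv == "N"
  is_mut <- drv != ref[di] & !amb
  is_ref <- drv == ref[di]
  calls <- list()
  for (j in seq_len(wl)) {
    col <- mat[, j]
    for (b in setdiff(unique(col), c(ref[j], "N"))) {
      hit <- col == b
      ms <- sum(hit & is_mut); rs <- sum(hit & is_ref)
      if (ms + rs > min_consensus_reads) {
        calls[[length(calls) + 1L]] <-
          data.frame(offset = window_offsets[j], alt = b,
                     driver_mut_support = ms, driver_ref_support = rs,
                     total_support = ms + rs, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(offset = integer(0), alt = character(0),
               driver_mut_support = integer(0), driver_ref_support = integer(0),
               total_support = integer(0))
  calls <- calls[order(calls$offset), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, n_driver_mut = sum(is_mut), n_driver_ref = sum(is_ref),
       n_driver_ambiguous = sum(amb))
}
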