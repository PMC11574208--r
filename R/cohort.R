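## Cohort pipeline: MAF-style ingestion, filtering, recurrence, subcohort
## classification, co-occurrence and burden-binned correlation.

MAF_COLS <- c(sample_id = "Tumor_Sample_Barcode", contig = "Chromosome",
              start = "Start_Position", ref = "Reference_Allele",
              alt = "Tumor_Seq_Allele2")

#' Read a MAF-style somatic mutation table
#'
#' Tab-delimited, 1-based inclusive coordinates. Required columns:
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`. All substitution records must
#' have equal-length ref and alt alleles; other columns are carried through.
#'
#' @param path File path.
#' @return Data frame with standardized columns `sample_id`, `contig`,
#'   `start`, `ref`, `alt`, `span` (1 = SNV, 2 = DNV, >= 3 = ONV), plus any
#'   extra input columns.
#' @export
read_maf <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  missing <- setdiff(unname(MAF_COLS), names(d))
  if (length(missing)) stop("MAF is missing columns: ", paste(missing, collapse = ", "))
  out <- d
  for (nm in names(MAF_COLS)) out[[nm]] <- d[[MAF_COLS[[nm]]]]
  standardize_mutations(out)
}

standardize_mutations <- function(m) {
  m$ref <- toupper(m$ref); m$alt <- toupper(m$alt)
  if (any(nchar(m$ref) != nchar(m$alt))) {
    stop("only length-preserving substitutions (SNV/DNV/ONV) are supported")
  }
  if (!all(grepl("^[ACGT]+$", m$ref)) || !all(grepl("^[ACGT]+$", m$alt))) {
    stop("alleles must be uppercase A/C/G/T strings")
  }
  m$start <- as.integer(m$start)
  m$span <- nchar(m$ref)
  m
}

#' Write mutations as a minimal MAF
#'
#' @param mutations Standardized mutation data frame.
#' @param path Output path.
#' @export
write_maf <- function(mutations, path) {
  d <- data.frame(
    Hugo_Symbol = if (!is.null(mutations$gene)) mutations$gene else "TERT",
    Chromosome = mutations$contig,
    Start_Position = mutations$start,
    End_Position = mutations$start + nchar(mutations$ref) - 1L,
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele2 = mutations$alt,
    Variant_Type = c("SNP", "DNP", "ONP")[pmin(nchar(mutations$ref), 3L)],
    Tumor_Sample_Barcode = mutations$sample_id,
    stringsAsFactors = FALSE)
  if (!is.null(mutations$ref_context)) d$ref_context <- mutations$ref_context
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `patient_id`, `cancer_type`,
#' `assay_id`, `capture_size_bp`, `covers_tertp`, `report_order`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_meta <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "cancer_type")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("sample metadata missing columns: ",
                            paste(missing, collapse = ", "))
  d
}

#' Construct a cohort table
#'
#' Bundles mutations with sample metadata; every mutation's sample must be
#' present in the metadata. Filter provenance accumulates in
#' `filters_applied`.
#'
#' @param mutations Standardized mutation data frame (see [read_maf()]).
#' @param samples Sample metadata data frame.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(mutations, samples) {
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  orphan <- setdiff(unique(mutations$sample_id), samples$sample_id)
  if (length(orphan)) stop("mutations reference unknown samples: ",
                           paste(utils::head(orphan, 3), collapse = ", "))
  structure(list(mutations = mutations, samples = samples,
                 filters_applied = data.frame(step = character(0),
                                              samples_removed = integer(0),
                                              mutations_removed = integer(0))),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples, %d mutations, %d filter steps\n",
              nrow(x$samples), nrow(x$mutations), nrow(x$filters_applied)))
  invisible(x)
}

## Reporting-strand promoter calls ------------------------------------------

#' Annotate mutations with promoter offsets and reporting-strand alleles
#'
#' Mutations on the promoter contig whose full footprint lies inside the
#' catalogue window get `offset` (of the most upstream, i.e. most negative,
#' substituted base), `ref_rs`/`alt_rs` (alleles on the reporting strand) and
#' `site_key` (`"<offset>:<ref>><alt>"`). For a gene on the genomic minus
#' strand the reporting strand is the minus strand, so alleles are
#' reverse-complemented and allele strings reversed.
#'
#' @param mutations Standardized mutation data frame.
#' @param catalog A `site_catalog`.
#' @return `mutations` with the added columns (`NA` off-promoter).
#' @export
annotate_promoter <- function(mutations, catalog) {
  map <- catalog$map
  m <- mutations
  m$offset <- NA_integer_
  m$ref_rs <- NA_character_; m$alt_rs <- NA_character_
  on <- m$contig == map$contig
  if (any(on)) {
    first <- m$start[on]
    last <- first + m$span[on] - 1L
    off_first <- if (map$gene_strand == "-") map$atg_anchor - first else first - map$atg_anchor
    off_last <- if (map$gene_strand == "-") map$atg_anchor - last else last - map$atg_anchor
    lo_off <- pmin(off_first, off_last)
    hi_off <- pmax(off_first, off_last)
    inside <- lo_off >= catalog$window[1] & hi_off <= catalog$window[2] &
      hi_off <= -1L
    idx <- which(on)[inside]
    if (length(idx)) {
      m$offset[idx] <- pmin(off_first, off_last)[inside]
      if (map$gene_strand == "-") {
        m$ref_rs[idx] <- revcomp(m$ref[idx])
        m$alt_rs[idx] <- revcomp(m$alt[idx])
      } else {
        m$ref_rs[idx] <- m$ref[idx]
        m$alt_rs[idx] <- m$alt[idx]
      }
    }
  }
  m$site_key <- ifelse(is.na(m$offset), NA_character_,
                       paste0(m$offset, ":", m$ref_rs, ">", m$alt_rs))
  m
}

driver_keys <- function(catalog) {
  vapply(seq_len(nrow(catalog$driver_set)), function(i) {
    d <- catalog$driver_set[i, ]
    paste0(min(d$offsets[[1]]), ":", d$ref, ">", d$alt)
  }, character(1))
}

#' Flag samples carrying a primary driver mutation
#'
#' @param cohort A `cohort_table`.
#' @param catalog A `site_catalog`.
#' @return Named logical vector over `cohort$samples$sample_id`.
#' @export
sample_has_driver <- function(cohort, catalog) {
  ann <- annotate_promoter(cohort$mutations, catalog)
  hit <- ann$sample_id[!is.na(ann$site_key) & ann$site_key %in% driver_keys(catalog)]
  out <- cohort$samples$sample_id %in% hit
  names(out) <- cohort$samples$sample_id
  out
}

#' Flag samples with any mutation overlapping a set of promoter offsets
#'
#' A mutation overlaps if any substituted base falls on one of `offsets`.
#' Primary driver events are excluded when `exclude_drivers` is set, so that
#' e.g. native-site secondary status is not confounded by drivers.
#'
#' @param cohort A `cohort_table`.
#' @param catalog A `site_catalog`.
#' @param offsets Integer vector of promoter offsets.
#' @param exclude_drivers Drop catalogue driver events before flagging.
#' @return Named logical vector over samples.
#' @export
sample_has_site <- function(cohort, catalog, offsets, exclude_drivers = TRUE) {
  ann <- annotate_promoter(cohort$mutations, catalog)
  ann <- ann[!is.na(ann$offset), , drop = FALSE]
  if (exclude_drivers) ann <- ann[!(ann$site_key %in% driver_keys(catalog)), , drop = FALSE]
  ov <- logical(nrow(ann))
  s1 <- ann$span == 1L
  ov[s1] <- ann$offset[s1] %in% offsets
  for (i in which(!s1)) {
    span_off <- ann$offset[i] + seq_len(ann$span[i]) - 1L
    changed <- strsplit(ann$ref_rs[i], "")[[1]] != strsplit(ann$alt_rs[i], "")[[1]]
    ov[i] <- any(span_off[changed] %in% offsets)
  }
  hit <- unique(ann$sample_id[ov])
  out <- cohort$samples$sample_id %in% hit
  names(out) <- cohort$samples$sample_id
  out
}

## Filtering ----------------------------------------------------------------

#' Apply the cohort inclusion filters
#'
#' Filters are applied in a fixed order, each logged with its removal
#' counts: (1) assay filter -- samples whose assay does not cover the
#' promoter or captured fewer than `min_capture_bp` bases (missing capture
#' metadata excludes the sample, with a log entry); (2) first sample per
#' patient (lowest `report_order`); (3) cancer types with fewer than
#' `min_samples_per_type` samples or fewer than `min_mutations_per_type`
#' mutations in total; (4) cancer types whose primary-driver mutation
#' frequency is below `min_driver_freq`.
#'
#' @param cohort A `cohort_table`.
#' @param catalog A `site_catalog` (for driver identification).
#' @param min_capture_bp Minimum assay capture size (default 300,000 bp).
#' @param min_samples_per_type,min_mutations_per_type Cancer-type floors
#'   (defaults 40 samples / 500 mutations).
#' @param min_driver_freq Driver-frequency floor (default 1%).
#' @return Filtered `cohort_table` with `filters_applied` updated. The
#'   operation is idempotent.
#' @export
filter_cohort <- function(cohort, catalog, min_capture_bp = 300000,
                          min_samples_per_type = 40,
                          min_mutations_per_type = 500,
                          min_driver_freq = 0.01) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep_samples <- function(ch, keep, step) {
    drop_n <- sum(!keep)
    mut_drop <- sum(!(ch$mutations$sample_id %in% ch$samples$sample_id[keep]))
    ch$samples <- ch$samples[keep, , drop = FALSE]
    ch$mutations <- ch$mutations[ch$mutations$sample_id %in% ch$samples$sample_id, , drop = FALSE]
    ch$filters_applied <- rbind(ch$filters_applied,
                                data.frame(step = step, samples_removed = drop_n,
                                           mutations_removed = mut_drop))
    ch
  }
  s <- cohort$samples
  covers <- if (!is.null(s$covers_tertp)) s$covers_tertp else rep(NA, nrow(s))
  capture <- if (!is.null(s$capture_size_bp)) s$capture_size_bp else rep(NA_real_, nrow(s))
  ok <- !is.na(covers) & covers & !is.na(capture) & capture >= min_capture_bp
  n_missing <- sum(is.na(covers) | is.na(capture))
  cohort <- keep_samples(cohort, ok, sprintf("assay (covers promoter, capture >= %g bp; %d with missing metadata excluded)",
                                             min_capture_bp, n_missing))

  s <- cohort$samples
  ord <- if (!is.null(s$report_order)) s$report_order else seq_len(nrow(s))
  first <- !duplicated(s$patient_id[order(s$patient_id, ord)])
  keep_ids <- s$sample_id[order(s$patient_id, ord)][first]
  cohort <- keep_samples(cohort, s$sample_id %in% keep_ids, "first sample per patient")

  s <- cohort$samples
  n_by_type <- table(s$cancer_type)
  mut_by_type <- table(factor(s$cancer_type[match(cohort$mutations$sample_id, s$sample_id)],
                              levels = names(n_by_type)))
  ok_type <- names(n_by_type)[n_by_type >= min_samples_per_type &
                                mut_by_type >= min_mutations_per_type]
  cohort <- keep_samples(cohort, s$cancer_type %in% ok_type,
                         sprintf("cancer-type size (>= %d samples, >= %d mutations)",
                                 min_samples_per_type, min_mutations_per_type))

  s <- cohort$samples
  drv <- sample_has_driver(cohort, catalog)
  freq <- tapply(drv[s$sample_id], s$cancer_type, mean)
  ok_type <- names(freq)[!is.na(freq) & freq >= min_driver_freq]
  cohort <- keep_samples(cohort, s$cancer_type %in% ok_type,
                         sprintf("driver frequency >= %g%%", 100 * min_driver_freq))
  cohort
}

#' Split oligonucleotide variants into their SNV components
#'
#' Records with span >= 3 are decomposed into one SNV per position where ref
#' and alt differ; dinucleotide variants (span 2) pass through unchanged, as
#' do SNVs. Records whose alleles agree at every position are dropped with a
#' warning. The multiset of single-base changes is conserved.
#'
#' @param mutations Standardized mutation data frame.
#' @return Mutation data frame with ONVs decomposed.
#' @export
split_onvs <- function(mutations) {
  m <- mutations
  degenerate <- m$ref == m$alt
  if (any(degenerate)) {
    warning(sum(degenerate), " record(s) with ref == alt dropped")
    m <- m[!degenerate, , drop = FALSE]
  }
  is_onv <- m$span >= 3L
  keep <- m[!is_onv, , drop = FALSE]
  if (!any(is_onv)) return(keep)
  pieces <- lapply(which(is_onv), function(i) {
    r <- strsplit(m$ref[i], "")[[1]]; a <- strsplit(m$alt[i], "")[[1]]
    at <- which(r != a)
    out <- m[rep(i, length(at)), , drop = FALSE]
    out$start <- m$start[i] + at - 1L
    out$ref <- r[at]; out$alt <- a[at]; out$span <- 1L
    out
  })
  out <- rbind(keep, do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}

#' Call recurrent promoter sites
#'
#' A site is a (offset, reporting-strand ref > alt) pattern; SNVs and DNVs
#' are tallied separately because their `site_key`s differ. A site is
#' recurrent when mutated in at least `min_samples` distinct samples and
#' lying within `window_bp` of the translation start.
#'
#' @param cohort A `cohort_table`.
#' @param catalog A `site_catalog`.
#' @param min_samples Distinct-sample threshold (default 10).
#' @param window_bp Window upstream of the start codon (default 300).
#' @return Data frame with `site_key`, `offset`, `span`, `n_samples`,
#'   `recurrent`.
#' @export
call_recurrent_sites <- function(cohort, catalog, min_samples = 10,
                                 window_bp = 300) {
  ann <- annotate_promoter(cohort$mutations, catalog)
  ann <- ann[!is.na(ann$offset) & ann$offset >= -window_bp, , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(site_key = character(0), offset = integer(0),
                      span = integer(0), n_samples = integer(0),
                      recurrent = logical(0)))
  }
  tal <- unique(ann[, c("site_key", "offset", "span", "sample_id")])
  n <- tapply(tal$sample_id, tal$site_key, function(x) length(unique(x)))
  info <- tal[!duplicated(tal$site_key), c("site_key", "offset", "span")]
  info$n_samples <- as.integer(n[info$site_key])
  info$recurrent <- info$n_samples >= min_samples
  info[order(info$offset), ]
}

## Subcohorts, co-occurrence, burden bins -----------------------------------

#' Classify cancer types into promoter/UV subcohorts
#'
#' Types with driver frequency of at least `driver_thresh` split by UV
#' fraction into `high_tertp_uv` (>= `uv_thresh`) and `high_tertp_no_uv`;
#' all remaining types are `low_tertp`. UV fraction per type aggregates
#' per-sample UV-attributed fractions by unweighted mean (default) or by
#' mutation-count weighting.
#'
#' @param cohort A `cohort_table`.
#' @param catalog A `site_catalog`.
#' @param uv_fractions Data frame `sample_id`, `uv_fraction` (per-sample
#'   fraction of mutations attributed to the UV signatures), optionally
#'   `n_mutations` for pooled aggregation.
#' @param driver_thresh,uv_thresh Classification thresholds (0.20, 0.10).
#' @param aggregate `"mean"` or `"pooled"`.
#' @return Data frame per cancer type with `driver_frequency`,
#'   `uv_fraction`, `label`, `low_confidence` (no signature data).
#' @export
classify_subcohorts <- function(cohort, catalog, uv_fractions,
                                driver_thresh = 0.20, uv_thresh = 0.10,
                                aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  s <- cohort$samples
  drv <- sample_has_driver(cohort, catalog)
  types <- sort(unique(s$cancer_type))
  uv <- uv_fractions[match(s$sample_id, uv_fractions$sample_id), , drop = FALSE]
  out <- do.call(rbind, lapply(types, function(ty) {
    i <- s$cancer_type == ty
    f <- mean(drv[s$sample_id[i]])
    u <- uv$uv_fraction[i]
    low_conf <- all(is.na(u))
    uvf <- if (low_conf) 0 else if (aggregate == "mean") {
      mean(u, na.rm = TRUE)
    } else {
      w <- uv$n_mutations[i]
      if (is.null(w)) stop("pooled aggregation needs an n_mutations column")
      sum(u * w, na.rm = TRUE) / sum(w[!is.na(u)])
    }
    data.frame(cancer_type = ty, driver_frequency = f, uv_fraction = uvf,
               label = if (f >= driver_thresh) {
                 if (uvf >= uv_thresh) "high_tertp_uv" else "high_tertp_no_uv"
               } else "low_tertp",
               low_confidence = low_conf, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Driver / secondary-site co-occurrence test
#'
#' Labels every sample driver-positive/negative and secondary-positive/
#' negative (mutation overlapping `secondary_offsets`, drivers excluded) and
#' applies the two-sided Fisher's exact test, uncorrected.
#'
#' @param cohort A `cohort_table` (subset to the cohort of interest first).
#' @param catalog A `site_catalog`.
#' @param secondary_offsets Offsets defining the secondary site group.
#' @return List with `table` (2x2: rows driver +/-, columns secondary +/-),
#'   `odds_ratio`, `p`.
#' @export
fisher_cooccurrence <- function(cohort, catalog, secondary_offsets) {
  drv <- sample_has_driver(cohort, catalog)
  sec <- sample_has_site(cohort, catalog, secondary_offsets)
  tab <- rbind(c(sum(drv & sec), sum(drv & !sec)),
               c(sum(!drv & sec), sum(!drv & !sec)))
  dimnames(tab) <- list(driver = c("pos", "neg"), secondary = c("pos", "neg"))
  res <- fisher_exact_2x2(tab)
  list(table = tab, odds_ratio = res$odds_ratio, p = res$p)
}

#' Bin samples by UV burden and correlate site frequency with burden
#'
#' Samples are binned by burden; per bin the frequency of `mutated` samples
#' is computed with an 80% normal-approximation confidence half-width
#' `z[0.9] * sqrt(p (1 - p) / n)`. Pearson's r between bin-mean burden and
#' bin frequency is tested two-sided against the t distribution with
#' `k - 2` degrees of freedom.
#'
#' The default binning is by burden quantiles (bins of roughly equal
#' occupancy), which keeps every binned frequency comparably precise;
#' equal-width binning on log10(burden + 1) is available but produces
#' sparsely occupied, high-leverage extreme bins on long-tailed burden
#' distributions, mis-calibrating the correlation test.
#'
#' @param burden Numeric per-sample UV burden.
#' @param mutated Logical per-sample site-group status (same order).
#' @param n_bins Number of bins (default 5).
#' @param edges Optional explicit bin edges (overrides `n_bins` and
#'   `method`).
#' @param method `"quantile"` (default) or `"logwidth"`.
#' @param min_bin_n Bins with fewer samples than this contribute to
#'   `per_bin` but are excluded from the correlation (a frequency from a
#'   handful of samples is not an estimate; default 10).
#' @return List with `bin_edges`, `per_bin` (n, mutated_count, frequency,
#'   ci80_half_width, mean_burden), `pearson_r`, `p_two_sided` (both `NA`
#'   with `degenerate = TRUE` when frequencies are constant), and
#'   `excluded_bins` (indices of empty or under-occupied bins left out of
#'   the correlation).
#' @export
bin_burden_correlate <- function(burden, mutated, n_bins = 5, edges = NULL,
                                 method = c("quantile", "logwidth"),
                                 min_bin_n = 10) {
  stopifnot(length(burden) == length(mutated))
  method <- match.arg(method)
  if (is.null(edges)) {
    edges <- if (method == "quantile") {
      unique(stats::quantile(burden, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE))
    } else {
      lb <- log10(burden + 1)
      10^seq(min(lb), max(lb), length.out = n_bins + 1) - 1
    }
    edges[1] <- -Inf; edges[length(edges)] <- Inf
  }
  bin <- cut(burden, breaks = edges, include.lowest = TRUE, labels = FALSE)
  k <- length(edges) - 1L
  per_bin <- do.call(rbind, lapply(seq_len(k), function(i) {
    j <- which(bin == i)
    n <- length(j)
    mc <- sum(mutated[j])
    p <- if (n) mc / n else NA_real_
    data.frame(bin = i, n = n, mutated_count = mc, frequency = p,
               ci80_half_width = if (n) stats::qnorm(0.9) * sqrt(p * (1 - p) / n) else NA_real_,
               mean_burden = if (n) mean(burden[j]) else NA_real_)
  }))
  used <- per_bin$n >= min_bin_n
  excluded_bins <- which(!used)
  x <- per_bin$mean_burden[used]; y <- per_bin$frequency[used]
  if (length(x) < 3 || stats::sd(y) == 0 || stats::sd(x) == 0) {
    r <- NA_real_; p <- NA_real_; degen <- TRUE
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value; degen <- FALSE
  }
  list(bin_edges = edges, per_bin = per_bin, pearson_r = r, p_two_sided = p,
       degenerate = degen, excluded_bins = excluded_bins)
}
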