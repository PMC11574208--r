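## Mutation spectra (SBS-96 / DBS-78), forward-selection non-negative
## signature fitting, and dipyrimidine C>T UV burden.

PYRIMIDINES <- c("C", "T")

#' The 96 single-base-substitution classes
#'
#' Pyrimidine-strand convention: six substitutions (C>A, C>G, C>T, T>A,
#' T>C, T>G) in each of 16 trinucleotide contexts, labelled `"A[C>T]G"`.
#'
#' @return Character vector of 96 class labels in canonical order.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))))
}

#' The 78 doublet-base-substitution classes
#'
#' Strand-collapsed convention: reference doublets are canonicalized to
#' \{AC, AT, CC, CG, CT, GC, TA, TC, TG, TT\} (others reverse-complemented
#' together with their alt); for reverse-complement-palindromic references
#' the alt is the lexicographic minimum of itself and its reverse
#' complement. Alts differ from the reference at both positions.
#'
#' @return Character vector of 78 labels `"CC>TT"`.
#' @export
dbs78_classes <- function() {
  bases <- c("A", "C", "G", "T")
  refs <- as.vector(outer(bases, bases, paste0))
  alts <- refs
  grid <- expand.grid(ref = refs, alt = alts, stringsAsFactors = FALSE)
  keep <- substr(grid$ref, 1, 1) != substr(grid$alt, 1, 1) &
    substr(grid$ref, 2, 2) != substr(grid$alt, 2, 2)
  grid <- grid[keep, ]
  canon <- canonical_dbs(grid$ref, grid$alt)
  sort(unique(paste0(canon$ref, ">", canon$alt)))
}

canonical_dbs <- function(ref2, alt2) {
  canon_refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  flip <- !(ref2 %in% canon_refs)
  ref2[flip] <- revcomp(ref2[flip])
  alt2[flip] <- revcomp(alt2[flip])
  pal <- ref2 %in% c("AT", "CG", "TA", "GC")
  if (any(pal)) {
    rc_alt <- revcomp(alt2[pal])
    alt2[pal] <- pmin(alt2[pal], rc_alt)
  }
  list(ref = ref2, alt = alt2)
}

#' Classify SNVs into SBS-96 classes
#'
#' Purine-reference substitutions are reverse-complemented to the pyrimidine
#' strand. Contexts whose central base disagrees with the reference allele
#' yield `NA` (the caller counts them as skipped).
#'
#' @param ref,alt Single-base alleles (plus strand).
#' @param context Plus-strand trinucleotide centred on the mutated base.
#' @return Character vector of class labels (`NA` = unresolvable).
#' @export
classify_sbs <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  out <- rep(NA_character_, n)
  ok <- !is.na(context) & nchar(context) == 3L & substr(context, 2, 2) == ref &
    ref != alt & grepl("^[ACGT]{3}$", context)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  r[pur] <- complement_base(r[pur])
  a[pur] <- complement_base(a[pur])
  ctx[pur] <- revcomp(ctx[pur])
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}

#' Classify DNVs into DBS-78 classes
#'
#' @param ref,alt Two-base alleles (plus strand). Alt must differ from ref
#'   at both positions to be a canonical doublet class; otherwise `NA`.
#' @return Character vector of class labels.
#' @export
classify_dbs <- function(ref, alt) {
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- nchar(ref) == 2L & nchar(alt) == 2L &
    substr(ref, 1, 1) != substr(alt, 1, 1) &
    substr(ref, 2, 2) != substr(alt, 2, 2)
  if (!any(ok)) return(out)
  canon <- canonical_dbs(ref[ok], alt[ok])
  out[ok] <- paste0(canon$ref, ">", canon$alt)
  out
}

#' Build SBS-96 / DBS-78 mutation spectra
#'
#' @param mutations Standardized mutation data frame; SNVs need a
#'   `ref_context` column (plus-strand trinucleotide) or a `context_fun`
#'   resolving `(contig, start)` to one.
#' @param context_fun Optional function `(contig, start) -> trinucleotide`.
#' @return List with `sbs` (named counts, 96), `dbs` (named counts, 78) and
#'   `skipped` (mutations with unresolvable context/class).
#' @export
build_spectrum <- function(mutations, context_fun = NULL) {
  m <- mutations
  snv <- m[m$span == 1L, , drop = FALSE]
  dnv <- m[m$span == 2L, , drop = FALSE]
  ctx <- if (!is.null(context_fun)) {
    context_fun(snv$contig, snv$start)
  } else if (!is.null(snv$ref_context)) snv$ref_context else {
    stop("SNV trinucleotide contexts unavailable: supply a ref_context ",
         "column or a context_fun")
  }
  sbs_lab <- classify_sbs(snv$ref, snv$alt, ctx)
  dbs_lab <- classify_dbs(dnv$ref, dnv$alt)
  sbs <- table(factor(sbs_lab, levels = sbs96_classes()))
  dbs <- table(factor(dbs_lab, levels = dbs78_classes()))
  list(sbs = stats::setNames(as.numeric(sbs), names(sbs)),
       dbs = stats::setNames(as.numeric(dbs), names(dbs)),
       skipped = sum(is.na(sbs_lab)) + sum(is.na(dbs_lab)) +
         sum(m$span > 2L))
}

#' Remove recurrent driver sites before signature analysis
#'
#' Within each cancer type, SNV sites mutated in at least `snv_min` distinct
#' samples and DNV sites in at least `dnv_min` are excluded (recurrent
#' sites are dominated by selection, not by the mutational process).
#'
#' @param mutations Standardized mutation data frame with a `cancer_type`
#'   column (or supply `cancer_type` explicitly).
#' @param cancer_type Optional vector overriding the column.
#' @param snv_min,dnv_min Distinct-sample thresholds (4 and 2).
#' @return Filtered mutation data frame.
#' @export
remove_recurrent_before_fit <- function(mutations, cancer_type = NULL,
                                        snv_min = 4, dnv_min = 2) {
  m <- mutations
  ty <- if (!is.null(cancer_type)) cancer_type else m$cancer_type
  if (is.null(ty)) stop("cancer_type required to define the per-cohort recurrence scope")
  site <- paste(ty, m$contig, m$start, m$ref, m$alt, sep = "|")
  n_samp <- tapply(m$sample_id, site, function(x) length(unique(x)))
  n_here <- as.integer(n_samp[site])
  thresh <- ifelse(m$span == 1L, snv_min, ifelse(m$span == 2L, dnv_min, Inf))
  m[n_here < thresh, , drop = FALSE]
}

## Signature matrices --------------------------------------------------------

normalize_signatures <- function(signatures, scaling = NULL) {
  sig <- as.matrix(signatures)
  if (!is.null(scaling)) {
    stopifnot(length(scaling) == nrow(sig), all(scaling > 0))
    sig <- sig * scaling
  }
  sweep(sig, 2, colSums(sig), "/")
}

#' Read a signature matrix from TSV
#'
#' First column holds class labels; remaining columns are per-signature
#' probability vectors (renormalized to sum 1).
#'
#' @param path File path.
#' @return Numeric matrix with class labels as row names.
#' @export
read_signature_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  normalize_signatures(m)
}

#' Built-in toy signature matrices
#'
#' Four synthetic SBS signatures (a CpG-deamination-like, a flat clock-like,
#' a UV-like concentrated in C>T at dipyrimidines, and a C>A oxidative-like)
#' and three DBS signatures (UV-like CC>TT, a flat one, and an
#' APOBEC-doublet-like one). Names follow the field's usual labels so the
#' UV components are `SBS7` and `DBS1`.
#'
#' @param type `"sbs"` or `"dbs"`.
#' @return Column-normalized matrix with class labels as row names.
#' @export
toy_signature_matrix <- function(type = c("sbs", "dbs")) {
  type <- match.arg(type)
  if (type == "sbs") {
    cls <- sbs96_classes()
    p5 <- substr(cls, 1, 1); p3 <- substr(cls, 7, 7)
    sub <- substr(cls, 3, 5)
    sbs1 <- ifelse(sub == "C>T" & p3 == "G", 1, 0.001)
    sbs5 <- rep(1, length(cls))
    sbs7 <- ifelse(sub == "C>T" & p5 %in% PYRIMIDINES,
                   ifelse(p5 == "T", 3, 1.5), 0.002)
    sbs18 <- ifelse(sub == "C>A", ifelse(p5 == "G", 2, 1), 0.002)
    m <- cbind(SBS1 = sbs1, SBS5 = sbs5, SBS7 = sbs7, SBS18 = sbs18)
    rownames(m) <- cls
  } else {
    cls <- dbs78_classes()
    ref <- substr(cls, 1, 2); alt <- substr(cls, 4, 5)
    dbs1 <- ifelse(ref == "CC" & alt == "TT", 1,
                   ifelse(ref %in% c("CC", "CT", "TC") & grepl("T", alt), 0.02, 0.001))
    dbs2 <- rep(1, length(cls))
    dbs11 <- ifelse(ref == "CC" & alt %in% c("AA", "AT", "TA"), 1, 0.005)
    m <- cbind(DBS1 = dbs1, DBS2 = dbs2, DBS11 = dbs11)
    rownames(m) <- cls
  }
  normalize_signatures(m)
}

## Fitting -------------------------------------------------------------------

#' Forward-selection non-negative signature fit
#'
#' Greedy forward selection on the normalized spectrum: at each step the
#' candidate signature whose joint non-negative least-squares refit most
#' reduces the residual sum of squares is added; selection stops when the
#' improvement falls below `stop_delta` or `max_k` signatures are selected.
#' Final weights are refit jointly on the selected set; weights below
#' `weight_tol` are dropped. Ties are broken by signature name order, so the
#' fit is fully deterministic.
#'
#' @param spectrum Named non-negative counts (96 or 78 classes, in the order
#'   of the signature matrix rows).
#' @param signatures Column-normalized signature matrix.
#' @param max_k Maximum number of signatures (default 5).
#' @param stop_delta Minimum SSE improvement to continue (default 1e-5 on
#'   the normalized spectrum scale, where a flat spectrum has a total
#'   sum-of-squares of about 1e-2; a genuine >= 10-20% mixture component
#'   typically improves the SSE by 1e-4 or more).
#' @param scaling Optional strictly positive per-class rescaling of the
#'   signature matrix (context-frequency adjustment) applied before
#'   column renormalization.
#' @param weight_tol Weights below this are dropped (default 1e-6).
#' @return List with `selected`, `weights`, `fractions` (weights normalized
#'   to sum 1), `residual_sse`, `fitted`.
#' @export
fit_forward_selection <- function(spectrum, signatures, max_k = 5,
                                  stop_delta = 1e-5, scaling = NULL,
                                  weight_tol = 1e-6) {
  sig <- normalize_signatures(signatures, scaling)
  sig <- sig[, order(colnames(sig)), drop = FALSE]
  stopifnot(length(spectrum) == nrow(sig))
  tot <- sum(spectrum)
  if (tot == 0) {
    return(list(selected = character(0), weights = numeric(0),
                fractions = numeric(0), residual_sse = 0,
                fitted = rep(0, length(spectrum)), empty = TRUE))
  }
  b <- as.numeric(spectrum) / tot
  sel <- character(0)
  sse_prev <- sum(b^2)
  repeat {
    cands <- setdiff(colnames(sig), sel)
    if (!length(cands) || length(sel) >= max_k) break
    sses <- vapply(cands, function(cd) {
      A <- sig[, c(sel, cd), drop = FALSE]
      fit <- pracma::lsqnonneg(A, b)
      sum((b - A %*% fit$x)^2)
    }, numeric(1))
    best <- cands[which.min(sses)]  # cands already name-ordered: ties -> first
    if (sse_prev - sses[best] < stop_delta) break
    sel <- c(sel, best)
    sse_prev <- sses[best]
  }
  if (!length(sel)) {
    # degenerate: force the single best signature so a nonzero spectrum
    # always gets an attribution
    sses <- vapply(colnames(sig), function(cd)
      sum((b - sig[, cd, drop = FALSE] %*% pracma::lsqnonneg(sig[, cd, drop = FALSE], b)$x)^2),
      numeric(1))
    sel <- colnames(sig)[which.min(sses)]
  }
  A <- sig[, sel, drop = FALSE]
  w <- pracma::lsqnonneg(A, b)$x
  names(w) <- sel
  keep <- w > weight_tol
  w <- w[keep]; sel <- sel[keep]
  A <- sig[, sel, drop = FALSE]
  fitted <- as.numeric(A %*% w)
  list(selected = sel, weights = w, fractions = w / sum(w),
       residual_sse = sum((b - fitted)^2), fitted = fitted, empty = FALSE)
}

#' UV-attributed fractions from signature fits
#'
#' @param fit_sbs,fit_dbs Fits from [fit_forward_selection()] on the SBS and
#'   DBS spectra (either may be `NULL`).
#' @param sbs_uv,dbs_uv Names of the UV signatures in the matrices.
#' @return List `sbs7_fraction`, `dbs1_fraction` (0 when unselected).
#' @export
uv_fraction <- function(fit_sbs, fit_dbs = NULL, sbs_uv = "SBS7",
                        dbs_uv = "DBS1") {
  frac_of <- function(fit, nm) {
    if (is.null(fit) || !length(fit$fractions)) return(0)
    f <- fit$fractions[startsWith(names(fit$fractions), nm)]
    if (length(f)) sum(f) else 0
  }
  list(sbs7_fraction = frac_of(fit_sbs, sbs_uv),
       dbs1_fraction = frac_of(fit_dbs, dbs_uv))
}

#' Dipyrimidine C>T UV burden
#'
#' Counts SNVs that are C>T on the pyrimidine strand with the adjacent 5'
#' or 3' base also a pyrimidine on that strand. Apply
#' [remove_recurrent_before_fit()] first when recurrent driver sites should
#' not contribute.
#'
#' @param mutations Standardized mutation data frame with SNV `ref_context`.
#' @param context_fun Optional context resolver as in [build_spectrum()].
#' @return Integer count.
#' @export
uv_burden <- function(mutations, context_fun = NULL) {
  snv <- mutations[mutations$span == 1L, , drop = FALSE]
  if (!nrow(snv)) return(0L)
  ctx <- if (!is.null(context_fun)) context_fun(snv$contig, snv$start) else snv$ref_context
  lab <- classify_sbs(snv$ref, snv$alt, ctx)
  ok <- !is.na(lab) & substr(lab, 3, 5) == "C>T"
  p5 <- substr(lab[ok], 1, 1); p3 <- substr(lab[ok], 7, 7)
  sum(p5 %in% PYRIMIDINES | p3 %in% PYRIMIDINES)
}

#' Per-sample dipyrimidine C>T burden
#'
#' Vectorized [uv_burden()] over a whole cohort's mutation table.
#'
#' @param mutations Standardized mutation data frame with `sample_id` and
#'   SNV `ref_context`.
#' @param sample_ids Samples to report (default: those present); samples
#'   without qualifying mutations get 0.
#' @return Named integer vector of burdens.
#' @export
uv_burden_by_sample <- function(mutations, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(mutations$sample_id)
  snv <- mutations[mutations$span == 1L, , drop = FALSE]
  out <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (!nrow(snv)) return(out)
  lab <- classify_sbs(snv$ref, snv$alt, snv$ref_context)
  ok <- !is.na(lab) & substr(lab, 3, 5) == "C>T" &
    (substr(lab, 1, 1) %in% PYRIMIDINES | substr(lab, 7, 7) %in% PYRIMIDINES)
  tal <- table(factor(snv$sample_id[ok], levels = sample_ids))
  out[names(tal)] <- as.integer(tal)
  out
}

#' Per-sample UV fractions for subcohort classification
#'
#' For each sample, builds the SBS/DBS spectra (after per-cohort recurrent
#' driver removal), fits signatures by forward selection, and reports the
#' UV-attributed fraction: SBS7-attributed SNVs plus DBS1-attributed DNVs
#' over all SNVs + DNVs.
#'
#' @param mutations Standardized mutation data frame with `cancer_type`.
#' @param sbs_signatures,dbs_signatures Signature matrices (defaults: toy
#'   matrices).
#' @param max_k,stop_delta Passed to [fit_forward_selection()].
#' @return Data frame `sample_id`, `uv_fraction`, `sbs7_fraction`,
#'   `dbs1_fraction`, `n_mutations`.
#' @export
sample_uv_fractions <- function(mutations,
                                sbs_signatures = toy_signature_matrix("sbs"),
                                dbs_signatures = toy_signature_matrix("dbs"),
                                max_k = 5, stop_delta = 1e-5) {
  m <- remove_recurrent_before_fit(mutations)
  ids <- unique(mutations$sample_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    mi <- m[m$sample_id == id, , drop = FALSE]
    sp <- build_spectrum(mi)
    n_snv <- sum(sp$sbs); n_dnv <- sum(sp$dbs)
    fs <- if (n_snv > 0) fit_forward_selection(sp$sbs, sbs_signatures, max_k, stop_delta) else NULL
    fd <- if (n_dnv > 0) fit_forward_selection(sp$dbs, dbs_signatures, max_k, stop_delta) else NULL
    uf <- uv_fraction(fs, fd)
    tot <- n_snv + n_dnv
    data.frame(sample_id = id,
               uv_fraction = if (tot) (uf$sbs7_fraction * n_snv + uf$dbs1_fraction * n_dnv) / tot else NA_real_,
               sbs7_fraction = uf$sbs7_fraction, dbs1_fraction = uf$dbs1_fraction,
               n_mutations = tot, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
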