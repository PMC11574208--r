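## Seeded synthetic-data generators emulating every input class of the
## analysis: a two-step MAF cohort, diploid promoter reads, UMI amplicon
## reads, and a toy genome for the paired-site scan. Each generator is a
## pure function of (config, seed) and emits a ground-truth record.

#' Configuration for the synthetic two-step cohort
#'
#' Defaults emulate a UV-exposed, highly promoter-mutated skin-cancer
#' cohort: driver prevalence 67.4% (independent of burden), log-normal UV
#' burden, and conditional secondary-hotspot probabilities linear in burden
#' (clamped at 1) that only apply when the hotspot's ETS core is occupied,
#' i.e. when the required driver is present.
#'
#' @param n_samples Samples per cancer type (vector, one per type).
#' @param cancer_type Type codes.
#' @param driver_frequency Per-type probability that a sample carries a
#'   primary driver (independent of burden).
#' @param driver_mix Named probabilities over driver events.
#' @param burden_meanlog,burden_sdlog Log-normal UV-burden parameters.
#' @param hotspot_rates Named per-offset probability of the secondary
#'   hotspot mutation per unit burden, conditional on occupancy.
#' @param background_rate Passenger SNVs per unit burden.
#' @param dnv_rate Passenger DNVs per unit burden.
#' @param uv_weight Fraction of passengers drawn from the UV channel
#'   (SBS7/DBS1-like) versus the flat channel.
#' @param onv_merge_prob Probability that a co-occurring driver + adjacent
#'   hotspot pair is reported as a single ONV record (exercises
#'   [split_onvs()]).
#' @param seed Mandatory integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 5000,
                              cancer_type = "SKCM_SYN",
                              driver_frequency = 0.674,
                              driver_mix = c(m124 = 0.45, m146 = 0.45,
                                             dnv139_138 = 0.05,
                                             dnv125_124 = 0.05),
                              burden_meanlog = log(10), burden_sdlog = 1,
                              hotspot_rates = c(`-149` = 0.0020,
                                                `-148` = 0.0004,
                                                `-126` = 0.0012,
                                                `-101` = 0.0016,
                                                `-100` = 0.0008,
                                                `-97` = 0.0001),
                              background_rate = 1, dnv_rate = 0.05,
                              uv_weight = 0.8, onv_merge_prob = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  k <- length(cancer_type)
  rec <- function(x) rep_len(x, k)
  probs <- c(driver_frequency, driver_mix, hotspot_rates, uv_weight,
             onv_merge_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_samples = rec(n_samples), cancer_type = cancer_type,
                 driver_frequency = rec(driver_frequency),
                 driver_mix = driver_mix / sum(driver_mix),
                 burden_meanlog = rec(burden_meanlog),
                 burden_sdlog = rec(burden_sdlog),
                 hotspot_rates = hotspot_rates,
                 background_rate = rec(background_rate),
                 dnv_rate = rec(dnv_rate), uv_weight = rec(uv_weight),
                 onv_merge_prob = onv_merge_prob,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# which driver events occupy the core a hotspot offset belongs to
hotspot_requirements <- list(
  `-149` = c("m146"), `-148` = c("m146"),
  `-126` = c("m124", "dnv125_124"), `-125` = c("m124", "dnv125_124"),
  `-101` = c("m124", "m146", "dnv139_138", "dnv125_124"),
  `-100` = c("m124", "m146", "dnv139_138", "dnv125_124"),
  `-97`  = c("m124", "m146", "dnv139_138", "dnv125_124"))

promoter_context <- function(catalog, offset) {
  b <- promoter_bases(catalog)
  paste0(b[as.character(offset - 1L)], b[as.character(offset)],
         b[as.character(offset + 1L)])
}

sample_sbs_mutations <- function(n, sig_col, contig = "chrB",
                                 pos_max = 5e6L) {
  cls <- sample(names(sig_col), n, replace = TRUE, prob = sig_col)
  ref <- substr(cls, 3, 3); alt <- substr(cls, 5, 5)
  ctx <- paste0(substr(cls, 1, 1), ref, substr(cls, 7, 7))
  flip <- stats::runif(n) < 0.5  # report half on the purine strand
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(contig = contig, start = sample.int(pos_max, n, replace = TRUE),
             ref = ref, alt = alt, span = 1L, ref_context = ctx,
             stringsAsFactors = FALSE)
}

sample_dbs_mutations <- function(n, sig_col, contig = "chrB",
                                 pos_max = 5e6L) {
  cls <- sample(names(sig_col), n, replace = TRUE, prob = sig_col)
  ref <- substr(cls, 1, 2); alt <- substr(cls, 4, 5)
  flip <- stats::runif(n) < 0.5
  ref[flip] <- revcomp(ref[flip]); alt[flip] <- revcomp(alt[flip])
  data.frame(contig = contig, start = sample.int(pos_max, n, replace = TRUE),
             ref = ref, alt = alt, span = 2L, ref_context = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate a two-step MAF cohort
#'
#' Per sample: a UV burden is drawn; a primary driver is present with the
#' type's frequency, independent of burden; each secondary hotspot mutation
#' is drawn only when its required ETS core is occupied (matching driver
#' present), with probability `min(1, rate x burden)`; passenger SNVs/DNVs
#' arrive at `rate x burden` with spectra drawn from the UV-like or flat
#' toy signatures.
#'
#' @param config A [cohort_sim_config()].
#' @param catalog A `site_catalog` (defaults to the bundled promoter).
#' @return List with `cohort` (a `cohort_table` whose mutations carry
#'   `ref_context`), `truth` (per-sample burden, driver, hotspots) and
#'   `config`.
#' @export
simulate_cohort <- function(config, catalog = build_reference_promoter()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  sbs_sigs <- toy_signature_matrix("sbs")
  dbs_sigs <- toy_signature_matrix("dbs")
  uv_col <- stats::setNames(sbs_sigs[, "SBS7"], rownames(sbs_sigs))
  flat_col <- stats::setNames(sbs_sigs[, "SBS5"], rownames(sbs_sigs))
  uv_dbs <- stats::setNames(dbs_sigs[, "DBS1"], rownames(dbs_sigs))
  flat_dbs <- stats::setNames(dbs_sigs[, "DBS2"], rownames(dbs_sigs))
  map <- catalog$map
  all_mut <- list(); all_samp <- list(); all_truth <- list()
  for (t in seq_along(config$cancer_type)) {
    n <- config$n_samples[t]
    ty <- config$cancer_type[t]
    ids <- sprintf("%s_S%05d", ty, seq_len(n))
    burden <- stats::rlnorm(n, config$burden_meanlog[t], config$burden_sdlog[t])
    has_driver <- stats::runif(n) < config$driver_frequency[t]
    driver <- rep(NA_character_, n)
    driver[has_driver] <- sample(names(config$driver_mix), sum(has_driver),
                                 replace = TRUE, prob = config$driver_mix)
    muts <- list()
    # driver events
    for (d in names(config$driver_mix)) {
      i <- which(driver == d)
      if (!length(i)) next
      row <- catalog$driver_set[catalog$driver_set$name == d, ]
      offs <- row$offsets[[1]]
      start_off <- min(offs)
      muts[[d]] <- data.frame(
        sample_id = ids[i], contig = map$contig,
        start = offset_to_genomic(map, start_off) -
          (if (map$gene_strand == "-") nchar(row$ref) - 1L else 0L),
        ref = if (map$gene_strand == "-") revcomp(row$ref) else row$ref,
        alt = if (map$gene_strand == "-") revcomp(row$alt) else row$alt,
        span = nchar(row$ref),
        ref_context = if (nchar(row$ref) == 1L)
          promoter_context(catalog, start_off) else NA_character_,
        stringsAsFactors = FALSE)
    }
    # conditional secondary hotspots
    hot <- matrix(FALSE, n, length(config$hotspot_rates),
                  dimnames = list(NULL, names(config$hotspot_rates)))
    for (h in names(config$hotspot_rates)) {
      req <- hotspot_requirements[[h]]
      if (is.null(req)) stop("no occupancy rule for hotspot offset ", h)
      occupied <- driver %in% req
      p <- pmin(1, config$hotspot_rates[[h]] * burden)
      hit <- occupied & stats::runif(n) < p
      hot[, h] <- hit
      i <- which(hit)
      if (!length(i)) next
      off <- as.integer(h)
      muts[[paste0("hs", h)]] <- data.frame(
        sample_id = ids[i], contig = map$contig,
        start = offset_to_genomic(map, off),
        ref = if (map$gene_strand == "-") "G" else "C",
        alt = if (map$gene_strand == "-") "A" else "T",
        span = 1L, ref_context = promoter_context(catalog, off),
        stringsAsFactors = FALSE)
    }
    # background passengers
    n_bg <- stats::rpois(n, config$background_rate[t] * burden)
    n_dnv <- stats::rpois(n, config$dnv_rate[t] * burden)
    uv_flag <- function(k, w) stats::runif(k) < w
    if (sum(n_bg)) {
      who <- rep(seq_len(n), n_bg)
      uvb <- uv_flag(sum(n_bg), config$uv_weight[t])
      bg_uv <- sample_sbs_mutations(sum(uvb), uv_col)
      bg_fl <- sample_sbs_mutations(sum(!uvb), flat_col)
      bg <- rbind(bg_uv, bg_fl)
      bg$sample_id <- ids[c(who[uvb], who[!uvb])]
      muts[["bg_snv"]] <- bg
    }
    if (sum(n_dnv)) {
      who <- rep(seq_len(n), n_dnv)
      uvb <- uv_flag(sum(n_dnv), config$uv_weight[t])
      dn <- rbind(sample_dbs_mutations(sum(uvb), uv_dbs),
                  sample_dbs_mutations(sum(!uvb), flat_dbs))
      dn$sample_id <- ids[c(who[uvb], who[!uvb])]
      muts[["bg_dnv"]] <- dn
    }
    m <- do.call(rbind, lapply(muts, function(d)
      d[, c("sample_id", "contig", "start", "ref", "alt", "span",
            "ref_context")]))
    m$cancer_type <- ty
    # optionally merge a -146 driver with a co-occurring -149/-148 hotspot
    # into one ONV record (heterogeneous complex-variant calling)
    if (config$onv_merge_prob > 0 && nrow(m)) {
      m <- merge_adjacent_to_onv(m, ids, driver, hot, catalog,
                                 config$onv_merge_prob)
    }
    all_mut[[t]] <- m
    all_samp[[t]] <- data.frame(
      sample_id = ids, patient_id = paste0("P_", ids), cancer_type = ty,
      assay_id = "SYN-PANEL-V1", capture_size_bp = 1e6, covers_tertp = TRUE,
      report_order = 1L, stringsAsFactors = FALSE)
    all_truth[[t]] <- data.frame(sample_id = ids, cancer_type = ty,
                                 burden = burden, driver = driver,
                                 stringsAsFactors = FALSE)
    all_truth[[t]] <- cbind(all_truth[[t]], as.data.frame(hot))
  }
  mutations <- do.call(rbind, all_mut)
  rownames(mutations) <- NULL
  list(cohort = cohort_table(mutations, do.call(rbind, all_samp)),
       truth = do.call(rbind, all_truth), config = config)
}

merge_adjacent_to_onv <- function(m, ids, driver, hot, catalog, prob) {
  map <- catalog$map
  cand <- which(driver == "m146" & hot[, "-149"] & stats::runif(length(ids)) < prob)
  if (!length(cand)) return(m)
  b <- promoter_bases(catalog)
  for (i in cand) {
    id <- ids[i]
    drop <- m$sample_id == id & m$contig == map$contig &
      m$start %in% c(offset_to_genomic(map, -146L), offset_to_genomic(map, -149L))
    m <- m[!drop, , drop = FALSE]
    ref_rs <- paste(b[as.character(-149:-146)], collapse = "")
    alt_rs <- ref_rs
    substr(alt_rs, 1, 1) <- "T"; substr(alt_rs, 4, 4) <- "T"
    g <- offset_to_genomic(map, -149L)
    onv <- data.frame(sample_id = id, contig = map$contig,
                      start = if (map$gene_strand == "-") g - 3L else g,
                      ref = if (map$gene_strand == "-") revcomp(ref_rs) else ref_rs,
                      alt = if (map$gene_strand == "-") revcomp(alt_rs) else alt_rs,
                      span = 4L, ref_context = NA_character_,
                      cancer_type = m$cancer_type[1],
                      stringsAsFactors = FALSE)
    m <- rbind(m, onv)
  }
  m
}

#' Configuration for diploid promoter-read simulation
#'
#' @param depth Number of reads.
#' @param read_length Read length (bp).
#' @param base_error_rate Per-base substitution error probability.
#' @param driver Driver event name (from the catalogue driver set).
#' @param secondary_offsets Offsets of planted secondary variants (C>T).
#' @param cis_fraction Probability that, in the cell a read derives from,
#'   the secondary variants sit on the driver haplotype.
#' @param seed Mandatory integer seed.
#' @return List of class `read_sim_config`.
#' @export
read_sim_config <- function(depth = 1000, read_length = 150,
                            base_error_rate = 1e-3, driver = "m146",
                            secondary_offsets = -101L, cis_fraction = 0.95,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(cis_fraction >= 0, cis_fraction <= 1)
  structure(list(depth = depth, read_length = read_length,
                 base_error_rate = base_error_rate, driver = driver,
                 secondary_offsets = as.integer(secondary_offsets),
                 cis_fraction = cis_fraction, seed = as.integer(seed)),
            class = "read_sim_config")
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(rl[i], n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

#' Simulate diploid promoter reads in SAM form
#'
#' A diploid locus over the catalogue window: the driver sits on one
#' homolog; in each cell the secondary variants sit on the driver haplotype
#' with probability `cis_fraction` (else on the other homolog). Reads
#' sample a homolog 50/50 and a uniform start, with substitution errors.
#'
#' @param config A [read_sim_config()].
#' @param catalog A `site_catalog`.
#' @return List with `sam` (data frame as from [read_sam()]), `reference`
#'   (contig sequence), `contig`, `targets` (genomic positions of the
#'   catalogued positions of interest, driver first), `truth` (per-read
#'   homolog and cis indicator) and `config`.
#' @export
simulate_promoter_reads <- function(config,
                                    catalog = build_reference_promoter()) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed)
  map <- catalog$map
  stopifnot(map$gene_strand == "+")  # synthetic locus layout
  L <- nchar(catalog$wt_sequence)
  rl <- config$read_length
  if (rl > L) stop("read_length exceeds the locus length")
  drow <- catalog$driver_set[catalog$driver_set$name == config$driver, ]
  if (!nrow(drow)) stop("unknown driver: ", config$driver)
  drv_seq <- apply_mutation(catalog, drow$offsets[[1]],
                            strsplit(drow$alt, "")[[1]])
  wt <- catalog$wt_sequence
  sec <- config$secondary_offsets
  with_sec <- function(s) if (length(sec)) apply_mutation(catalog, sec, "T", seq = s) else s
  hap <- c(wt = wt, wt_sec = with_sec(wt), drv = drv_seq,
           drv_sec = with_sec(drv_seq))
  n <- config$depth
  is_drv <- stats::runif(n) < 0.5
  cis_cell <- stats::runif(n) < config$cis_fraction
  which_hap <- ifelse(is_drv, ifelse(cis_cell, "drv_sec", "drv"),
                      ifelse(cis_cell, "wt", "wt_sec"))
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  seqs <- substr(hap[which_hap], starts, starts + rl - 1L)
  seqs <- add_read_errors(seqs, config$base_error_rate)
  sam <- data.frame(qname = sprintf("r%06d", seq_len(n)), flag = 0L,
                    rname = map$contig, pos = starts, mapq = 60L,
                    cigar = paste0(rl, "M"), seq = seqs,
                    qual = strrep("?", rl), stringsAsFactors = FALSE)
  driver_target <- offset_to_genomic(map, min(drow$offsets[[1]]))
  poi <- sort(unique(c(min(drow$offsets[[1]]), sec,
                       catalog$sites$offset[catalog$sites$role %in%
                         c("secondary_hotspot", "central_hotspot")])))
  targets <- offset_to_genomic(map, poi)
  if (rl < diff(range(targets)) + 1L) {
    warning("read_length shorter than the target span; no reads will cover ",
            "all positions of interest")
  }
  list(sam = sam, reference = wt, contig = map$contig,
       driver_target = driver_target, targets = targets,
       truth = data.frame(read_id = sam$qname, homolog = ifelse(is_drv, "driver", "wt"),
                          cis_cell = cis_cell, start = starts,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Write alignments as a text SAM file
#'
#' @param sam Data frame as from [read_sam()].
#' @param path Output path.
#' @param contig Reference name for the header.
#' @param contig_length Reference length for the header.
#' @export
write_sam <- function(sam, path, contig, contig_length) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_length))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                 sam$cigar, sam$seq, sam$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Configuration for UMI amplicon-read simulation
#'
#' @param n_molecules Number of template molecules.
#' @param driver Driver event name (heterozygous; ~50% of molecules carry
#'   it).
#' @param subclones Data frame `offset`, `alt`, `cell_fraction`,
#'   `haplotype` (`"driver"` or `"wt"`).
#' @param family_mu,family_size Shifted negative-binomial amplification
#'   model: family size = 1 + NB(size = `family_size`, mu = `family_mu`).
#' @param family_fixed Optional constant family size overriding the
#'   negative-binomial model (e.g. 2 to make every family sub-threshold).
#' @param read_error_rate Per-base substitution error in reads.
#' @param umi_error_rate Per-base substitution error in the UMI tag
#'   (default 0; hairpin-protected tags).
#' @param indel_rate Fraction of molecules carrying a 1-bp deletion in the
#'   window.
#' @param umi_length UMI length.
#' @param window Offsets `c(lo, hi)` of the amplicon target window.
#' @param primer_length Bases of locus-specific primer immediately 5' of
#'   the window.
#' @param seed Mandatory integer seed.
#' @return List of class `umi_sim_config`.
#' @export
umi_sim_config <- function(n_molecules = 10000, driver = "m146",
                           subclones = data.frame(offset = -149L, alt = "T",
                                                  cell_fraction = 0.01,
                                                  haplotype = "driver"),
                           family_mu = 5, family_size = 2,
                           family_fixed = NULL,
                           read_error_rate = 1e-3, umi_error_rate = 0,
                           indel_rate = 0, umi_length = 12,
                           window = c(-160L, -81L), primer_length = 18,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(subclones$cell_fraction >= 0 & subclones$cell_fraction <= 1),
            all(subclones$haplotype %in% c("driver", "wt")))
  structure(list(n_molecules = n_molecules, driver = driver,
                 subclones = subclones, family_mu = family_mu,
                 family_size = family_size, family_fixed = family_fixed,
                 read_error_rate = read_error_rate,
                 umi_error_rate = umi_error_rate, indel_rate = indel_rate,
                 umi_length = as.integer(umi_length),
                 window = as.integer(window),
                 primer_length = as.integer(primer_length),
                 seed = as.integer(seed)),
            class = "umi_sim_config")
}

int_to_umi <- function(i, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(i))
  x <- i - 1
  chars <- matrix("", length(i), len)
  for (p in seq_len(len)) {
    chars[, p] <- bases[x %% 4 + 1]
    x <- x %/% 4
  }
  apply(chars, 1, paste, collapse = "")
}

#' Simulate UMI-tagged amplicon reads
#'
#' Molecules come from a cell population heterozygous for the driver
#' (about half the molecules carry it); each configured subclonal mutation
#' is placed on molecules of its haplotype with its cell fraction. Each
#' molecule is amplified into a UMI family with a shifted negative-binomial
#' size and per-read substitution errors; a configurable fraction of
#' molecules carries a 1-bp deletion.
#'
#' @param config A [umi_sim_config()].
#' @param catalog A `site_catalog`.
#' @return List with `reads` (data frame `read_id`, `umi`, `bases`,
#'   `quals`, directly consumable by [anchor_reads()] after the UMI is
#'   already split off), `primer`, `window_offsets`, `ref_window`,
#'   `truth` (per-molecule record) and `config`.
#' @export
simulate_umi_reads <- function(config, catalog = build_reference_promoter()) {
  stopifnot(inherits(config, "umi_sim_config"))
  set.seed(config$seed)
  b <- promoter_bases(catalog)
  win_off <- seq(config$window[1], config$window[2])
  ref_window <- paste(b[as.character(win_off)], collapse = "")
  primer_off <- seq(config$window[1] - config$primer_length, config$window[1] - 1L)
  primer <- paste(b[as.character(primer_off)], collapse = "")
  drow <- catalog$driver_set[catalog$driver_set$name == config$driver, ]
  if (!nrow(drow)) stop("unknown driver: ", config$driver)
  doffs <- drow$offsets[[1]]
  put_window <- function(s, offs, alts) {
    idx <- match(offs, win_off)
    stopifnot(!anyNA(idx))
    v <- strsplit(s, "")[[1]]; v[idx] <- alts; paste(v, collapse = "")
  }
  drv_window <- put_window(ref_window, doffs, strsplit(drow$alt, "")[[1]])

  n <- config$n_molecules
  hap <- ifelse(stats::runif(n) < 0.5, "driver", "wt")
  mol_seq <- ifelse(hap == "driver", drv_window, ref_window)
  sub_flags <- matrix(FALSE, n, nrow(config$subclones))
  for (s in seq_len(nrow(config$subclones))) {
    sc <- config$subclones[s, ]
    carry <- hap == sc$haplotype & stats::runif(n) < sc$cell_fraction
    sub_flags[, s] <- carry
    for (i in which(carry)) {
      mol_seq[i] <- put_window(mol_seq[i], sc$offset, sc$alt)
    }
  }
  has_indel <- stats::runif(n) < config$indel_rate
  for (i in which(has_indel)) {
    p <- sample.int(nchar(mol_seq[i]), 1)
    mol_seq[i] <- paste0(substr(mol_seq[i], 1, p - 1),
                         substr(mol_seq[i], p + 1, nchar(mol_seq[i])))
  }
  umis <- int_to_umi(sample.int(4^config$umi_length, n),
                     config$umi_length)
  fam <- if (!is.null(config$family_fixed)) {
    rep(as.integer(config$family_fixed), n)
  } else {
    1L + stats::rnbinom(n, size = config$family_size, mu = config$family_mu)
  }
  who <- rep(seq_len(n), fam)
  payload <- paste0(primer, mol_seq[who])
  payload <- add_read_errors(payload, config$read_error_rate)
  umi_part <- umis[who]
  if (config$umi_error_rate > 0) {
    umi_part <- add_read_errors(umi_part, config$umi_error_rate)
  }
  reads <- data.frame(read_id = sprintf("m%06d_r%02d", who,
                                        unlist(lapply(fam, seq_len))),
                      umi = umi_part, bases = payload,
                      quals = strrep("I", nchar(payload)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(molecule = seq_len(n), umi = umis, haplotype = hap,
                      family_size = fam, has_indel = has_indel,
                      stringsAsFactors = FALSE)
  if (nrow(config$subclones)) {
    colnames(sub_flags) <- paste0("sub_", config$subclones$offset)
    truth <- cbind(truth, as.data.frame(sub_flags))
  }
  list(reads = reads, primer = primer, window_offsets = win_off,
       ref_window = ref_window, driver_offset = min(doffs), truth = truth,
       config = config)
}

#' Write UMI reads as FASTQ
#'
#' The UMI is prepended to the read sequence, matching the layout
#' [read_umi_fastq()] expects.
#'
#' @param reads Read data frame from [simulate_umi_reads()].
#' @param path Output path.
#' @export
write_umi_fastq <- function(reads, path) {
  seqs <- paste0(reads$umi, reads$bases)
  quals <- paste0(strrep("I", nchar(reads$umi)), reads$quals)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- reads$read_id
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Configuration for the paired-site toy world
#'
#' @param n_contigs,contig_length Genome shape.
#' @param gene_spacing Distance between consecutive coding starts.
#' @param n_bound Genes receiving a planted "bound" pair: helical-phase
#'   spacing (~10.5 bp multiples), a covering ChIP peak, and elevated
#'   mutation load at the hotspot (NN) positions.
#' @param n_unbound Genes receiving an unbound pair at uniform spacing, no
#'   peak, background mutation load only.
#' @param bound_spacings Spacings sampled for bound pairs.
#' @param n_donors,n_background_mutations Background mutation model.
#' @param bound_site_mut_lambda Poisson mean of per-site mutation count at
#'   bound-pair hotspot positions.
#' @param n_experiments ChIP experiments (cell line x replicate).
#' @param seed Mandatory integer seed.
#' @return List of class `pairscan_sim_config`.
#' @export
pairscan_sim_config <- function(n_contigs = 2, contig_length = 120000,
                                gene_spacing = 2000, n_bound = 50,
                                n_unbound = 50,
                                bound_spacings = round(10.5 * (2:8)),
                                n_donors = 50,
                                n_background_mutations = 1000,
                                bound_site_mut_lambda = 3,
                                n_experiments = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "pairscan_sim_config")
}

#' Simulate a toy genome with paired ETS sites, mutations and ChIP peaks
#'
#' @param config A [pairscan_sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes` (data
#'   frame), `mutations` (data frame `donor`, `contig`, `start`, `ref`,
#'   `alt`, `span`), `peaks` (named list of `GRanges` per experiment) and
#'   `truth` (planted pair table with `bound` flag).
#' @export
simulate_pairscan_world <- function(config) {
  stopifnot(inherits(config, "pairscan_sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  genome_chr <- lapply(seq_len(config$n_contigs), function(i)
    sample(bases, config$contig_length, replace = TRUE,
           prob = c(0.22, 0.28, 0.28, 0.22)))
  names(genome_chr) <- paste0("chr", seq_len(config$n_contigs))
  starts <- seq(2000, config$contig_length - 2000, by = config$gene_spacing)
  genes <- do.call(rbind, lapply(names(genome_chr), function(ctg)
    data.frame(gene_id = paste0(ctg, "_g", seq_along(starts)), contig = ctg,
               strand = rep(c("+", "-"), length.out = length(starts)),
               coding_start = starts, stringsAsFactors = FALSE)))
  n_plant <- config$n_bound + config$n_unbound
  if (n_plant > nrow(genes)) stop("not enough genes to plant pairs into")
  plant_idx <- sample.int(nrow(genes), n_plant)
  bound <- c(rep(TRUE, config$n_bound), rep(FALSE, config$n_unbound))
  motif <- strsplit("CCTTCCG", "")[[1]]
  planted <- list()
  for (k in seq_len(n_plant)) {
    g <- genes[plant_idx[k], ]
    reg_start <- if (g$strand == "+") g$coding_start - 1000L else g$coding_start + 1L
    a <- reg_start + sample.int(400, 1) + 50L
    d <- if (bound[k]) sample(config$bound_spacings, 1) else sample(7:100, 1)
    for (s in c(a, a + d)) {
      genome_chr[[g$contig]][s:(s + 6L)] <- motif
    }
    planted[[k]] <- data.frame(contig = g$contig, start_a = a,
                               start_b = a + d, distance = d,
                               bound = bound[k], stringsAsFactors = FALSE)
  }
  truth <- if (length(planted)) do.call(rbind, planted) else
    data.frame(contig = character(0), start_a = integer(0),
               start_b = integer(0), distance = integer(0),
               bound = logical(0))
  # mutations: elevated at hotspot (NN) positions of bound sites
  mut <- list()
  bsites <- truth[truth$bound, , drop = FALSE]
  for (i in seq_len(nrow(bsites))) {
    for (s in c(bsites$start_a[i], bsites$start_b[i])) {
      n_m <- stats::rpois(1, config$bound_site_mut_lambda)
      if (!n_m) next
      donors <- sample.int(config$n_donors, min(n_m, config$n_donors))
      pos <- s + sample(0:1, length(donors), replace = TRUE)  # NN prefix
      mut[[length(mut) + 1L]] <- data.frame(
        donor = paste0("D", donors), contig = bsites$contig[i], start = pos,
        ref = "C", alt = "T", span = 1L, stringsAsFactors = FALSE)
    }
  }
  n_bg <- config$n_background_mutations
  if (n_bg) {
    ctg <- sample(names(genome_chr), n_bg, replace = TRUE)
    pos <- sample.int(config$contig_length, n_bg, replace = TRUE)
    ref <- mapply(function(c1, p) genome_chr[[c1]][p], ctg, pos)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    mut[[length(mut) + 1L]] <- data.frame(
      donor = paste0("D", sample.int(config$n_donors, n_bg, replace = TRUE)),
      contig = ctg, start = pos, ref = unname(ref), alt = unname(alt),
      span = 1L, stringsAsFactors = FALSE)
  }
  mutations <- if (length(mut)) do.call(rbind, mut) else
    data.frame(donor = character(0), contig = character(0),
               start = integer(0), ref = character(0), alt = character(0),
               span = integer(0))
  rownames(mutations) <- NULL
  # ChIP peaks: one covering peak per bound pair per experiment + decoys
  peaks <- lapply(seq_len(config$n_experiments), function(e) {
    pk_b <- GenomicRanges::GRanges(
      bsites$contig,
      IRanges::IRanges(bsites$start_a - 20L, bsites$start_b + 26L))
    pk_b$signalValue <- stats::runif(length(pk_b), 80, 100)
    n_decoy <- 4L * nrow(bsites)
    pk_d <- GenomicRanges::GRanges(
      sample(names(genome_chr), n_decoy, replace = TRUE),
      IRanges::IRanges(start = sample.int(config$contig_length - 300L, n_decoy),
                       width = 200L))
    pk_d$signalValue <- stats::runif(n_decoy, 1, 40)
    c(pk_b, pk_d)
  })
  names(peaks) <- paste0("synthetic_chip_rep", seq_along(peaks))
  genome <- Biostrings::DNAStringSet(vapply(genome_chr, paste,
                                            character(1), collapse = ""))
  list(genome = genome, genes = genes, mutations = mutations, peaks = peaks,
       truth = truth, config = config)
}

#' Write the paired-site world to standard-format files
#'
#' FASTA genome, gene-model TSV, mutation MAF-style TSV and one broadPeak
#' file per experiment.
#'
#' @param world From [simulate_pairscan_world()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_pairscan_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(world$genome, fa)
  genes <- file.path(dir, "genes.tsv")
  utils::write.table(world$genes, genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  muts <- file.path(dir, "mutations.tsv")
  utils::write.table(world$mutations, muts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pk_paths <- vapply(names(world$peaks), function(nm) {
    p <- file.path(dir, paste0(nm, ".broadPeak"))
    gr <- world$peaks[[nm]]
    utils::write.table(
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = BiocGenerics::start(gr) - 1L,
                 end = BiocGenerics::end(gr), name = ".", score = 0,
                 strand = ".", signalValue = gr$signalValue, pValue = -1,
                 qValue = -1),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  list(genome = fa, genes = genes, mutations = muts, peaks = pk_paths)
}
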