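test_that("cohort filters apply in order with logged removals and are idempotent", {
  ch <- toy_cohort()
  f <- filter_cohort(ch, CATALOG, min_samples_per_type = 2,
                     min_mutations_per_type = 1)
  # S6: small-capture assay; S1: second sample of P1 (higher report_order);
  # BBB then has no samples left
  expect_setequal(f$samples$sample_id, c("S2", "S3", "S4", "S5"))
  expect_identical(nrow(f$filters_applied), 4L)
  expect_true(all(f$filters_applied$samples_removed >= 0))
  f2 <- filter_cohort(f, CATALOG, min_samples_per_type = 2,
                      min_mutations_per_type = 1)
  expect_identical(f2$samples$sample_id, f$samples$sample_id)
  expect_identical(f2$mutations, f$mutations)
})

test_that("cancer types below size or driver-frequency floors are dropped", {
  set.seed(42)
  g124 <- offset_to_genomic(SYN_MAP, -124L)
  mk_type <- function(ty, n, n_driver) {
    samples <- data.frame(sample_id = sprintf("%s_%03d", ty, 1:n),
                          patient_id = sprintf("%sP%03d", ty, 1:n),
                          cancer_type = ty, assay_id = "A",
                          capture_size_bp = 5e5, covers_tertp = TRUE,
                          report_order = 1L, stringsAsFactors = FALSE)
    # background mutations so the mutation-count floor passes
    muts <- data.frame(sample_id = rep(samples$sample_id, each = 15),
                       contig = "chrB",
                       start = sample.int(1e6, 15 * n), ref = "C", alt = "T",
                       span = 1L, ref_context = "TCA",
                       stringsAsFactors = FALSE)
    if (n_driver > 0) {
      muts <- rbind(muts, data.frame(sample_id = samples$sample_id[1:n_driver],
                                     contig = SYN_MAP$contig, start = g124,
                                     ref = "C", alt = "T", span = 1L,
                                     ref_context = "CCT"))
    }
    list(samples = samples, muts = muts)
  }
  big_ok <- mk_type("OK", 50, 10)       # 20% drivers
  small <- mk_type("SMALL", 39, 10)     # below 40-sample floor
  lowdrv <- mk_type("LOWDRV", 111, 1)   # 0.9% driver frequency
  ch <- cohort_table(rbind(big_ok$muts, small$muts, lowdrv$muts),
                     rbind(big_ok$samples, small$samples, lowdrv$samples))
  f <- filter_cohort(ch, CATALOG)
  expect_setequal(unique(f$samples$cancer_type), "OK")
})

test_that("ONV splitting decomposes only changed bases and conserves them", {
  m <- data.frame(sample_id = c("a", "a", "b"),
                  contig = "chrB", start = c(100L, 200L, 300L),
                  ref = c("CCC", "CC", "CCT"), alt = c("TTT", "TT", "TTT"),
                  span = c(3L, 2L, 3L), stringsAsFactors = FALSE)
  out <- split_onvs(m)
  expect_identical(sum(out$span == 1L), 5L)          # 3 from CCC>TTT, 2 from CCT>TTT
  expect_identical(sum(out$span == 2L), 1L)          # DNV untouched
  cct <- out[out$start %in% 300:302, ]
  expect_setequal(cct$start, c(300L, 301L))          # middle T unchanged
  # conservation of the single-base change multiset
  expand <- function(d) {
    unlist(lapply(seq_len(nrow(d)), function(i) {
      r <- strsplit(d$ref[i], "")[[1]]; a <- strsplit(d$alt[i], "")[[1]]
      at <- which(r != a)
      paste(d$sample_id[i], d$start[i] + at - 1L, r[at], a[at])
    }))
  }
  expect_setequal(expand(out), expand(m))
  expect_warning(split_onvs(rbind(m, data.frame(sample_id = "c", contig = "chrB",
                                                start = 1L, ref = "CCC",
                                                alt = "CCC", span = 3L))),
                 "dropped")
})

test_that("recurrence calling uses distinct samples and the site window", {
  g149 <- offset_to_genomic(SYN_MAP, -149L)
  mk <- function(ids) {
    samples <- data.frame(sample_id = unique(ids), patient_id = unique(ids),
                          cancer_type = "T", stringsAsFactors = FALSE)
    muts <- data.frame(sample_id = ids, contig = SYN_MAP$contig, start = g149,
                       ref = "C", alt = "T", span = 1L, stringsAsFactors = FALSE)
    cohort_table(muts, samples)
  }
  r10 <- call_recurrent_sites(mk(sprintf("S%02d", 1:10)), CATALOG)
  expect_true(r10$recurrent[r10$offset == -149])
  r9 <- call_recurrent_sites(mk(sprintf("S%02d", 1:9)), CATALOG)
  expect_false(r9$recurrent[r9$offset == -149])
  # ten records from one sample count once
  rdup <- call_recurrent_sites(mk(rep("S01", 10)), CATALOG)
  expect_identical(rdup$n_samples[rdup$offset == -149], 1L)
  expect_false(rdup$recurrent[rdup$offset == -149])
})

test_that("subcohort labels follow the 20% / 10% thresholds", {
  mk <- function(driver_freq, uvf) {
    n <- 100
    nd <- round(driver_freq * n)
    samples <- data.frame(sample_id = sprintf("S%03d", 1:n),
                          patient_id = sprintf("P%03d", 1:n),
                          cancer_type = "X", stringsAsFactors = FALSE)
    muts <- data.frame(sample_id = samples$sample_id[seq_len(nd)],
                       contig = SYN_MAP$contig,
                       start = offset_to_genomic(SYN_MAP, -124L),
                       ref = "C", alt = "T", span = 1L, stringsAsFactors = FALSE)
    ch <- cohort_table(muts, samples)
    uv <- data.frame(sample_id = samples$sample_id, uv_fraction = uvf)
    classify_subcohorts(ch, CATALOG, uv)$label
  }
  expect_identical(mk(0.25, 0.40), "high_tertp_uv")
  expect_identical(mk(0.25, 0.02), "high_tertp_no_uv")
  expect_identical(mk(0.19, 0.40), "low_tertp")
  expect_identical(mk(0.20, 0.10), "high_tertp_uv")  # boundaries inclusive
})

test_that("missing signature data yields a low-confidence but classified type", {
  ch <- toy_cohort()
  uv <- data.frame(sample_id = character(0), uv_fraction = numeric(0))
  lab <- classify_subcohorts(ch, CATALOG, uv)
  expect_true(all(lab$low_confidence))
  expect_true(all(lab$label %in% c("high_tertp_uv", "high_tertp_no_uv", "low_tertp")))
})

test_that("two-sided Fisher equals enumeration, is transposition-invariant, handles empty margins", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(1, 5, 20), 1)), 2)
    got <- fisher_exact_2x2(tab)
    expect_equal(got$p, oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    expect_equal(got$p, fisher_exact_2x2(t(tab))$p, tolerance = 1e-12)
    expect_equal(got$p, fisher_exact_2x2(tab[2:1, 2:1])$p, tolerance = 1e-12)
    expect_equal(got$p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_identical(fisher_exact_2x2(rbind(c(0, 10), c(0, 10)))$p, 1)
  expect_true(is.na(fisher_exact_2x2(rbind(c(0, 10), c(0, 10)))$odds_ratio))
  expect_identical(fisher_exact_2x2(rbind(c(5, 0), c(3, 0)))$p, 1)
})

test_that("driver/secondary co-occurrence builds the expected 2x2 table", {
  set.seed(3)
  sim <- simulate_cohort(cohort_sim_config(n_samples = 800, seed = 31))
  res <- fisher_cooccurrence(sim$cohort, CATALOG, c(-101, -100, -97))
  expect_identical(sum(res$table), nrow(sim$cohort$samples))
  # generator truth: native hotspots only arise in driver-positive samples
  truth_native <- sim$truth$`-101` | sim$truth$`-100` | sim$truth$`-97`
  expect_identical(res$table[1, 1] + res$table[2, 1],
                   sum(sample_has_site(sim$cohort, CATALOG, c(-101, -100, -97))))
  expect_gte(res$table[1, 1], sum(truth_native))  # background can only add
  expect_lt(res$p, 0.05)
})

test_that("burden binning: exact linearity, CI closed form, degenerate input", {
  # frequency exactly proportional to burden: r = 1
  burden <- rep(c(1, 2, 4, 8, 16), each = 2000)
  set.seed(1)
  mutated <- rbinom(length(burden), 1, burden / 40) == 1
  edges <- c(-Inf, 1.5, 3, 6, 12, Inf)
  res <- bin_burden_correlate(burden, mutated, edges = edges)
  expect_gt(res$pearson_r, 0.98)
  expect_lt(res$p_two_sided, 0.05)
  expect_identical(sum(res$per_bin$n), length(burden))
  # 80% CI half-width at p = 0.5, n = 100
  b2 <- bin_burden_correlate(c(rep(1, 100), rep(10, 100)),
                             c(rep(c(TRUE, FALSE), 50), rep(TRUE, 100)),
                             edges = c(-Inf, 5, Inf))
  expect_equal(b2$per_bin$ci80_half_width[1], qnorm(0.9) * sqrt(0.25 / 100),
               tolerance = 1e-12)
  expect_equal(b2$per_bin$ci80_half_width[1], 0.0641, tolerance = 1e-3)
  # constant frequency: flagged, not reported as r = 0
  cst <- bin_burden_correlate(runif(100, 1, 100), rep(TRUE, 100), n_bins = 5)
  expect_true(cst$degenerate)
  expect_true(is.na(cst$pearson_r))
})

test_that("frequency independent of burden gives non-significant r in most seeded runs", {
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    burden <- rlnorm(5000, log(10), 1)
    mutated <- runif(5000) < 0.05
    res <- bin_burden_correlate(burden, mutated)
    if (is.na(res$p_two_sided) || res$p_two_sided > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90% of runs
})

test_that("MAF and metadata round-trip through files", {
  sim <- simulate_cohort(cohort_sim_config(n_samples = 30, seed = 99))
  maf <- tempfile(fileext = ".maf")
  write_maf(sim$cohort$mutations, maf)
  back <- read_maf(maf)
  expect_identical(nrow(back), nrow(sim$cohort$mutations))
  expect_identical(back$start, sim$cohort$mutations$start)
  expect_identical(back$ref, sim$cohort$mutations$ref)
  bad <- tempfile()
  writeLines("Chromosome\tStart_Position\n1\t2", bad)
  expect_error(read_maf(bad), "missing columns")
})
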