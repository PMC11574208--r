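test_that("generators are pure functions of (config, seed)", {
  a <- simulate_cohort(cohort_sim_config(n_samples = 200, seed = 55))
  b <- simulate_cohort(cohort_sim_config(n_samples = 200, seed = 55))
  expect_identical(a$cohort$mutations, b$cohort$mutations)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(cohort_sim_config(n_samples = 200, seed = 56))
  expect_false(identical(a$cohort$mutations, c_$cohort$mutations))
  w1 <- simulate_pairscan_world(pairscan_sim_config(seed = 2, n_bound = 5,
                                                    n_unbound = 5,
                                                    n_background_mutations = 20))
  w2 <- simulate_pairscan_world(pairscan_sim_config(seed = 2, n_bound = 5,
                                                    n_unbound = 5,
                                                    n_background_mutations = 20))
  expect_identical(as.character(w1$genome), as.character(w2$genome))
  expect_identical(w1$mutations, w2$mutations)
})

test_that("seed is mandatory and invalid probabilities are rejected at load", {
  expect_error(cohort_sim_config(), "seed")
  expect_error(read_sim_config(), "seed")
  expect_error(umi_sim_config(), "seed")
  expect_error(pairscan_sim_config(), "seed")
  expect_error(cohort_sim_config(driver_frequency = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(read_sim_config(cis_fraction = -0.1, seed = 1))
  expect_error(umi_sim_config(subclones = data.frame(offset = -101L, alt = "T",
                                                     cell_fraction = 2,
                                                     haplotype = "driver"),
                              seed = 1))
})

test_that("zero hotspot rates produce no atypical promoter mutations", {
  cfg <- cohort_sim_config(n_samples = 400,
                           hotspot_rates = c(`-149` = 0, `-148` = 0,
                                             `-126` = 0, `-101` = 0,
                                             `-100` = 0, `-97` = 0),
                           seed = 77)
  sim <- simulate_cohort(cfg)
  atyp <- sample_has_site(sim$cohort, CATALOG,
                          c(-149, -148, -126, -101, -100, -97))
  expect_false(any(atyp))
})

test_that("negligible burden leaves only driver mutations", {
  cfg <- cohort_sim_config(n_samples = 400, burden_meanlog = -30,
                           burden_sdlog = 0.01, seed = 78)
  sim <- simulate_cohort(cfg)
  ann <- annotate_promoter(sim$cohort$mutations, CATALOG)
  expect_true(all(!is.na(ann$offset)))   # nothing off-promoter
  drv_keys <- paste0(c(-124, -146, -139, -125), ":",
                     c("C", "C", "CC", "CC"), ">", c("T", "T", "TT", "TT"))
  expect_true(all(ann$site_key %in% drv_keys))
})

test_that("secondary hotspots appear only alongside their required driver", {
  sim <- simulate_cohort(cohort_sim_config(n_samples = 2000, seed = 79))
  tr <- sim$truth
  expect_true(all(tr$driver[tr$`-149`] == "m146"))
  expect_true(all(tr$driver[tr$`-126`] %in% c("m124", "dnv125_124")))
  expect_true(all(!is.na(tr$driver[tr$`-101` | tr$`-100` | tr$`-97`])))
})

test_that("the two-step cohort rejects driver/native-site independence across seeds", {
  reject <- 0
  for (s in 1:10) {
    sim <- simulate_cohort(cohort_sim_config(n_samples = 2500, seed = 300 + s))
    p <- fisher_cooccurrence(sim$cohort, CATALOG, c(-101, -100, -97))$p
    if (p < 0.01) reject <- reject + 1
  }
  expect_gte(reject, 9)
})

test_that("ONV merging produces records that split back to driver + hotspot", {
  cfg <- cohort_sim_config(n_samples = 1500, onv_merge_prob = 1, seed = 80)
  sim <- simulate_cohort(cfg)
  onv <- sim$cohort$mutations[sim$cohort$mutations$span == 4L, ]
  expect_gt(nrow(onv), 0)
  back <- split_onvs(sim$cohort$mutations)
  ann <- annotate_promoter(back, CATALOG)
  merged_ids <- onv$sample_id
  for (id in merged_ids) {
    offs <- ann$offset[ann$sample_id == id & !is.na(ann$offset)]
    expect_true(all(c(-149L, -146L) %in% offs))
  }
})

test_that("promoter-read simulation encodes haplotypes faithfully at error 0", {
  sim <- simulate_promoter_reads(
    read_sim_config(depth = 300, base_error_rate = 0, cis_fraction = 0.5,
                    seed = 90), CATALOG)
  # every read matches its haplotype sequence exactly
  cov <- select_covering_reads(sim$sam, sim$targets)
  calls <- call_read_alleles(cov, sim$targets, sim$reference)
  truth <- sim$truth[match(cov$qname, sim$truth$read_id), ]
  drv_col <- as.character(sim$driver_target)
  expect_identical(unname(calls[, drv_col] != "ref"), truth$homolog == "driver")
  # recovered cis fraction within the exact binomial CI
  pt <- build_phase_table(calls, sim$driver_target)
  est <- estimate_cis_fraction(pt, offset_to_genomic(SYN_MAP, -101L))
  expect_gte(0.5, est$ci[1])
  expect_lte(0.5, est$ci[2])
})

test_that("short reads trigger the no-coverage warning", {
  expect_warning(
    simulate_promoter_reads(read_sim_config(depth = 10, read_length = 40,
                                            seed = 91), CATALOG),
    "cover")
})

test_that("UMI simulation with no subclones and no errors gives a clean driver split", {
  sim <- simulate_umi_reads(
    umi_sim_config(n_molecules = 1200, read_error_rate = 0,
                   subclones = data.frame(offset = integer(0),
                                          alt = character(0),
                                          cell_fraction = numeric(0),
                                          haplotype = character(0)),
                   seed = 92), CATALOG)
  a <- anchor_reads(sim$reads, sim$primer, nchar(sim$ref_window))
  cons <- filter_indel_consensus(call_consensus(group_families(a)))
  sc <- call_subclonal(cons, sim$window_offsets, sim$ref_window, -146L)
  expect_identical(sc$calls$offset, -146L)  # only the driver site
  split <- sc$n_driver_mut / (sc$n_driver_mut + sc$n_driver_ref)
  expect_gt(split, 0.42); expect_lt(split, 0.58)
})

test_that("planted indel molecules are removed at about the planted rate", {
  sim <- simulate_umi_reads(umi_sim_config(n_molecules = 2000, indel_rate = 0.05,
                                           read_error_rate = 0, seed = 93),
                            CATALOG)
  a <- anchor_reads(sim$reads, sim$primer, nchar(sim$ref_window))
  cons <- call_consensus(group_families(a))
  kept <- filter_indel_consensus(cons)
  removed <- attr(kept, "n_indel_removed")
  # binomial 99% band around the planted 5%
  p_band <- qbinom(c(0.005, 0.995), nrow(cons), 0.05)
  expect_gte(removed, p_band[1])
  expect_lte(removed, p_band[2])
  # truth cross-check: removed families are exactly the planted indel molecules
  planted <- sim$truth$umi[sim$truth$has_indel & sim$truth$family_size >= 3]
  expect_setequal(cons$umi[cons$has_indel], planted)
})

test_that("unplanted pair-scan world yields about the expected chance motif count", {
  cfg <- pairscan_sim_config(n_bound = 0, n_unbound = 0,
                             n_background_mutations = 0, seed = 94)
  w <- simulate_pairscan_world(cfg)
  reg <- extract_upstream_regions(w$genes)
  hits <- scan_motifs(w$genome, reg)
  # closed-form expectation under the generator's base composition
  p <- c(A = 0.22, C = 0.28, G = 0.28, T = 0.22)
  p_core <- p["T"]^2 * p["C"]^2 * (p["G"] + p["T"])
  n_pos <- sum(reg$end - reg$start + 1 - 6)
  expected <- 2 * n_pos * p_core  # both strands
  sd_ <- sqrt(expected)
  expect_gt(nrow(hits), expected - 4 * sd_)
  expect_lt(nrow(hits), expected + 4 * sd_)
})

test_that("bound pairs carry peaks and elevated mutations; classes separate", {
  w <- simulate_pairscan_world(pairscan_sim_config(seed = 95))
  reg <- extract_upstream_regions(w$genes)
  hits <- scan_motifs(w$genome, reg)
  pairs <- classify_pairs(enumerate_pairs(hits), hits, w$mutations)
  cc <- chip_cooccupancy(pairs, w$peaks)
  frac <- setNames(cc$by_class$fraction, cc$by_class$mutation_class)
  expect_gt(frac[["ge2_per_site"]], frac[["0"]])
  # planted bound pairs are recovered among the enumerated pairs
  key <- paste(pairs$contig, pairs$start_a, pairs$start_b)
  truth_key <- paste(w$truth$contig, w$truth$start_a, w$truth$start_b)
  expect_gt(mean(truth_key %in% key), 0.9)
})
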