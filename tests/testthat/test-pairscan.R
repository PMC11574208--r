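test_that("upstream region arithmetic and X/Y exclusion", {
  genes <- data.frame(gene_id = c("a", "b", "x"),
                      contig = c("chr1", "chr1", "chrX"),
                      strand = c("+", "-", "+"),
                      coding_start = c(10001L, 5000L, 10001L),
                      stringsAsFactors = FALSE)
  reg <- extract_upstream_regions(genes)
  expect_identical(reg$start[reg$gene_id == "a"], 9001L)
  expect_identical(reg$end[reg$gene_id == "a"], 10000L)
  expect_identical(reg$start[reg$gene_id == "b"], 5001L)
  expect_identical(reg$end[reg$gene_id == "b"], 6000L)
  expect_false("x" %in% reg$gene_id)
  reg_xy <- extract_upstream_regions(genes, drop_xy = FALSE)
  expect_true("x" %in% reg_xy$gene_id)
  expect_warning(extract_upstream_regions(
    data.frame(gene_id = "t", contig = "chr1", strand = "+",
               coding_start = 500L)), "truncated")
})

test_that("motif scan finds NNTTCCK hits with in-region prefixes on both strands", {
  gm <- Biostrings::DNAStringSet(c(chrT = "AATTCCGAA"))
  reg <- data.frame(gene_id = "g", contig = "chrT", strand = "+",
                    start = 1L, end = 9L)
  h <- scan_motifs(gm, reg)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 1L)
  expect_identical(h$strand, "+")
  expect_identical(h$kmer, "AATTCCG")
  # core at the region edge without a 2-base prefix: no hit
  gm2 <- Biostrings::DNAStringSet(c(chrT = "TTCCGAAAA"))
  h2 <- scan_motifs(gm2, transform(reg, end = 9L))
  expect_identical(nrow(h2), 0L)
  # minus-strand: revcomp(NNTTCCG) = CGGAANN on the plus strand
  gm3 <- Biostrings::DNAStringSet(c(chrT = "AACGGAATTAA"))
  h3 <- scan_motifs(gm3, data.frame(gene_id = "g", contig = "chrT",
                                    strand = "+", start = 1L, end = 11L))
  expect_identical(h3$strand, "-")
  expect_identical(h3$start, 3L)
  expect_identical(h3$kmer, "AATTCCG")
  # ambiguous bases never match
  gm4 <- Biostrings::DNAStringSet(c(chrT = "AATTCCNAA"))
  expect_identical(nrow(scan_motifs(gm4, reg)), 0L)
})

test_that("motif scan equals a brute-force regex oracle on random 10 kb sequence", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
  gm <- Biostrings::DNAStringSet(c(chrR = s))
  reg <- data.frame(gene_id = "g", contig = "chrR", strand = "+",
                    start = 1L, end = 10000L)
  got <- scan_motifs(gm, reg)
  fwd <- gregexpr("(?=..TTCC[GT])", s, perl = TRUE)[[1]]
  fwd <- if (fwd[1] == -1) integer(0) else as.integer(fwd)
  rev <- gregexpr("(?=[AC]GGAA..)", s, perl = TRUE)[[1]]
  rev <- if (rev[1] == -1) integer(0) else as.integer(rev)
  oracle <- rbind(data.frame(start = fwd, strand = "+"),
                  data.frame(start = rev, strand = "-"))
  expect_identical(sort(paste(got$start, got$strand)),
                   sort(paste(oracle$start, oracle$strand)))
})

test_that("pair enumeration respects strand and the 7..100 distance window", {
  hits <- data.frame(contig = "c",
                     start = c(100L, 110L, 106L, 210L, 205L),
                     strand = c("+", "+", "-", "+", "+"))
  p <- enumerate_pairs(hits)
  expect_false(any(p$strand == "-" & p$start_a == 100))  # no cross-strand pair
  expect_true(any(p$start_a == 100 & p$start_b == 110 & p$distance == 10))
  # boundary: 6 excluded, 7 included, 100 included, 101 excluded
  h2 <- data.frame(contig = "c", start = c(0L, 6L, 7L, 100L, 101L) + 1000L,
                   strand = "+")
  p2 <- enumerate_pairs(h2)
  d_from_first <- p2$distance[p2$start_a == 1000L]
  expect_setequal(d_from_first, c(7L, 100L))
  # brute-force oracle on a random hit set
  set.seed(10)
  h3 <- data.frame(contig = sample(c("c1", "c2"), 60, TRUE),
                   start = sample.int(500, 60),
                   strand = sample(c("+", "-"), 60, TRUE))
  h3 <- unique(h3)
  p3 <- enumerate_pairs(h3)
  brute <- 0L
  for (i in seq_len(nrow(h3))) for (j in seq_len(nrow(h3))) {
    d <- h3$start[j] - h3$start[i]
    if (h3$contig[i] == h3$contig[j] && h3$strand[i] == h3$strand[j] &&
        d >= 7 && d <= 100) brute <- brute + 1L
  }
  expect_identical(nrow(p3), brute)
})

test_that("mutation classes require the per-site threshold at both sites", {
  hits <- data.frame(contig = "c", start = c(100L, 150L, 300L, 350L, 500L, 550L),
                     strand = "+")
  pairs <- enumerate_pairs(hits)
  muts <- data.frame(donor = c("d1", "d2", "d1", "d2", "d1"),
                     contig = "c",
                     start = c(100L, 101L, 150L, 151L, 300L),
                     ref = "C", alt = "T", span = 1L)
  cl <- classify_pairs(pairs, hits, muts)
  expect_identical(cl$mutation_class[cl$start_a == 100], "ge2_per_site")
  expect_identical(cl$mutation_class[cl$start_a == 300], "0")  # one site 1, other 0
  expect_identical(cl$mutation_class[cl$start_a == 500], "0")
  # per-donor dedup: same donor, same call repeated counts once
  muts_dup <- rbind(muts, muts[1, ])
  cl2 <- classify_pairs(pairs, hits, muts_dup)
  expect_identical(cl2$mut_a, cl$mut_a)
  # monotonicity: ge2 pairs are a subset of pairs with both sites >= 1
  ge2 <- cl$mutation_class == "ge2_per_site"
  expect_true(all(cl$mut_a[ge2] >= 1 & cl$mut_b[ge2] >= 1))
})

test_that("site mutation counts agree with a brute-force interval overlap", {
  set.seed(12)
  hits <- data.frame(contig = sample(c("c1", "c2"), 40, TRUE),
                     start = sample.int(2000, 40), strand = "+")
  muts <- data.frame(donor = paste0("d", sample.int(20, 1000, TRUE)),
                     contig = sample(c("c1", "c2"), 1000, TRUE),
                     start = sample.int(2000, 1000, TRUE),
                     ref = "C", alt = "T", span = 1L)
  got <- count_site_mutations(hits, muts)
  dedup <- unique(muts[, c("donor", "contig", "start", "alt")])
  brute <- vapply(seq_len(nrow(hits)), function(i)
    sum(dedup$contig == hits$contig[i] &
          dedup$start >= hits$start[i] & dedup$start <= hits$start[i] + 6L),
    integer(1))
  expect_identical(got, brute)
})

test_that("spacing distribution smooths with window 3 and normalizes to 1", {
  d <- spacing_distribution(rep(50L, 10))
  expect_equal(sum(d$normalized), 1)
  expect_gt(sum(d$normalized[d$distance %in% 49:51]), 0.99)
  u <- spacing_distribution(rep(7:100, 3))
  expect_true(all(abs(u$normalized - u$normalized[50]) < 1e-12))
  # hand-computed example on five distances
  h <- spacing_distribution(c(10L, 10L, 11L, 12L, 14L))
  raw <- h$count[h$distance %in% 9:15]
  expect_identical(raw, c(0, 2, 1, 1, 0, 1, 0))
  expect_equal(h$smoothed[h$distance == 10], mean(c(0, 2, 1)))
  expect_equal(h$smoothed[h$distance == 7], mean(h$count[1:2]))  # edge rule
  e <- spacing_distribution(integer(0))
  expect_true(isTRUE(attr(e, "empty")))
})

test_that("ChIP co-occupancy needs both starts within one top-quartile peak", {
  pairs <- data.frame(contig = "c", strand = "+",
                      start_a = c(100L, 300L, 500L),
                      start_b = c(150L, 350L, 550L),
                      distance = 50L,
                      mutation_class = c("ge2_per_site", "0", "0"))
  gr <- function(s, e, sv) {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(s, e))
    g$signalValue <- sv
    g
  }
  peaks <- list(exp1 = c(gr(90, 160, 95),          # covers pair 1
                         gr(290, 320, 95),         # start_a of pair 2 only
                         gr(330, 360, 95),         # start_b of pair 2 only
                         gr(490, 560, 5)))         # low score: filtered out
  res <- chip_cooccupancy(pairs, peaks)
  expect_identical(res$pairs$chip_cooccupied, c(TRUE, FALSE, FALSE))
  expect_identical(res$by_class$fraction[res$by_class$mutation_class == "ge2_per_site"], 1)
  expect_warning(chip_cooccupancy(pairs, list(tiny = gr(1, 2, 1))), "fewer than 4")
})

test_that("periodicity picks the planted helical comb and is flat on uniform input", {
  comb <- unlist(lapply(seq(10, 94, by = 21), function(d) rep(c(d, d + 11L), 5)))
  ps <- periodicity_score(spacing_distribution(comb))
  expect_true(ps$period %in% c(10, 11))
  expect_gt(ps$amplitude, 0.2)
  flat <- periodicity_score(spacing_distribution(rep(7:100, 5)))
  expect_lt(abs(flat$amplitude), 0.1)
  degen <- periodicity_score(spacing_distribution(rep(50L, 4)))
  expect_false(is.na(degen$period))  # single spike smooths to 3 bins, defined
  expect_true(is.na(periodicity_score(spacing_distribution(integer(0)))$period))
})

test_that("broadPeak files round-trip through the reader", {
  w <- simulate_pairscan_world(pairscan_sim_config(n_bound = 10, n_unbound = 10,
                                                   n_background_mutations = 50,
                                                   seed = 6))
  dir <- tempfile()
  paths <- write_pairscan_world(w, dir)
  pk <- read_broadpeak(paths$peaks[[1]])
  expect_s4_class(pk, "GRanges")
  expect_identical(length(pk), length(w$peaks[[1]]))
  expect_equal(pk$signalValue, w$peaks[[1]]$signalValue, tolerance = 1e-6)
  expect_identical(BiocGenerics::start(pk), BiocGenerics::start(w$peaks[[1]]))
  genes <- read_gene_models(paths$genes)
  expect_identical(nrow(genes), nrow(w$genes))
})
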