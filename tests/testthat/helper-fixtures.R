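# Shared fixtures, built once per test run.

CATALOG <- build_reference_promoter()
SYN_MAP <- CATALOG$map

# brute-force regex scan for TTCCK cores on both strands; independent of
# the Biostrings-based implementation
oracle_scan_cores <- function(seq, lo) {
  hit <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- hit(seq, "(?=TTCC[GT])")
  rev <- hit(seq, "(?=[AC]GGAA)")
  data.frame(offset = c(fwd, rev) + lo - 1L,
             strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

# brute-force two-sided Fisher by explicit enumeration from log-factorials
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(supp))
  p0 <- exp(lp(a))
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# a tiny hand-made cohort: helper used by several cohort tests
toy_cohort <- function() {
  samples <- data.frame(
    sample_id = paste0("S", 1:6),
    patient_id = c("P1", "P1", "P2", "P3", "P4", "P5"),
    cancer_type = c(rep("AAA", 5), "BBB"),
    assay_id = "ASSAY1",
    capture_size_bp = c(rep(5e5, 5), 2e5),
    covers_tertp = TRUE,
    report_order = c(2L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  g124 <- offset_to_genomic(SYN_MAP, -124L)
  mutations <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    contig = SYN_MAP$contig,
    start = g124,
    ref = "C", alt = "T", span = 1L,
    ref_context = "CCT",
    stringsAsFactors = FALSE)
  cohort_table(mutations, samples)
}
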