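#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P-value by summation, over all tables with the observed
#' margins, of hypergeometric point probabilities not exceeding that of the
#' observed table (the usual "point probability" two-sided convention). The
#' odds ratio is the unconditional sample odds ratio `ad/bc` (`Inf` when
#' `bc = 0` and the numerator is positive), not the conditional MLE.
#'
#' @param tab 2x2 integer matrix `rbind(c(a, b), c(c, d))`, rows = driver
#'   status, columns = secondary status (any orientation; P is invariant to
#'   transposition and label swaps).
#' @return List with `p` (two-sided P; 1 when a margin is empty),
#'   `odds_ratio` (`NA` when undefined, i.e. 0/0) and `table`.
#' @examples
#' fisher_exact_2x2(rbind(c(41, 1017), c(3, 508)))$p  # ~6e-5
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    return(list(p = 1, odds_ratio = or, table = tab))
  }
  supp <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(supp, r1, r2, c1)
  p0 <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(dens[dens <= p0 * (1 + 1e-7)]))
  list(p = p, odds_ratio = or, table = tab)
}
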