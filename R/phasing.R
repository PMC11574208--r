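## Read-backed cis/trans phasing of closely spaced promoter variants
## relative to a driver allele, from SAM-format alignments.

#' Read a SAM file into a data frame
#'
#' Parses the eleven mandatory SAM columns of a text SAM file; header lines
#' are skipped and optional tags ignored. (The field's binary BAM tooling
#' is deliberately not involved: phasing works directly on the text
#' alignments, as the per-read CIGAR walk is the point of this module.)
#'
#' @param path SAM file path.
#' @return Data frame `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`, `qual`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) stop("malformed SAM record: fewer than 11 fields")
  g <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(qname = g(1), flag = as.integer(g(2)), rname = g(3),
             pos = as.integer(g(4)), mapq = as.integer(g(5)), cigar = g(6),
             seq = g(10), qual = g(11), stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, list(m))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", ops)),
       op = sub("^\\d+", "", ops))
}

# Query index of the read base aligned at reference position `target`,
# or NA when the target falls in a deletion/skip or outside the alignment.
query_index_at <- function(pos, cigar, target) {
  if (target < pos) return(NA_integer_)
  cg <- parse_cigar(cigar)
  rpos <- pos; qpos <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (target < rpos + len) return(qpos + (target - rpos))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (target < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } # H, P consume nothing relevant
  }
  NA_integer_
}

FLAG_SECONDARY <- 256L; FLAG_DUP <- 1024L; FLAG_SUPPLEMENTARY <- 2048L

#' Select reads covering every target position
#'
#' Duplicates, secondary and supplementary alignments are excluded, and a
#' retained read must have an aligned query base (CIGAR M/=/X) at every
#' target position; a deletion or reference skip spanning any target
#' excludes the read.
#'
#' @param sam SAM data frame from [read_sam()].
#' @param targets Integer vector of 1-based reference positions.
#' @param contig Optional contig name to restrict to.
#' @return The covering subset of `sam` (possibly empty).
#' @export
select_covering_reads <- function(sam, targets, contig = NULL) {
  s <- sam
  if (!is.null(contig)) s <- s[s$rname == contig, , drop = FALSE]
  s <- s[bitwAnd(s$flag, FLAG_SECONDARY + FLAG_DUP + FLAG_SUPPLEMENTARY) == 0L, ,
         drop = FALSE]
  if (!nrow(s)) return(s)
  simple <- s$cigar == paste0(nchar(s$seq), "M")
  covers <- logical(nrow(s))
  covers[simple] <- s$pos[simple] <= min(targets) &
    s$pos[simple] + nchar(s$seq[simple]) - 1L >= max(targets)
  for (i in which(!simple)) {
    covers[i] <- all(!is.na(vapply(targets, function(t)
      query_index_at(s$pos[i], s$cigar[i], t), integer(1))))
  }
  s[covers, , drop = FALSE]
}

#' Call per-read alleles at target positions
#'
#' Locates the query base at each target by a CIGAR walk and compares it to
#' the reference: `"ref"`, the alternative base, or `"low_quality"` when the
#' base quality is below `min_base_qual`.
#'
#' @param sam Covering reads (see [select_covering_reads()]).
#' @param targets 1-based reference positions.
#' @param reference Reference sequence of the contig (character scalar,
#'   position 1 = coordinate 1).
#' @param min_base_qual Phred threshold (default 20).
#' @return Character matrix reads x targets (dimnames: qname, target).
#' @export
call_read_alleles <- function(sam, targets, reference, min_base_qual = 20) {
  ref_bases <- strsplit(toupper(reference), "")[[1]]
  out <- matrix(NA_character_, nrow(sam), length(targets),
                dimnames = list(sam$qname, as.character(targets)))
  if (!nrow(sam)) return(out)
  simple <- sam$cigar == paste0(nchar(sam$seq), "M")
  if (any(simple)) {
    si <- which(simple)
    for (j in seq_along(targets)) {
      qi <- targets[j] - sam$pos[si] + 1L
      if (any(qi < 1L | qi > nchar(sam$seq[si]))) {
        stop("read does not cover target ", targets[j],
             "; select covering reads first")
      }
      b <- substr(sam$seq[si], qi, qi)
      qc <- substr(sam$qual[si], qi, qi)
      q <- as.integer(charToRaw(paste(qc, collapse = ""))) - 33L
      call <- ifelse(q < min_base_qual, "low_quality",
                     ifelse(b == ref_bases[targets[j]], "ref", b))
      out[si, j] <- call
    }
  }
  for (i in which(!simple)) {
    if (nchar(sam$seq[i]) != sum(with(parse_cigar(sam$cigar[i]),
                                      len[op %in% c("M", "I", "S", "=", "X")]))) {
      stop("CIGAR/sequence inconsistency for read ", sam$qname[i])
    }
    for (j in seq_along(targets)) {
      qi <- query_index_at(sam$pos[i], sam$cigar[i], targets[j])
      if (is.na(qi)) stop("read ", sam$qname[i], " does not cover target ",
                          targets[j], "; select covering reads first")
      q <- utf8ToInt(substr(sam$qual[i], qi, qi)) - 33L
      b <- substr(sam$seq[i], qi, qi)
      out[i, j] <- if (q < min_base_qual) "low_quality"
      else if (b == ref_bases[targets[j]]) "ref" else b
    }
  }
  out
}

#' Build a driver-partitioned phase table
#'
#' Reads are partitioned by their allele at the driver position (reads with
#' a low-quality driver base are dropped and counted); per secondary
#' position, mutant reads are tallied within each partition.
#'
#' @param calls Allele matrix from [call_read_alleles()].
#' @param driver_target Driver reference position (must be a column of
#'   `calls`).
#' @return Object of class `phase_table`: list with `driver_target`,
#'   `n_driver_mut`, `n_driver_ref`, `n_driver_dropped` and `counts`
#'   (per secondary target: `cis_mut` = mutant reads among driver-mutant
#'   reads, `trans_mut` = mutant reads among driver-reference reads, plus
#'   allele fractions), and `empty` flag when no covering reads exist.
#' @export
build_phase_table <- function(calls, driver_target) {
  dt <- as.character(driver_target)
  stopifnot(dt %in% colnames(calls))
  if (!nrow(calls)) {
    return(structure(list(driver_target = driver_target, n_driver_mut = 0L,
                          n_driver_ref = 0L, n_driver_dropped = 0L,
                          counts = NULL, empty = TRUE), class = "phase_table"))
  }
  drv <- calls[, dt]
  dropped <- drv == "low_quality"
  mut <- drv != "ref" & !dropped
  refr <- drv == "ref"
  sec <- setdiff(colnames(calls), dt)
  counts <- do.call(rbind, lapply(sec, function(tg) {
    v <- calls[, tg]
    is_mut <- v != "ref" & v != "low_quality"
    data.frame(target = as.integer(tg),
               cis_mut = sum(is_mut & mut), trans_mut = sum(is_mut & refr),
               af_driver_mut = if (sum(mut)) sum(is_mut & mut) / sum(mut) else NA_real_,
               af_driver_ref = if (sum(refr)) sum(is_mut & refr) / sum(refr) else NA_real_)
  }))
  structure(list(driver_target = driver_target,
                 n_driver_mut = sum(mut), n_driver_ref = sum(refr),
                 n_driver_dropped = sum(dropped), counts = counts,
                 empty = FALSE),
            class = "phase_table")
}

#' @export
print.phase_table <- function(x, ...) {
  cat(sprintf("phase_table: driver @%s, %d driver-mut / %d driver-ref reads\n",
              x$driver_target, x$n_driver_mut, x$n_driver_ref))
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

#' Per-sample phasing verdicts
#'
#' A secondary position is `cis` when at least `min_support` mutant reads
#' lie in the driver-mutant partition and at most `max_leak` in the
#' driver-reference partition; `trans` symmetrically; `mixed` when both
#' partitions exceed the leak tolerance with support; `indeterminate`
#' otherwise.
#'
#' @param phase_table From [build_phase_table()].
#' @param min_support Minimum mutant-read support (default 3).
#' @param max_leak Maximum tolerated mutant reads in the opposite partition
#'   (default 2).
#' @return Data frame `target`, `cis_mut`, `trans_mut`, `verdict`.
#' @export
summarize_sample <- function(phase_table, min_support = 3, max_leak = 2) {
  stopifnot(inherits(phase_table, "phase_table"))
  if (phase_table$empty) {
    return(data.frame(target = integer(0), cis_mut = integer(0),
                      trans_mut = integer(0), verdict = character(0)))
  }
  ct <- phase_table$counts
  verdict <- mapply(function(ci, tr) {
    if (ci >= min_support && tr <= max_leak) "cis"
    else if (tr >= min_support && ci <= max_leak) "trans"
    else if (ci >= min_support && tr >= min_support) "mixed"
    else if (ci > max_leak && tr > max_leak) "mixed"
    else "indeterminate"
  }, ct$cis_mut, ct$trans_mut)
  data.frame(target = ct$target, cis_mut = ct$cis_mut,
             trans_mut = ct$trans_mut, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Estimate the cis fraction of a secondary variant
#'
#' Among reads mutant at the secondary position, the fraction lying in the
#' driver-mutant partition, with an exact (Clopper-Pearson) binomial 95%
#' confidence interval.
#'
#' @param phase_table From [build_phase_table()].
#' @param target Secondary position.
#' @return List `estimate`, `n_mut_reads`, `ci` (length 2).
#' @export
estimate_cis_fraction <- function(phase_table, target) {
  ct <- phase_table$counts
  row <- ct[ct$target == target, ]
  if (!nrow(row)) stop("target not in phase table")
  x <- row$cis_mut; n <- row$cis_mut + row$trans_mut
  if (n == 0) return(list(estimate = NA_real_, n_mut_reads = 0L, ci = c(0, 1)))
  bt <- stats::binom.test(x, n)
  list(estimate = x / n, n_mut_reads = n, ci = as.numeric(bt$conf.int))
}
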