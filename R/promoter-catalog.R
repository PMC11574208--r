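## Promoter site catalogue: the wild-type reporting-strand sequence together
## with the driver, proto-ETS, native-ETS and UV-hotspot positions.

#' Build the reference promoter catalogue
#'
#' Constructs a synthetic wild-type promoter sequence on the reporting strand
#' that satisfies, simultaneously, all sequence constraints implied by the
#' known mutant and native ETS motifs:
#'
#' * C>T at offset -124 creates the de novo motif `CCCCTTCCGG`
#'   (wild type `CCCCCTCCGG` over -128..-119);
#' * C>T at -146 creates `CCCCTTCCGG` with hotspot cytosines at -149/-148
#'   (wild type `CCCCTCCCGG` over -151..-142);
#' * CC>TT at -139/-138 creates a `TTCCK` core (wild type `CCCCG` over
#'   -139..-135, flanked by CC at -141/-140);
#' * the native ETS region carries `CCTTCCG` over -101..-95, placing a
#'   pre-existing `TTCCG` core at -99..-95 with strong hotspot bases at
#'   -101/-100 and a weaker one at the first central cytosine, -97;
#' * a second native core (the "ETS-195" partner) is placed immediately
#'   downstream, non-overlapping, with configurable start-to-start spacing.
#'
#' All remaining positions are filled with a fixed GC alternation; the filler
#' contains no A or T, so the only ETS cores present or creatable by the
#' catalogued substitutions are the intended ones.
#'
#' @param map A [promoter_map()]; defaults to the synthetic locus map.
#' @param window Length-2 integer vector `c(lo, hi)` of offsets covered by
#'   the wild-type sequence; must contain -160..-85.
#' @param ets195_spacing Start-to-start spacing (bp) between the two native
#'   cores; values below 5 would overlap the cores and are rejected.
#' @return An object of class `site_catalog` with elements `map`, `window`,
#'   `wt_sequence`, `sites` (data frame of catalogued positions), `cores`
#'   (data frame of ETS cores and the driver each depends on) and
#'   `driver_set` (data frame of primary driver mutations).
#' @examples
#' cat <- build_reference_promoter()
#' mut <- apply_mutation(cat, -146, "T")
#' grepl("CCCCTTCCGG", mut)  # TRUE
#' @export
build_reference_promoter <- function(map = synthetic_promoter_map(),
                                     window = c(-300L, -1L),
                                     ets195_spacing = 5L) {
  stopifnot(length(window) == 2L, window[1] < window[2], window[2] <= -1L)
  if (window[1] > -160L || window[2] < -85L) {
    stop("window must cover offsets -160..-85")
  }
  if (ets195_spacing < 5L) stop("ets195_spacing below 5 bp would overlap the native cores")
  lo <- as.integer(window[1]); hi <- as.integer(window[2])
  offs <- lo:hi
  # GC filler: no A/T anywhere outside the constraint blocks, so no ETS core
  # (TTCCK) or reverse-strand core (revcomp MGGAA) can occur by accident.
  base <- ifelse(offs %% 2L == 0L, "G", "C")
  names(base) <- offs
  put <- function(b, from, bases) { b[as.character(seq(from, from + length(bases) - 1L))] <- bases; b }
  base <- put(base, -151L, c("C","C","C","C","T","C","C","C","G","G"))   # -146 proto block
  base <- put(base, -141L, c("C","C","C","C","C","C","G"))               # -139/-138 proto block
  base <- put(base, -128L, c("C","C","C","C","C","T","C","C","G","G"))   # -124 proto block
  base <- put(base, -101L, c("C","C","T","T","C","C","G"))               # native ETS (ETS-200)
  e195 <- -99L + as.integer(ets195_spacing)
  if (e195 + 4L > hi) stop("window too short for the second native core")
  base <- put(base, e195, c("T","T","C","C","G"))                        # ETS-195 partner

  sites <- rbind(
    data.frame(offset = -146L, role = "canonical_driver", ref = "C", alt = "T", linked_core = -147L),
    data.frame(offset = -124L, role = "canonical_driver", ref = "C", alt = "T", linked_core = -124L),
    data.frame(offset = -139L, role = "proto_ets", ref = "C", alt = "T", linked_core = -139L),
    data.frame(offset = -138L, role = "proto_ets", ref = "C", alt = "T", linked_core = -139L),
    data.frame(offset = -125L, role = "proto_ets", ref = "C", alt = "T", linked_core = -124L),
    data.frame(offset = -149L, role = "secondary_hotspot", ref = "C", alt = "T", linked_core = -147L),
    data.frame(offset = -148L, role = "secondary_hotspot", ref = "C", alt = "T", linked_core = -147L),
    data.frame(offset = -126L, role = "secondary_hotspot", ref = "C", alt = "T", linked_core = -124L),
    data.frame(offset = -101L, role = "secondary_hotspot", ref = "C", alt = "T", linked_core = -99L),
    data.frame(offset = -100L, role = "secondary_hotspot", ref = "C", alt = "T", linked_core = -99L),
    data.frame(offset = -97L,  role = "central_hotspot",   ref = "C", alt = "T", linked_core = -99L),
    data.frame(offset = -99L,  role = "native_ets", ref = "T", alt = NA_character_, linked_core = -99L),
    data.frame(offset = e195,  role = "native_ets", ref = "T", alt = NA_character_, linked_core = e195)
  )

  # ETS cores: offset of the core's first (most upstream) base on the
  # reporting strand, and the driver event required for occupancy.
  cores <- data.frame(
    core_offset = c(-147L, -139L, -124L, -99L, e195),
    kind = c("de_novo", "de_novo", "de_novo", "native", "native"),
    requires = c("m146", "dnv139_138", "m124", "any_driver", "none"),
    stringsAsFactors = FALSE
  )

  driver_set <- data.frame(
    name = c("m124", "m146", "dnv139_138", "dnv125_124"),
    offsets = I(list(-124L, -146L, c(-139L, -138L), c(-125L, -124L))),
    ref = c("C", "C", "CC", "CC"),
    alt = c("T", "T", "TT", "TT"),
    stringsAsFactors = FALSE
  )

  obj <- structure(
    list(map = map, window = c(lo, hi),
         wt_sequence = paste(base, collapse = ""),
         sites = sites, cores = cores, driver_set = driver_set),
    class = "site_catalog"
  )
  validate_site_catalog(obj)
  obj
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("site_catalog: window [%d, %d], %d sites, %d cores, %d drivers\n",
              x$window[1], x$window[2], nrow(x$sites), nrow(x$cores),
              nrow(x$driver_set)))
  invisible(x)
}

#' Validate a site catalogue against its own motif constraints
#'
#' Re-applies each catalogued driver mutation to the wild-type sequence and
#' checks that the expected mutant ETS motifs appear; rejects contradictory
#' user-supplied catalogues naming the violated constraint.
#'
#' @param catalog A `site_catalog`.
#' @return The catalogue, invisibly; stops on violation.
#' @export
validate_site_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "site_catalog"))
  checks <- list(
    list(off = -146L, alt = "T", motif = "CCCCTTCCGG",
         what = "C>T at -146 must create CCCCTTCCGG"),
    list(off = -124L, alt = "T", motif = "CCCCTTCCGG",
         what = "C>T at -124 must create CCCCTTCCGG"),
    list(off = c(-139L, -138L), alt = c("T", "T"), motif = "CCTTCCG",
         what = "CC>TT at -139/-138 must create a CC-flanked TTCCK core")
  )
  for (ck in checks) {
    mut <- apply_mutation(catalog, ck$off, ck$alt)
    if (!grepl(ck$motif, mut, fixed = TRUE)) {
      stop("catalogue constraint violated: ", ck$what)
    }
  }
  if (!grepl("CCTTCC", catalog$wt_sequence, fixed = TRUE)) {
    stop("catalogue constraint violated: ",
         "wild type must carry the native CC-flanked TTCCK core")
  }
  invisible(catalog)
}

#' Wild-type bases as a named vector
#'
#' @param catalog A `site_catalog`.
#' @return Character vector of single bases named by offset.
#' @export
promoter_bases <- function(catalog) {
  b <- strsplit(catalog$wt_sequence, "")[[1]]
  names(b) <- seq(catalog$window[1], catalog$window[2])
  b
}

offset_index <- function(catalog, offset) {
  idx <- as.integer(offset) - catalog$window[1] + 1L
  if (any(idx < 1L | idx > nchar(catalog$wt_sequence))) {
    stop("offset outside the catalogue window [", catalog$window[1], ", ",
         catalog$window[2], "]")
  }
  idx
}

#' Apply substitution mutations to the promoter sequence
#'
#' @param x A `site_catalog` (mutates its wild type) or a plain character
#'   sequence with an accompanying `window` attribute-style `lo` argument.
#' @param offset Integer vector of offsets to substitute.
#' @param alt Character vector of replacement bases (recycled to length of
#'   `offset`).
#' @param seq Optional sequence to mutate instead of the catalogue wild type
#'   (same window).
#' @return The mutated sequence (character scalar, same length as input).
#' @export
apply_mutation <- function(x, offset, alt, seq = NULL) {
  stopifnot(inherits(x, "site_catalog"))
  s <- if (is.null(seq)) x$wt_sequence else seq
  stopifnot(nchar(s) == x$window[2] - x$window[1] + 1L)
  alt <- toupper(rep_len(alt, length(offset)))
  if (!all(alt %in% c("A", "C", "G", "T"))) stop("alt bases must be A/C/G/T")
  idx <- offset_index(x, offset)
  b <- strsplit(s, "")[[1]]
  if (all(b[idx] == alt)) {
    stop("identity substitution: alt equals ref at every given offset")
  }
  b[idx] <- alt
  paste(b, collapse = "")
}

#' Scan a sequence for ETS core motifs (TTCCK) on both strands
#'
#' @param seq Character scalar, reporting-strand sequence.
#' @param lo Offset of the first base of `seq`.
#' @return Data frame with `offset` (of the core's leftmost base in reporting
#'   coordinates) and `strand` (`"+"` reporting strand, `"-"` opposite).
#' @export
scan_ets_cores <- function(seq, lo) {
  subj <- Biostrings::DNAString(seq)
  # fixed = "subject": the K ambiguity in the pattern is honoured but
  # ambiguous subject bases (N) never match
  fwd <- Biostrings::matchPattern("TTCCK", subj, fixed = "subject")
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString("TTCCK")),
    subj, fixed = "subject")
  data.frame(
    offset = as.integer(c(BiocGenerics::start(fwd), BiocGenerics::start(rev))) + as.integer(lo) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
}

#' ETS core gains and losses between two sequences
#'
#' Scans both strands of the wild-type and mutant sequences for `TTCCK`
#' cores and reports cores present in one but not the other.
#'
#' @param wt,mut Equal-length reporting-strand sequences.
#' @param lo Offset of the first base (default -300 to match the bundled
#'   catalogue window).
#' @return List with data frames `gained` and `lost` (columns `offset`,
#'   `strand`).
#' @export
scan_ets_gain <- function(wt, mut, lo = -300L) {
  if (nchar(wt) != nchar(mut)) stop("wt and mut sequences must have equal length")
  w <- scan_ets_cores(wt, lo)
  m <- scan_ets_cores(mut, lo)
  key <- function(d) paste(d$offset, d$strand)
  list(gained = m[!(key(m) %in% key(w)), , drop = FALSE],
       lost   = w[!(key(w) %in% key(m)), , drop = FALSE])
}

#' Predict UV (CPD) hotspot bases at an ETS core
#'
#' ETS occupancy stimulates CPD formation primarily at the two bases
#' immediately 5' of the `TTCCK` core (strong hotspots, requiring both to be
#' cytosines on the reporting strand, i.e. a CC dipyrimidine) and, to a
#' lesser extent, at the first central cytosine of the core (weak hotspot).
#' Unoccupied sites show no elevated damage and yield an empty prediction.
#'
#' @param catalog A `site_catalog`.
#' @param core_offset Offset of the core's first base (see `catalog$cores`).
#' @param occupied Logical; is the site bound (e.g. driver present for de
#'   novo / native partner cores)?
#' @param seq Optional mutant sequence in which the core exists; flanking
#'   bases are looked up here (defaults to the wild type, whose flanks are
#'   unchanged by the core-creating substitutions).
#' @return Data frame with columns `offset` and `strength`
#'   (`"strong"`/`"weak"`); zero rows when unoccupied or no dipyrimidine.
#' @export
predict_hotspots <- function(catalog, core_offset, occupied = TRUE, seq = NULL) {
  stopifnot(inherits(catalog, "site_catalog"), length(core_offset) == 1L)
  out <- data.frame(offset = integer(0), strength = character(0),
                    stringsAsFactors = FALSE)
  if (!isTRUE(occupied)) return(out)
  b <- if (is.null(seq)) promoter_bases(catalog) else {
    v <- strsplit(seq, "")[[1]]
    names(v) <- seq(catalog$window[1], catalog$window[2])
    v
  }
  at <- function(o) unname(b[as.character(o)])
  core_offset <- as.integer(core_offset)
  pre <- c(core_offset - 2L, core_offset - 1L)
  if (all(at(pre) == "C")) {
    out <- rbind(out, data.frame(offset = pre, strength = "strong"))
  }
  central <- core_offset + 2L  # first central cytosine of T T C C K
  if (identical(at(central), "C")) {
    out <- rbind(out, data.frame(offset = central, strength = "weak"))
  }
  out
}

#' Write the catalogue wild-type sequence as FASTA
#'
#' The header records the anchor, gene strand and assembly tag.
#'
#' @param catalog A `site_catalog`.
#' @param path Output file path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  s <- Biostrings::DNAStringSet(catalog$wt_sequence)
  names(s) <- sprintf("%s anchor=%d gene_strand=%s assembly=%s window=%d..%d",
                      catalog$map$contig, catalog$map$atg_anchor,
                      catalog$map$gene_strand, catalog$map$assembly_tag,
                      catalog$window[1], catalog$window[2])
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Serialize / deserialize a site catalogue as YAML
#'
#' @param catalog A `site_catalog`.
#' @param path File path.
#' @return `read_catalog_yaml` returns a `site_catalog`.
#' @export
write_catalog_yaml <- function(catalog, path) {
  y <- list(
    map = unclass(catalog$map),
    window = as.integer(catalog$window),
    wt_sequence = catalog$wt_sequence,
    sites = lapply(seq_len(nrow(catalog$sites)), function(i) as.list(catalog$sites[i, ])),
    cores = lapply(seq_len(nrow(catalog$cores)), function(i) as.list(catalog$cores[i, ])),
    driver_set = lapply(seq_len(nrow(catalog$driver_set)), function(i) {
      d <- catalog$driver_set[i, ]
      list(name = d$name, offsets = as.integer(d$offsets[[1]]), ref = d$ref, alt = d$alt)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_catalog_yaml
#' @export
read_catalog_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  m <- promoter_map(contig = y$map$contig, atg_anchor = y$map$atg_anchor,
                    gene_strand = y$map$gene_strand,
                    assembly_tag = y$map$assembly_tag)
  sites <- do.call(rbind, lapply(y$sites, function(s)
    data.frame(offset = as.integer(s$offset), role = s$role,
               ref = s$ref, alt = if (is.null(s$alt)) NA_character_ else s$alt,
               linked_core = as.integer(s$linked_core))))
  cores <- do.call(rbind, lapply(y$cores, function(s)
    data.frame(core_offset = as.integer(s$core_offset), kind = s$kind,
               requires = s$requires)))
  drv <- do.call(rbind, lapply(y$driver_set, function(d)
    data.frame(name = d$name, offsets = I(list(as.integer(d$offsets))),
               ref = d$ref, alt = d$alt)))
  obj <- structure(
    list(map = m, window = as.integer(y$window), wt_sequence = y$wt_sequence,
         sites = sites, cores = cores, driver_set = drv),
    class = "site_catalog")
  validate_site_catalog(obj)
  obj
}
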