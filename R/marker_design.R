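#' Primer and product constraints for marker design
#'
#' Defaults encode a standard EST-SSR marker design recipe: primers of
#' 18-22 bp (optimum 20), melting temperature 50-60 degrees C with at most a
#' 4 degree difference within a pair, PCR product of 100-300 bp, and at least
#' 150 bp of sequence flanking the repeat on each side.
#'
#' @param min_len,opt_len,max_len Primer length bounds in bases.
#' @param tm_min,tm_max Melting-temperature window, degrees C.
#' @param tm_diff_max Maximum forward/reverse Tm difference, degrees C.
#' @param product_min,product_max PCR product length bounds, bp.
#' @param min_flank Minimum flank on each side of the repeat, bp.
#' @param strict_flank If `TRUE`, flanks must be strictly greater than
#'   `min_flank`; the default inclusive reading requires `>= min_flank`.
#' @param max_homopolymer Longest allowed single-base run within a primer;
#'   candidates containing a run of this length plus one are rejected.
#' @param max_3prime_gc_run Longest allowed run of an identical G or C
#'   terminating the 3' end of a primer.
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(min_len = 18L, opt_len = 20L, max_len = 22L,
                        tm_min = 50, tm_max = 60, tm_diff_max = 4,
                        product_min = 100L, product_max = 300L,
                        min_flank = 150L, strict_flank = FALSE,
                        max_homopolymer = 4L, max_3prime_gc_run = 2L) {
  if (!(min_len <= opt_len && opt_len <= max_len))
    stop("need min_len <= opt_len <= max_len")
  if (!(tm_min < tm_max)) stop("need tm_min < tm_max")
  if (!(product_min < product_max)) stop("need product_min < product_max")
  structure(list(min_len = as.integer(min_len), opt_len = as.integer(opt_len),
                 max_len = as.integer(max_len), tm_min = tm_min,
                 tm_max = tm_max, tm_diff_max = tm_diff_max,
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 min_flank = as.integer(min_flank),
                 strict_flank = isTRUE(strict_flank),
                 max_homopolymer = as.integer(max_homopolymer),
                 max_3prime_gc_run = as.integer(max_3prime_gc_run)),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf(paste0("<primer_spec> len %d-%d (opt %d), Tm %.0f-%.0f ",
                     "(dTm <= %.0f), product %d-%d bp, flank %s%d bp\n"),
              x$min_len, x$max_len, x$opt_len, x$tm_min, x$tm_max,
              x$tm_diff_max, x$product_min, x$product_max,
              if (x$strict_flank) ">" else ">=", x$min_flank))
  invisible(x)
}

#' Flanking-length filter for a locus
#'
#' A repeat can be turned into a marker only when enough flanking sequence
#' exists on both sides to place primers.  The inclusive reading
#' (`flank >= min_flank`, the default) or the strict one (`>`) is chosen in
#' the [primer_spec()].
#'
#' @param locus One row of a locus table (list or single-row data.frame with
#'   `left_flank` and `right_flank`).
#' @param spec A [primer_spec()].
#' @return `TRUE` when both flanks pass.
#' @export
flank_filter <- function(locus, spec = primer_spec()) {
  lf <- locus$left_flank; rf <- locus$right_flank
  if (spec$strict_flank) lf > spec$min_flank & rf > spec$min_flank
  else lf >= spec$min_flank & rf >= spec$min_flank
}

#' Primer melting temperature
#'
#' Deterministic closed-form Tm: the Wallace rule `2(A+T) + 4(G+C)` for
#' primers shorter than 14 bases, and the GC-corrected formula
#' `64.9 + 41 * (GC - 16.4) / length` otherwise.  Vectorized.
#'
#' @param primer Character vector of primer sequences over `{A,C,G,T}`,
#'   each at least 8 bases.
#' @return Numeric vector of melting temperatures in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGT")        # 36
#' melting_temperature(strrep("ACGTA", 4))    # 64.9 + 41*(8-16.4)/20
#' @export
melting_temperature <- function(primer) {
  if (any(grepl("[^ACGT]", primer)))
    stop("primer contains characters outside {A,C,G,T}")
  len <- nchar(primer)
  if (any(len < 8L)) stop("primers must be at least 8 bases")
  gc <- nchar(gsub("[AT]", "", primer))
  ifelse(len < 14L, 2 * (len - gc) + 4 * gc, 64.9 + 41 * (gc - 16.4) / len)
}

# Primer-quality screen: no homopolymer run longer than allowed, and the
# 3'-terminal base, when G or C, must not close a longer-than-allowed run of
# itself (a strong polymerase clamp prone to mispriming).
primer_quality_ok <- function(primer, spec) {
  homo <- sprintf("([ACGT])\\1{%d}", spec$max_homopolymer)
  bad_run <- grepl(homo, primer, perl = TRUE)
  clamp <- sprintf("(G{%d}|C{%d})$", spec$max_3prime_gc_run + 1L,
                   spec$max_3prime_gc_run + 1L)
  bad_clamp <- grepl(clamp, primer, perl = TRUE)
  !bad_run & !bad_clamp
}

# All acceptable single-primer candidates within [lo, hi] of `seq`.
# For reverse candidates the primer sequence is the reverse complement of
# the binding site.  Returns start/end of the binding site (1-based), the
# primer string and its Tm.
enumerate_primers <- function(seq, lo, hi, spec, reverse = FALSE) {
  out <- list(start = integer(0), end = integer(0),
              primer = character(0), tm = numeric(0))
  if (hi - lo + 1L < spec$min_len) return(out)
  starts <- integer(0); ends <- integer(0)
  for (l in spec$min_len:spec$max_len) {
    if (hi - l + 1L < lo) next
    s <- seq.int(lo, hi - l + 1L)
    starts <- c(starts, s); ends <- c(ends, s + l - 1L)
  }
  if (length(starts) == 0L) return(out)
  site <- substring(seq, starts, ends)
  primer <- if (reverse) revcomp_chr(site) else site
  ok <- !grepl("N", primer, fixed = TRUE)
  tm <- rep(NA_real_, length(primer))
  tm[ok] <- melting_temperature(primer[ok])
  ok <- ok & tm >= spec$tm_min & tm <= spec$tm_max & primer_quality_ok(primer, spec)
  list(start = starts[ok], end = ends[ok], primer = primer[ok], tm = tm[ok])
}

#' Design a primer pair for one microsatellite locus
#'
#' Exhaustively enumerates forward primer candidates in the left flank and
#' reverse candidates in the right flank (all lengths from `min_len` to
#' `max_len`), keeps pairs satisfying every [primer_spec()] constraint
#' (Tm window, pair Tm difference, product size with the product spanning
#' the whole repeat, homopolymer and 3'-run quality rules), and returns the
#' pair whose mean Tm is closest to the midpoint of the Tm window.  Ties are
#' broken by total deviation from the optimal primer length, then by the
#' leftmost forward start, the leftmost reverse end, and finally the shorter
#' forward then reverse primer, so the result is a deterministic function of
#' its inputs.
#'
#' @param locus One row of a locus table.
#' @param record The source sequence (character or `DNAString`); must be the
#'   sequence `locus$seq_id` refers to.
#' @param spec A [primer_spec()].
#' @return A list of class `marker_candidate` with the locus fields plus
#'   `fwd`, `rev` (reverse primer 5'->3' on the reverse strand), `fwd_tm`,
#'   `rev_tm`, `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (binding-site
#'   coordinates, 1-based) and `product_len`; or `NULL` when no pair passes.
#' @export
design_marker <- function(locus, record, spec = primer_spec()) {
  seq <- as.character(record)
  if (!flank_filter(locus, spec)) return(NULL)
  fwd <- enumerate_primers(seq, 1L, locus$start - 1L, spec, reverse = FALSE)
  if (length(fwd$start) == 0L) return(NULL)
  rev <- enumerate_primers(seq, locus$end + 1L, nchar(seq), spec, reverse = TRUE)
  if (length(rev$start) == 0L) return(NULL)

  nf <- length(fwd$start); nr <- length(rev$start)
  fi <- rep(seq_len(nf), each = nr)
  ri <- rep(seq_len(nr), times = nf)
  product <- rev$end[ri] - fwd$start[fi] + 1L
  dtm <- abs(fwd$tm[fi] - rev$tm[ri])
  ok <- product >= spec$product_min & product <= spec$product_max &
    dtm <= spec$tm_diff_max
  if (!any(ok)) return(NULL)
  fi <- fi[ok]; ri <- ri[ok]; product <- product[ok]

  mid <- (spec$tm_min + spec$tm_max) / 2
  s1 <- abs((fwd$tm[fi] + rev$tm[ri]) / 2 - mid)
  s2 <- abs((fwd$end[fi] - fwd$start[fi] + 1L) - spec$opt_len) +
    abs((rev$end[ri] - rev$start[ri] + 1L) - spec$opt_len)
  flen <- fwd$end[fi] - fwd$start[fi] + 1L
  rlen <- rev$end[ri] - rev$start[ri] + 1L
  best <- order(s1, s2, fwd$start[fi], rev$end[ri], flen, rlen)[1]
  f <- fi[best]; r <- ri[best]
  structure(list(
    seq_id = locus$seq_id, locus_start = locus$start, locus_end = locus$end,
    motif = locus$motif, class = locus$class, unit_len = locus$unit_len,
    repeats = locus$repeats,
    fwd = fwd$primer[f], rev = rev$primer[r],
    fwd_tm = fwd$tm[f], rev_tm = rev$tm[r],
    fwd_start = fwd$start[f], fwd_end = fwd$end[f],
    rev_start = rev$start[r], rev_end = rev$end[r],
    product_len = as.integer(product[best])
  ), class = "marker_candidate")
}

#' @export
print.marker_candidate <- function(x, ...) {
  cat(sprintf("<marker_candidate> %s (%s)x%d on %s\n", x$motif, x$class,
              x$repeats, x$seq_id))
  cat(sprintf("  F 5'-%s-3'  Tm %.2f\n", x$fwd, x$fwd_tm))
  cat(sprintf("  R 5'-%s-3'  Tm %.2f\n", x$rev, x$rev_tm))
  cat(sprintf("  product %d bp [%d..%d]\n", x$product_len, x$fwd_start,
              x$rev_end))
  invisible(x)
}

#' Re-verify every constraint on a designed marker
#'
#' Independent recheck of a [design_marker()] result against its source
#' sequence and spec: primer sequences match their binding sites, lengths,
#' Tm window, pair Tm difference, product size and span, quality rules.
#'
#' @param cand A `marker_candidate`.
#' @param record The source sequence.
#' @param spec A [primer_spec()].
#' @return `TRUE` if all constraints hold, otherwise `FALSE` with a
#'   `failures` attribute naming the violated checks.
#' @export
verify_marker <- function(cand, record, spec = primer_spec()) {
  seq <- as.character(record)
  checks <- c(
    fwd_site = substr(seq, cand$fwd_start, cand$fwd_end) == cand$fwd,
    rev_site = revcomp_chr(substr(seq, cand$rev_start, cand$rev_end)) == cand$rev,
    fwd_len = nchar(cand$fwd) >= spec$min_len && nchar(cand$fwd) <= spec$max_len,
    rev_len = nchar(cand$rev) >= spec$min_len && nchar(cand$rev) <= spec$max_len,
    fwd_tm = cand$fwd_tm >= spec$tm_min && cand$fwd_tm <= spec$tm_max &&
      isTRUE(all.equal(cand$fwd_tm, melting_temperature(cand$fwd))),
    rev_tm = cand$rev_tm >= spec$tm_min && cand$rev_tm <= spec$tm_max &&
      isTRUE(all.equal(cand$rev_tm, melting_temperature(cand$rev))),
    tm_diff = abs(cand$fwd_tm - cand$rev_tm) <= spec$tm_diff_max,
    product_len = cand$product_len == cand$rev_end - cand$fwd_start + 1L,
    product_range = cand$product_len >= spec$product_min &&
      cand$product_len <= spec$product_max,
    spans_locus = cand$fwd_end < cand$locus_start &&
      cand$rev_start > cand$locus_end,
    quality = all(primer_quality_ok(c(cand$fwd, cand$rev), spec))
  )
  ok <- all(checks)
  if (!ok) attr(ok, "failures") <- names(checks)[!checks]
  ok
}

#' Design markers for a locus table
#'
#' Applies [flank_filter()] and [design_marker()] to every locus.
#'
#' @param loci Locus data.frame.
#' @param records Named source sequences.
#' @param spec A [primer_spec()].
#' @param unit_lens Unit lengths to design for; mononucleotide repeats are
#'   often excluded in practice, so a mask is exposed rather than a policy.
#'   Default designs for all unit lengths 1-6.
#' @return data.frame with one row per designed marker: `marker_id`,
#'   `seq_id`, `class`, `unit_len`, `repeats`, `fwd`, `rev`, `fwd_tm`,
#'   `rev_tm`, `product_len`.
#' @export
design_markers <- function(loci, records, spec = primer_spec(),
                           unit_lens = 1:6) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  chr <- as.character(records)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    if (!locus$unit_len %in% unit_lens) next
    cand <- design_marker(locus, chr[[locus$seq_id]], spec)
    if (is.null(cand)) next
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = cand$seq_id, class = cand$class, unit_len = cand$unit_len,
      repeats = cand$repeats, fwd = cand$fwd, rev = cand$rev,
      fwd_tm = round(cand$fwd_tm, 2), rev_tm = round(cand$rev_tm, 2),
      product_len = cand$product_len, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(seq_id = character(0), class = character(0),
               unit_len = integer(0), repeats = integer(0),
               fwd = character(0), rev = character(0), fwd_tm = numeric(0),
               rev_tm = numeric(0), product_len = integer(0))
  out <- cbind(marker_id = sprintf("mk%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a marker table as TSV
#'
#' @param markers data.frame from [design_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
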