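#' Repeat-threshold configuration
#'
#' Minimum repeat counts per unit length for calling a microsatellite, and the
#' maximum interruption distance for merging neighbouring loci into compound
#' SSRs.  The defaults are the marker-development thresholds used throughout
#' this toolkit: eleven repeats for mononucleotides, six for dinucleotides,
#' five for tri- and tetranucleotides, four for penta- and hexanucleotides,
#' with a 100 bp compound gap.
#'
#' @param min_repeats Named integer vector mapping unit lengths `"1"`..`"6"`
#'   to minimum repeat counts; all minima must be `>= 2`.
#' @param max_compound_gap Maximum gap in bp between two loci merged into one
#'   compound SSR.
#' @return An object of class `threshold_config`.
#' @examples
#' threshold_config()
#' threshold_config(min_repeats = c(`1` = 11, `2` = 5, `3` = 4,
#'                                  `4` = 4, `5` = 4, `6` = 4))
#' @export
threshold_config <- function(min_repeats = c(`1` = 11L, `2` = 6L, `3` = 5L,
                                             `4` = 5L, `5` = 4L, `6` = 4L),
                             max_compound_gap = 100L) {
  min_repeats <- as.integer(min_repeats[as.character(1:6)])
  names(min_repeats) <- as.character(1:6)
  if (anyNA(min_repeats))
    stop("min_repeats must provide a threshold for every unit length 1..6")
  if (any(min_repeats < 2L)) stop("all repeat minima must be >= 2")
  max_compound_gap <- as.integer(max_compound_gap)
  if (is.na(max_compound_gap) || max_compound_gap < 0L)
    stop("max_compound_gap must be a non-negative integer")
  structure(list(min_repeats = min_repeats,
                 max_compound_gap = max_compound_gap),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config> min repeats:",
      paste0(names(x$min_repeats), ":", x$min_repeats, collapse = " "),
      "| compound gap:", x$max_compound_gap, "bp\n")
  invisible(x)
}

empty_locus_table <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             motif = character(0), class = character(0),
             unit_len = integer(0), repeats = integer(0),
             left_flank = integer(0), right_flank = integer(0),
             compound_id = character(0), stringsAsFactors = FALSE)
}

# Leftmost-greedy scan of one sequence at one unit length.  A backreference
# regex locates candidate runs; a match whose unit is non-primitive is
# discarded and the scan resumes one position past its start, reproducing
# exact per-position semantics without per-position cost.
scan_unit_length <- function(seq, k, min_rep) {
  pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_rep - 1L)
  L <- nchar(seq)
  starts <- integer(0); ends <- integer(0); units <- character(0)
  from <- 1L
  while (from + k * min_rep - 1L <= L) {
    m <- regexpr(pat, substr(seq, from, L), perl = TRUE)
    if (m == -1L) break
    st <- from + as.integer(m) - 1L
    len <- attr(m, "match.length")
    unit <- substr(seq, st, st + k - 1L)
    if (is_primitive(unit)) {
      starts <- c(starts, st); ends <- c(ends, st + len - 1L)
      units <- c(units, unit)
      from <- st + len
    } else {
      from <- st + 1L
    }
  }
  list(start = starts, end = ends, unit = units)
}

#' Find perfect microsatellites in one sequence
#'
#' Detects every maximal perfect tandem repeat of a primitive unit of length
#' 1-6 bp that meets its unit-length repeat threshold.  Runs containing `N`
#' are broken at the `N`; no locus spans one.  When the same stretch is
#' reportable at several unit lengths, only the smallest-unit interpretation
#' is kept, and reported intervals never overlap (loci of different classes
#' may abut).  Loci at sequence boundaries (zero flank) are reported;
#' flank-based marker filtering is a separate, later step.
#'
#' @param seq A single sequence: character string or [Biostrings::DNAString].
#'   Must be normalized (uppercase, ambiguity as `N`), as [read_fasta()]
#'   produces.
#' @param seq_id Identifier recorded in the output.
#' @param cfg A [threshold_config()].
#' @return Locus data.frame sorted by `(start, unit_len)` with columns
#'   `seq_id`, `start`, `end` (1-based inclusive), `motif` (unit as observed
#'   at the locus start), `class` (canonical label), `unit_len`, `repeats`,
#'   `left_flank`, `right_flank`, `compound_id` (`NA` until
#'   [merge_compound()]).
#' @examples
#' find_perfect_ssrs(paste0("CCCC", strrep("AG", 6), "CCCC"), "toy")
#' @export
find_perfect_ssrs <- function(seq, seq_id = "seq", cfg = threshold_config()) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L, inherits(cfg, "threshold_config"))
  L <- nchar(seq)
  cand <- list()
  for (k in 1:6) {
    sc <- scan_unit_length(seq, k, cfg$min_repeats[[as.character(k)]])
    if (length(sc$start) > 0L)
      cand[[length(cand) + 1L]] <- data.frame(
        start = sc$start, end = sc$end, unit = sc$unit, unit_len = k,
        stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) return(empty_locus_table())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$unit_len, cand$start), , drop = FALSE]

  # cross-unit-length resolution: smallest unit wins, intervals never overlap
  keep <- logical(nrow(cand))
  acc_start <- integer(0); acc_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= acc_end & cand$end[i] >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, cand$start[i])
      acc_end <- c(acc_end, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    seq_id = seq_id, start = cand$start, end = cand$end, motif = cand$unit,
    class = motif_class_label(cand$unit), unit_len = cand$unit_len,
    repeats = as.integer((cand$end - cand$start + 1L) %/% cand$unit_len),
    left_flank = cand$start - 1L, right_flank = L - cand$end,
    compound_id = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find perfect microsatellites in a sequence collection
#'
#' Applies [find_perfect_ssrs()] to every record and row-binds the results.
#'
#' @param records Named [Biostrings::DNAStringSet] or named character vector.
#' @param cfg A [threshold_config()].
#' @param merge_compounds If `TRUE` (default) compound groups are annotated
#'   via [merge_compound()].
#' @return Locus data.frame (see [find_perfect_ssrs()]), sorted by
#'   `(seq_id, start, unit_len)`.
#' @export
find_ssrs <- function(records, cfg = threshold_config(),
                      merge_compounds = TRUE) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (is.null(names(records))) stop("records must be named")
  chr <- as.character(records)
  res <- lapply(names(records), function(id)
    find_perfect_ssrs(chr[[id]], seq_id = id, cfg = cfg))
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(empty_locus_table())
  rownames(out) <- NULL
  if (merge_compounds) out <- merge_compound(out, cfg)
  out
}

#' Annotate compound microsatellites
#'
#' Consecutive loci on the same sequence whose gap (bases strictly between
#' them) is at most `cfg$max_compound_gap` are chained into one compound
#' group sharing a `compound_id`.  Groups whose members span more than one
#' motif class are flagged `"mixed"` (the classical compound SSR of different
#' motifs); single-class groups are flagged `"same_motif"`.  Loci not in any
#' group keep `compound_id = NA`.
#'
#' @param loci Locus data.frame; must be sorted by `start` within each
#'   `seq_id` (as the scanners emit), otherwise an error is raised.
#' @param cfg A [threshold_config()].
#' @return `loci` with `compound_id` and `compound_type` columns filled.
#' @export
merge_compound <- function(loci, cfg = threshold_config()) {
  if (nrow(loci) == 0L) {
    loci$compound_type <- character(0)
    return(loci)
  }
  loci$compound_id <- NA_character_
  loci$compound_type <- NA_character_
  for (sid in unique(loci$seq_id)) {
    idx <- which(loci$seq_id == sid)
    st <- loci$start[idx]; en <- loci$end[idx]
    if (is.unsorted(st)) stop("loci must be sorted by start within '", sid, "'")
    if (length(idx) == 1L) next
    gap <- st[-1] - en[-length(en)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > cfg$max_compound_gap)))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < 2L) next
      cid <- sprintf("%s.c%d", sid, g + 1L)
      loci$compound_id[members] <- cid
      loci$compound_type[members] <-
        if (length(unique(loci$class[members])) > 1L) "mixed" else "same_motif"
    }
  }
  loci
}

#' Write a locus table as TSV (1-based inclusive coordinates)
#'
#' @param loci Locus data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  out <- loci
  names(out)[names(out) == "start"] <- "start1"
  names(out)[names(out) == "end"] <- "end1"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a locus table written by [write_loci_tsv()]
#'
#' @param path TSV path.
#' @return Locus data.frame with internal column names restored.
#' @export
read_loci_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "-",
                          colClasses = "character")
  names(df)[names(df) == "start1"] <- "start"
  names(df)[names(df) == "end1"] <- "end"
  for (col in c("start", "end", "unit_len", "repeats",
                "left_flank", "right_flank"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  df
}
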