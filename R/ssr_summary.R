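#' Motif classes broken out individually in repeat summaries
#'
#' The classes conventionally reported as their own rows in genic-SSR
#' repeat-count tables for legume transcriptomes; everything else is pooled
#' into an `Others` row per unit length.  Labels follow this package's
#' canonical labelling rule (see [canonical_motif()]).
#'
#' @return Character vector of class labels.
#' @export
default_summary_classes <- function() {
  c("A/T", "C/G",
    "AG/CT", "AT/AT", "AC/GT",
    "AAG/CTT", "ATC/GAT", "ACC/GGT", "AGC/GCT", "AAC/GTT",
    "AAAG/CTTT", "ACTC/GAGT", "AAAT/ATTT", "AATG/CATT",
    "AAGAG/CTCTT", "AAAAT/ATTTT", "AAAAG/CTTTT", "AACAC/GTGTT",
    "AAACCC/GGGTTT", "AATGGC/GCCATT", "AAAGAG/CTCTTT", "AACTTG/CAAGTT",
    "ACAGCC/GGCTGT")
}

repeat_bin_labels <- function() c("4", "5", "6", "7", "8", "9", "10", ">10")

bin_repeats <- function(repeats) {
  lab <- as.character(repeats)
  lab[repeats >= 11L] <- ">10"
  lab[repeats < 4L] <- "<4"
  lab
}

#' Summarize microsatellite loci by motif class and repeat count
#'
#' Builds the classical motif-class-by-repeat-count contingency table: one
#' row per motif class (classes not in `classes` pooled as `Others` within
#' their unit length), columns for repeat counts 4-10 and `>10` (meaning
#' `>= 11`), plus row totals, per-unit-length totals and the grand total.
#' With non-default thresholds loci of fewer than four repeats can occur;
#' they are reported in an extra leading `<4` column rather than dropped.
#'
#' @param loci Locus data.frame from [find_ssrs()].
#' @param classes Class labels given individual rows; defaults to
#'   [default_summary_classes()].
#' @return An object of class `repeat_summary`: list with `table` (data.frame
#'   with `unit_len`, `class`, one column per repeat bin, `total`),
#'   `unit_len_totals` (named integer vector) and `grand_total`.
#' @export
summarize_ssrs <- function(loci, classes = default_summary_classes()) {
  bins <- repeat_bin_labels()
  if (nrow(loci) > 0L && any(loci$repeats < 4L)) bins <- c("<4", bins)
  rows <- list()
  for (k in sort(unique(loci$unit_len))) {
    sub <- loci[loci$unit_len == k, , drop = FALSE]
    cls <- ifelse(sub$class %in% classes, sub$class, "Others")
    shown <- intersect(classes, unique(cls))
    if ("Others" %in% cls) shown <- c(shown, "Others")
    for (cl in shown) {
      rc <- bin_repeats(sub$repeats[cls == cl])
      counts <- vapply(bins, function(b) sum(rc == b), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        unit_len = k, class = cl, t(counts), total = sum(counts),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(unit_len = integer(0), class = character(0),
               t(stats::setNames(integer(length(bins)), bins))[0, , drop = FALSE],
               total = integer(0), check.names = FALSE)
  names(tab)[3:(2 + length(bins))] <- bins
  ult <- vapply(split(tab$total, tab$unit_len), sum, numeric(1))
  structure(
    list(table = tab,
         unit_len_totals = stats::setNames(as.integer(ult), names(ult)),
         grand_total = as.integer(sum(tab$total))),
    class = "repeat_summary"
  )
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("Repeat-count summary (", x$grand_total, " loci)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("per unit length:",
      paste0(names(x$unit_len_totals), "bp:", x$unit_len_totals,
             collapse = "  "), "\n")
  invisible(x)
}

#' Write a repeat summary as TSV
#'
#' @param summary A `repeat_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_summary <- function(summary, path) {
  stopifnot(inherits(summary, "repeat_summary"))
  utils::write.table(summary$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Count SSR-bearing sequences
#'
#' Distinct-sequence tallies used as the headline numbers of an SSR survey:
#' sequences containing at least one SSR; sequences containing at least two
#' independent SSRs, where a compound group counts as one independent unit;
#' and sequences containing at least one compound SSR of different motif
#' classes (same-motif compounds are not counted here, matching the usual
#' reporting of "compound SSRs of different motifs").
#'
#' @param loci Locus data.frame carrying `compound_id`/`compound_type`
#'   annotation from [merge_compound()]; an error is raised if the
#'   annotation is absent.
#' @return Named integer vector `c(n_with_ssr, n_with_2plus,
#'   n_compound_unigenes)`.
#' @export
count_ssr_unigenes <- function(loci) {
  if (is.null(loci$compound_type))
    stop("loci lack compound annotation; run merge_compound() first")
  if (nrow(loci) == 0L)
    return(c(n_with_ssr = 0L, n_with_2plus = 0L, n_compound_unigenes = 0L))
  per_seq <- split(loci, loci$seq_id)
  units <- vapply(per_seq, function(d) {
    length(unique(ifelse(is.na(d$compound_id),
                         paste0("s", seq_len(nrow(d))), d$compound_id)))
  }, integer(1))
  has_mixed <- vapply(per_seq, function(d)
    any(!is.na(d$compound_type) & d$compound_type == "mixed"), logical(1))
  c(n_with_ssr = length(per_seq),
    n_with_2plus = sum(units >= 2L),
    n_compound_unigenes = sum(has_mixed))
}

#' Sweep the compound-merging gap
#'
#' Recomputes compound annotation and sequence tallies across a range of
#' interruption distances.  Useful because published compound-SSR counts
#' rarely state the gap they were called under.
#'
#' @param loci Locus data.frame (compound annotation is recomputed).
#' @param gaps Integer vector of gaps in bp to evaluate.
#' @param cfg Base [threshold_config()] supplying the repeat minima.
#' @return data.frame with one row per gap: `gap`, `n_with_ssr`,
#'   `n_with_2plus`, `n_compound_unigenes`.
#' @export
compound_gap_sweep <- function(loci, gaps = seq(0L, 150L, by = 10L),
                               cfg = threshold_config()) {
  res <- lapply(gaps, function(g) {
    cfg$max_compound_gap <- as.integer(g)
    counts <- count_ssr_unigenes(merge_compound(loci, cfg))
    data.frame(gap = as.integer(g), t(counts), check.names = FALSE)
  })
  do.call(rbind, res)
}
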