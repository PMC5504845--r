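#' Read a genotype table
#'
#' Parses an accession-by-marker TSV of co-dominant allele calls.  The first
#' column holds accession ids, the header row holds marker ids.  A cell is
#' `"a1/a2"` (unordered allele pair, typically band sizes), `"a1"`
#' (homozygote shorthand, expanded to an identical pair) or `"-"` (missing).
#' Allele labels are opaque strings; no size arithmetic is performed.
#'
#' @param path TSV path.
#' @return An object of class `genotype_matrix`: list with `accessions`,
#'   `markers`, and character matrices `a1`, `a2` (accessions x markers,
#'   `NA` where missing).
#' @export
read_genotypes <- function(path) {
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nfields)) != 1L)
    stop("ragged genotype table: rows have differing field counts")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("genotype table needs an accession column and at least one marker")
  acc <- df[[1]]
  if (anyDuplicated(acc)) stop("duplicate accession id(s)")
  markers <- colnames(df)[-1]
  calls <- as.matrix(df[, -1, drop = FALSE])
  parse_genotype_calls(calls, acc, markers)
}

parse_genotype_calls <- function(calls, accessions, markers) {
  a1 <- a2 <- matrix(NA_character_, nrow = length(accessions),
                     ncol = length(markers),
                     dimnames = list(accessions, markers))
  miss <- is.na(calls) | calls == "-" | calls == ""
  cells <- calls[!miss]
  # strsplit drops trailing empty fields, so catch empty labels up front
  bad <- grepl("^/|/$|//", cells) | grepl("^\\s*$", cells)
  parts <- strsplit(cells, "/", fixed = TRUE)
  bad <- bad | vapply(parts, function(p)
    length(p) > 2L || length(p) == 0L || any(!nzchar(p)), logical(1))
  if (any(bad)) stop("malformed genotype call(s): ",
                     paste(unique(cells[bad]), collapse = ", "))
  a1[!miss] <- vapply(parts, `[[`, character(1), 1L)
  a2[!miss] <- vapply(parts, function(p) p[[length(p)]], character(1))
  structure(list(accessions = accessions, markers = markers, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d markers (%.1f%% missing)\n",
              length(x$accessions), length(x$markers),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]; homozygotes are written in shorthand and
#' missing calls as `"-"`.
#'
#' @param g A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  cells <- ifelse(is.na(g$a1), "-",
                  ifelse(g$a1 == g$a2, g$a1, paste0(g$a1, "/", g$a2)))
  df <- data.frame(accession = g$accessions, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("accession", g$markers)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

marker_calls <- function(g, marker) {
  if (!marker %in% g$markers) stop("unknown marker: ", marker)
  j <- match(marker, g$markers)
  ok <- !is.na(g$a1[, j])
  if (!any(ok)) stop("marker '", marker, "' has no scored calls")
  list(a1 = g$a1[ok, j], a2 = g$a2[ok, j])
}

#' Allele frequencies at one marker
#'
#' Frequencies over the `2 * n_scored` allele observations of the
#' non-missing calls.
#'
#' @param g A `genotype_matrix`.
#' @param marker Marker id.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
allele_frequencies <- function(g, marker) {
  calls <- marker_calls(g, marker)
  tab <- table(c(calls$a1, calls$a2))
  freqs <- as.numeric(tab) / sum(tab)
  stats::setNames(freqs, names(tab))
}

#' Observed heterozygosity at one marker
#'
#' Fraction of scored (non-missing) calls whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return A number in `[0, 1]`.
#' @export
observed_heterozygosity <- function(g, marker) {
  calls <- marker_calls(g, marker)
  mean(calls$a1 != calls$a2)
}

#' Polymorphic information content
#'
#' The bounded marker-informativeness measure of Botstein et al.:
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed here through
#' the power-sum identity `sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 -
#' sum p_i^4`.  `PIC` is 0 for a monomorphic marker and always below 1.
#'
#' @param freqs Numeric vector of allele frequencies; must be non-negative
#'   and sum to 1 (tolerance `tol`).
#' @param tol Tolerance on the frequency sum.
#' @return A number in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))      # 0.375
#' pic(rep(1 / 3, 3))    # 16/27
#' @export
pic <- function(freqs, tol = 1e-8) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > tol)
    stop("allele frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Per-marker polymorphism statistics and panel summary
#'
#' Computes the classical marker-validation panel statistics: number of
#' distinct alleles (Na), observed heterozygosity (Ho) and polymorphic
#' information content (PIC) for every marker, with unweighted panel means
#' and standard deviations.  Missing calls are excluded listwise per marker.
#'
#' @param g A `genotype_matrix`.
#' @return A list of class `marker_stats`: `per_marker` (data.frame with
#'   `marker_id`, `na`, `ho`, `pic`, `n_scored`) and `panel` (data.frame
#'   with rows `mean` and `sd` over the `na`, `ho`, `pic` columns).
#' @export
summarize_markers <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(g$markers) < 1L) stop("no markers in genotype matrix")
  rows <- lapply(g$markers, function(m) {
    calls <- marker_calls(g, m)
    freqs <- allele_frequencies(g, m)
    data.frame(marker_id = m, na = length(freqs),
               ho = observed_heterozygosity(g, m), pic = pic(freqs),
               n_scored = length(calls$a1), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  panel <- data.frame(
    na = c(mean(per$na), stats::sd(per$na)),
    ho = c(mean(per$ho), stats::sd(per$ho)),
    pic = c(mean(per$pic), stats::sd(per$pic)),
    row.names = c("mean", "sd"))
  structure(list(per_marker = per, panel = panel), class = "marker_stats")
}

#' @export
print.marker_stats <- function(x, ...) {
  cat("Marker polymorphism statistics (", nrow(x$per_marker), " markers)\n",
      sep = "")
  print(utils::head(x$per_marker, 10), row.names = FALSE)
  if (nrow(x$per_marker) > 10) cat("  ...\n")
  cat("panel:\n")
  print(round(x$panel, 4))
  invisible(x)
}

#' Write marker statistics as TSV
#'
#' @param stats A `marker_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_stats <- function(stats, path) {
  stopifnot(inherits(stats, "marker_stats"))
  per <- stats$per_marker
  per$ho <- round(per$ho, 4); per$pic <- round(per$pic, 4)
  utils::write.table(per, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
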