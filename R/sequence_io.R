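#' Read transcript sequences from a FASTA file
#'
#' Reads a (multi-line) FASTA file into a [Biostrings::DNAStringSet].
#' Residues are uppercased; IUPAC ambiguity codes and any character outside
#' `{A,C,G,T,N}` are mapped to `N`, with one warning reporting how many
#' residues were replaced.  Record identifiers are the first whitespace-
#' delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, in file order.
#'   The attribute `n_masked` carries the number of residues mapped to `N`.
#' @details Errors on: empty file, a sequence line before the first header,
#'   duplicate ids (naming the id), and records with zero sequence length.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- head_lines[nzchar(trimws(head_lines))][1]
  if (is.na(first)) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("malformed FASTA: sequence data before the first '>' header")

  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(ss) == 0L)) {
    bad <- ids[Biostrings::width(ss) == 0L]
    stop("record(s) with no sequence: ", paste(bad, collapse = ", "))
  }

  chr <- toupper(as.character(ss))
  n_before <- vapply(gregexpr("[^ACGTN]", chr, perl = TRUE),
                     function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  n_masked <- sum(n_before)
  if (n_masked > 0L) {
    chr <- gsub("[^ACGTN]", "N", chr, perl = TRUE)
    warning(n_masked, " residue(s) outside {A,C,G,T,N} mapped to N")
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  attr(out, "n_masked") <- n_masked
  out
}

#' Write sequences to a FASTA file
#'
#' @param records A named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(records, filepath = path, width = width)
  invisible(path)
}

#' Default transcript length bins
#'
#' The conventional reporting bins for transcriptome assemblies with a 201 bp
#' assembler floor: 201-500, 501-1000, 1001-1500, 1501-2000 and >2000 bp.
#' [assembly_stats()] prepends an extra `<=200` bin whenever shorter sequences
#' are present, so no record is ever dropped from the histogram.
#'
#' @return Integer vector of bin lower bounds (the final bin is open-ended).
#' @export
default_length_bins <- function() c(201L, 501L, 1001L, 1501L, 2001L)

#' Assembly summary statistics
#'
#' Computes the sequence count, total and mean length, N50, GC fraction and a
#' length histogram for a set of assembled sequences.  N50 is the smallest
#' length `L` such that sequences of length `>= L` together contain at least
#' half of the total assembled bases; it is computed by a descending-length
#' cumulative sum with the half-total threshold kept exact (`2 * cumsum >=
#' total`), so odd totals never suffer integer truncation.  The GC fraction
#' denominator excludes `N` residues, which carry no composition information.
#'
#' @param records A named [Biostrings::DNAStringSet] or named character vector.
#' @param bins Integer vector of bin lower bounds, strictly increasing; each
#'   bin spans up to the next bound minus one and the last bin is open-ended.
#'   Sequences below `bins[1]` are counted in a leading `<=bins[1]-1` bin.
#' @return An object of class `assembly_stats`: a list with `n_seqs`,
#'   `total_bp`, `mean_len`, `n50`, `gc_fraction` and `length_bins`
#'   (a data.frame with columns `bin` and `count`).
#' @examples
#' recs <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACG", c = "AAA",
#'                                    d = "AT", e = "GC", f = "TA"))
#' assembly_stats(recs, bins = c(2L, 4L))$n50  # 3
#' @export
assembly_stats <- function(records, bins = default_length_bins()) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  if (length(records) == 0L) stop("no sequences: cannot compute assembly statistics")
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  lens <- Biostrings::width(records)
  total <- sum(as.numeric(lens))

  dec <- sort(lens, decreasing = TRUE)
  n50 <- dec[which(2 * cumsum(as.numeric(dec)) >= total)[1]]

  freq <- Biostrings::letterFrequency(records, letters = c("G", "C", "N"))
  non_n <- total - sum(freq[, "N"])
  gc <- if (non_n > 0) sum(freq[, "G"] + freq[, "C"]) / non_n else NA_real_

  hi <- c(bins[-1] - 1L, NA)
  labels <- ifelse(is.na(hi), paste0(">", bins[length(bins)] - 1L),
                   paste0(bins, "-", hi))
  counts <- as.integer(table(cut(lens, breaks = c(bins - 0.5, Inf),
                                 labels = labels)))
  # cut() above drops sequences below the first bound; report them explicitly
  below <- sum(lens < bins[1])
  if (below > 0L) {
    labels <- c(paste0("<=", bins[1] - 1L), labels)
    counts <- c(below, counts)
  }
  lb <- data.frame(bin = labels, count = counts, stringsAsFactors = FALSE)
  stopifnot(sum(lb$count) == length(records))

  structure(
    list(n_seqs = length(records), total_bp = total,
         mean_len = total / length(records), n50 = as.integer(n50),
         gc_fraction = gc, length_bins = lb),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  sequences : %d\n", x$n_seqs))
  cat(sprintf("  total bp  : %.0f\n", x$total_bp))
  cat(sprintf("  mean len  : %.1f bp\n", x$mean_len))
  cat(sprintf("  N50       : %d bp\n", x$n50))
  cat(sprintf("  GC        : %.3f\n", x$gc_fraction))
  cat("  length distribution:\n")
  for (i in seq_len(nrow(x$length_bins)))
    cat(sprintf("    %-10s %d\n", x$length_bins$bin[i], x$length_bins$count[i]))
  invisible(x)
}

#' Write assembly statistics as a two-column TSV
#'
#' @param stats An `assembly_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  stopifnot(inherits(stats, "assembly_stats"))
  rows <- data.frame(
    metric = c("n_seqs", "total_bp", "mean_len", "n50", "gc_fraction",
               paste0("len_", stats$length_bins$bin)),
    value = c(stats$n_seqs, stats$total_bp, round(stats$mean_len, 4),
              stats$n50, round(stats$gc_fraction, 6), stats$length_bins$count),
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export microsatellite loci as GFF3
#'
#' Writes loci as `microsatellite` features with 1-based inclusive
#' coordinates and attributes `motif`, `motif_class`, `unit_len`, `repeats`
#' and (when present) `compound_id`.
#'
#' @param loci A locus table as returned by [find_ssrs()] (columns `seq_id`,
#'   `start`, `end`, `motif`, `class`, `unit_len`, `repeats`, ...).
#' @param records The source sequences (named `DNAStringSet`); every
#'   `seq_id` must be present, and sequence lengths are recorded in the
#'   GFF3 header region directives.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, records, path) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  unknown <- setdiff(unique(loci$seq_id), names(records))
  if (length(unknown) > 0L)
    stop("loci reference unknown sequence id(s): ",
         paste(unknown, collapse = ", "))
  if (nrow(loci) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = loci$seq_id,
      ranges = IRanges::IRanges(start = loci$start, end = loci$end)
    )
    S4Vectors::mcols(gr)$source <- "ssrminer"
    S4Vectors::mcols(gr)$type <- "microsatellite"
    S4Vectors::mcols(gr)$ID <- sprintf("ssr%05d", seq_len(nrow(loci)))
    S4Vectors::mcols(gr)$motif <- loci$motif
    S4Vectors::mcols(gr)$motif_class <- loci$class
    S4Vectors::mcols(gr)$unit_len <- loci$unit_len
    S4Vectors::mcols(gr)$repeats <- loci$repeats
    if (!is.null(loci$compound_id))
      S4Vectors::mcols(gr)$compound_id <- loci$compound_id
  }
  GenomeInfoDb::seqlevels(gr) <- names(records)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(records)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read microsatellite loci back from a GFF3 file
#'
#' Inverse of [write_loci_gff3()]; restores the locus table columns written
#' by the exporter (flank lengths are recomputed when `records` is given).
#'
#' @param path GFF3 path.
#' @param records Optional source sequences for flank recomputation.
#' @return A locus data.frame (possibly zero rows).
#' @export
read_loci_gff3 <- function(path, records = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_locus_table())
  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    motif = as.character(S4Vectors::mcols(gr)$motif),
    class = as.character(S4Vectors::mcols(gr)$motif_class),
    unit_len = as.integer(as.character(S4Vectors::mcols(gr)$unit_len)),
    repeats = as.integer(as.character(S4Vectors::mcols(gr)$repeats)),
    stringsAsFactors = FALSE
  )
  cid <- S4Vectors::mcols(gr)$compound_id
  df$compound_id <- if (is.null(cid)) NA_character_ else as.character(cid)
  if (!is.null(records)) {
    if (is.character(records)) records <- Biostrings::DNAStringSet(records)
    lens <- stats::setNames(Biostrings::width(records), names(records))
    df$left_flank <- df$start - 1L
    df$right_flank <- as.integer(lens[df$seq_id]) - df$end
  }
  df[order(df$seq_id, df$start, df$unit_len), , drop = FALSE]
}
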