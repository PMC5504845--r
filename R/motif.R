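#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the alphabet `{A,C,G,T,N}`.
#' Used in motif canonicalization and primer extraction, where the overhead
#' of constructing a [Biostrings::DNAString] per short motif is unwarranted.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_chr(c("AAG", "ACGT"))
#' @export
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Test whether a repeat unit is primitive
#'
#' A motif is primitive when it is not itself a whole-number repetition of a
#' shorter string: `"AT"` is primitive, `"ATAT"` is `(AT)^2` and is not.
#' Scanners must report tandem repeats with their primitive unit (a run of
#' twelve A's is a mononucleotide locus, never an `"AA"` dinucleotide locus),
#' so every candidate unit is reduced through this predicate.
#'
#' @param motif Character vector of non-empty motifs.
#' @return Logical vector, `TRUE` where the motif is primitive.
#' @examples
#' is_primitive(c("AAG", "ATAT", "A"))
#' @export
is_primitive <- function(motif) {
  if (any(!nzchar(motif))) stop("motif must be non-empty")
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 1L) return(TRUE)
    divs <- which(n %% seq_len(n - 1L) == 0L)
    for (d in divs) {
      unit <- substr(m, 1L, d)
      if (strrep(unit, n %/% d) == m) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

cyclic_rotations <- function(m) {
  n <- nchar(m)
  doubled <- paste0(m, m)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1))
}

#' Canonical motif class of a repeat unit
#'
#' Microsatellite motifs are grouped into classes that are invariant under
#' cyclic rotation and reverse complementation, the convention used when
#' tabulating repeat types: `GA`, `AG`, `TC` and `CT` all belong to one class.
#' The canonical representative is the lexicographically smallest string among
#' all rotations of the motif and all rotations of its reverse complement; the
#' display label is `"canonical/revcomp(canonical)"`, e.g. `"AAG/CTT"`.
#'
#' @param motif A single primitive motif over `{A,C,G,T}`, length 1 to 6.
#' @return A list of class `motif_class` with elements `canonical`, `label`
#'   and `unit_len`.
#' @examples
#' canonical_motif("GA")$label   # "AG/CT"
#' canonical_motif("CTT")$label  # "AAG/CTT"
#' @export
canonical_motif <- function(motif) {
  if (length(motif) != 1L || !is.character(motif))
    stop("motif must be a single character string")
  n <- nchar(motif)
  if (n < 1L || n > 6L) stop("motif length must be between 1 and 6")
  if (grepl("[^ACGT]", motif))
    stop("motif must contain only A, C, G, T (got '", motif, "')")
  if (!is_primitive(motif))
    stop("motif '", motif, "' is not primitive; reduce to its repeat unit first")
  cands <- c(cyclic_rotations(motif), cyclic_rotations(revcomp_chr(motif)))
  canon <- min(cands)
  structure(
    list(canonical = canon,
         label = paste0(canon, "/", revcomp_chr(canon)),
         unit_len = n),
    class = "motif_class"
  )
}

#' @export
print.motif_class <- function(x, ...) {
  cat("<motif_class> ", x$label, " (unit ", x$unit_len, " bp)\n", sep = "")
  invisible(x)
}

#' Canonical class labels for a vector of motifs
#'
#' Vectorized companion of [canonical_motif()], returning display labels only.
#'
#' @param motif Character vector of primitive motifs.
#' @return Character vector of class labels such as `"AG/CT"`.
#' @export
motif_class_label <- function(motif) {
  vapply(motif, function(m) canonical_motif(m)$label, character(1),
         USE.NAMES = FALSE)
}
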