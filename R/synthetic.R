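# Run code under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' A default panel of repeat implants
#'
#' One implant per unit length at its calling threshold plus longer variants,
#' cycled to the requested count.  Used as the default truth set for scanner
#' validation.
#'
#' @param n Number of implants.
#' @return data.frame with columns `motif` and `repeats`.
#' @export
default_implants <- function(n = 12L) {
  base <- data.frame(
    motif = c("A", "AG", "AAG", "AAAG", "AAGAG", "AAACCC",
              "AT", "ATC", "AC", "ACTC", "AACAC", "AATGGC"),
    repeats = c(11L, 6L, 5L, 5L, 4L, 4L, 8L, 7L, 6L, 5L, 4L, 4L),
    stringsAsFactors = FALSE)
  base[rep(seq_len(nrow(base)), length.out = n), , drop = FALSE]
}

#' Plan for synthetic sequences with implanted microsatellites
#'
#' Describes a seed-reproducible synthetic transcript set: i.i.d. background
#' at a given GC content, lognormal sequence lengths truncated to a range,
#' and a list of repeat implants with known motif, count and position.  The
#' defaults emulate an assembled plant transcriptome: GC 0.467, lengths with
#' a 201 bp floor and a median near 600 bp.
#'
#' @param n_seqs Number of sequences.
#' @param implants data.frame with columns `motif`, `repeats` and optionally
#'   `seq` (1-based target sequence index; default round-robin) and `offset`
#'   (1-based implant start; default centred).  Motifs must be primitive.
#' @param gc_background Background GC fraction.
#' @param meanlog,sdlog Lognormal length parameters.
#' @param min_len,max_len Truncation bounds on sequence length, bp.
#' @param clean_flank Width in bp of the window on each side of an implant
#'   kept free of chance threshold-passing repeats (by rejection sampling).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `implant_plan`.
#' @export
implant_plan <- function(n_seqs = 200L,
                         implants = default_implants(min(n_seqs, 12L)),
                         gc_background = 0.467, meanlog = log(600),
                         sdlog = 0.7, min_len = 201L, max_len = 3000L,
                         clean_flank = 160L, seed = 1L) {
  stopifnot(n_seqs >= 1L, gc_background > 0, gc_background < 1)
  if (nrow(implants) > 0L) {
    if (!all(is_primitive(implants$motif)))
      stop("implanted motifs must be primitive")
    if (is.null(implants$seq))
      implants$seq <- ((seq_len(nrow(implants)) - 1L) %% n_seqs) + 1L
    if (is.null(implants$offset)) implants$offset <- NA_integer_
    if (any(implants$seq < 1L | implants$seq > n_seqs))
      stop("implant seq index out of range")
  }
  structure(list(n_seqs = as.integer(n_seqs), implants = implants,
                 gc_background = gc_background, meanlog = meanlog,
                 sdlog = sdlog, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 clean_flank = as.integer(clean_flank),
                 seed = as.integer(seed)),
            class = "implant_plan")
}

# Chance repeats near an implant could extend or merge with it; resample the
# background of a sequence until the window around each implant is clean.
window_is_clean <- function(seq, wstart, wend, istart, iend, motif, repeats,
                            cfg) {
  win <- substr(seq, wstart, wend)
  loci <- find_perfect_ssrs(win, "w", cfg)
  if (nrow(loci) != 1L) return(FALSE)
  loci$start + wstart - 1L == istart && loci$end + wstart - 1L == iend &&
    loci$motif == motif && loci$repeats == repeats
}

#' Generate synthetic sequences with known implanted repeats
#'
#' Draws i.i.d. background sequence at the plan's GC content, implants each
#' planned repeat, and rejection-samples any sequence whose window of
#' `clean_flank` bp around an implant contains chance threshold-passing
#' repeats or lets the implant extend, so the truth table is exact by
#' construction.  Chance repeats far from implants are left alone:
#' background composition stays honest and downstream comparisons reconcile
#' them against a scanner oracle rather than the implant list.
#'
#' @param plan An [implant_plan()].
#' @param cfg [threshold_config()] used for the cleanliness check.
#' @param max_tries Resampling attempts per sequence before erroring.
#' @return List with `records` (named `DNAStringSet`, ids `syn00001`...) and
#'   `truth` (data.frame `seq_id`, `start`, `end`, `motif`, `class`,
#'   `unit_len`, `repeats`); the plan seed is attached as attribute `seed`
#'   on `truth`.
#' @export
generate_sequences <- function(plan, cfg = threshold_config(),
                               max_tries = 200L) {
  stopifnot(inherits(plan, "implant_plan"))
  with_seed(plan$seed, {
    lens <- round(stats::rlnorm(plan$n_seqs, plan$meanlog, plan$sdlog))
    lens <- as.integer(pmin(pmax(lens, plan$min_len), plan$max_len))
    ids <- sprintf("syn%05d", seq_len(plan$n_seqs))
    imp <- plan$implants
    seqs <- character(plan$n_seqs)
    truth <- list()
    for (i in seq_len(plan$n_seqs)) {
      rows <- if (nrow(imp) > 0L) which(imp$seq == i) else integer(0)
      ins <- if (length(rows) > 0L) imp[rows, , drop = FALSE] else NULL
      if (!is.null(ins)) {
        ins$len <- nchar(ins$motif) * ins$repeats
        if (any(ins$len > lens[i]))
          lens[i] <- max(ins$len) + 2L * plan$clean_flank
        ins$offset <- ifelse(is.na(ins$offset),
                             pmax(1L, (lens[i] - ins$len) %/% 2L + 1L),
                             ins$offset)
        if (any(ins$offset + ins$len - 1L > lens[i]))
          stop("implant does not fit in sequence ", i)
        if (nrow(ins) > 1L) {
          o <- order(ins$offset)
          if (any(ins$offset[o][-1] <= (ins$offset + ins$len - 1L)[o][-nrow(ins)]))
            stop("overlapping implants in sequence ", i)
        }
      }
      for (try in seq_len(max_tries)) {
        s <- random_dna(lens[i], plan$gc_background)
        if (!is.null(ins)) {
          for (r in seq_len(nrow(ins)))
            substr(s, ins$offset[r], ins$offset[r] + ins$len[r] - 1L) <-
              strrep(ins$motif[r], ins$repeats[r])
          clean <- all(vapply(seq_len(nrow(ins)), function(r) {
            ist <- ins$offset[r]; ien <- ist + ins$len[r] - 1L
            window_is_clean(s, max(1L, ist - plan$clean_flank),
                            min(lens[i], ien + plan$clean_flank),
                            ist, ien, ins$motif[r], ins$repeats[r], cfg)
          }, logical(1)))
          if (!clean) next
        }
        seqs[i] <- s
        break
      }
      if (!nzchar(seqs[i]))
        stop("could not generate a clean background for sequence ", i,
             " in ", max_tries, " tries")
      if (!is.null(ins))
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[i], start = ins$offset,
          end = ins$offset + ins$len - 1L, motif = ins$motif,
          class = motif_class_label(ins$motif),
          unit_len = nchar(ins$motif), repeats = ins$repeats,
          stringsAsFactors = FALSE)
    }
    records <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 motif = character(0), class = character(0),
                 unit_len = integer(0), repeats = integer(0))
    rownames(truth) <- NULL
    attr(truth, "seed") <- plan$seed
    list(records = records, truth = truth)
  })
}

#' Plan for simulated genotype panels
#'
#' Genotypes are drawn marker by marker from stated allele frequencies with
#' an inbreeding coefficient `f`: with probability `f` a single allele draw
#' is duplicated (autozygous call), otherwise the two alleles are drawn
#' independently.  Calls go missing i.i.d. at `missing_rate`.  Under this
#' model the expected observed heterozygosity at a marker is
#' `(1 - f) * (1 - sum(p^2))`.
#'
#' @param n_accessions Number of accessions.
#' @param freqs Named list: one numeric frequency vector per marker, each
#'   summing to 1 with at least one positive entry; allele names default to
#'   `a1, a2, ...`.
#' @param f Inbreeding coefficient in `[0, 1]`.
#' @param missing_rate Per-call missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `geno_sim_plan`.
#' @export
geno_sim_plan <- function(n_accessions = 32L,
                          freqs = list(m1 = c(0.5, 0.5),
                                       m2 = c(0.6, 0.3, 0.1)),
                          f = 0.9, missing_rate = 0.02, seed = 1L) {
  stopifnot(n_accessions >= 1L, f >= 0, f <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(freqs) < 1L) stop("at least one marker frequency vector needed")
  if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
    names(freqs) <- paste0("m", seq_along(freqs))
  freqs <- lapply(freqs, function(p) {
    if (length(p) < 1L || any(p < 0) || abs(sum(p) - 1) > 1e-8 || all(p == 0))
      stop("each frequency vector must be non-negative and sum to 1")
    if (is.null(names(p))) names(p) <- paste0("a", seq_along(p))
    p
  })
  structure(list(n_accessions = as.integer(n_accessions), freqs = freqs,
                 f = f, missing_rate = missing_rate, seed = as.integer(seed)),
            class = "geno_sim_plan")
}

#' Simulate a genotype panel with known truth
#'
#' @param plan A [geno_sim_plan()].
#' @return List with `genotypes` (a `genotype_matrix`) and `truth` (the
#'   plan itself, carrying the generating frequencies, `f` and seed).
#' @export
simulate_genotypes <- function(plan) {
  stopifnot(inherits(plan, "geno_sim_plan"))
  with_seed(plan$seed, {
    n <- plan$n_accessions
    acc <- sprintf("acc%04d", seq_len(n))
    mk <- names(plan$freqs)
    a1 <- a2 <- matrix(NA_character_, n, length(mk),
                       dimnames = list(acc, mk))
    for (j in seq_along(mk)) {
      p <- plan$freqs[[j]]
      auto <- stats::runif(n) < plan$f
      d1 <- sample(names(p), n, replace = TRUE, prob = p)
      d2 <- sample(names(p), n, replace = TRUE, prob = p)
      a1[, j] <- d1
      a2[, j] <- ifelse(auto, d1, d2)
      gone <- stats::runif(n) < plan$missing_rate
      a1[gone, j] <- NA; a2[gone, j] <- NA
    }
    g <- structure(list(accessions = acc, markers = mk, a1 = a1, a2 = a2),
                   class = "genotype_matrix")
    list(genotypes = g, truth = plan)
  })
}
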