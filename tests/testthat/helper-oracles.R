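# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package internals they check.

# N50 by direct definition: the smallest length L in the set such that the
# sum of all lengths >= L is at least half the total.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(lens[lens >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Primitivity by divisor enumeration.
oracle_primitive <- function(m) {
  n <- nchar(m)
  if (n == 1) return(TRUE)
  for (d in seq_len(n - 1)) {
    if (n %% d != 0) next
    if (paste(rep(substr(m, 1, d), n / d), collapse = "") == m) return(FALSE)
  }
  TRUE
}

# Canonical class by explicit enumeration of the candidate set.
oracle_canonical <- function(m) {
  n <- nchar(m)
  rots <- function(x) vapply(seq_len(n), function(i)
    paste0(substr(x, i, n), substr(x, 1, i - 1)), character(1))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]), collapse = "")
  min(c(rots(m), rots(rc)))
}

# Per-position leftmost-greedy maximal-extension SSR scan.  For each unit
# length: walk the sequence; at each position extend the candidate unit as
# far as it perfectly repeats; accept threshold-passing primitive runs and
# jump past them, otherwise advance one position.  Then resolve across unit
# lengths greedily, smallest unit first, never overlapping.
oracle_scan <- function(seq, min_repeats = c(`1` = 11L, `2` = 6L, `3` = 5L,
                                             `4` = 5L, `5` = 4L, `6` = 4L)) {
  L <- nchar(seq)
  cand <- list()
  for (k in 1:6) {
    t <- min_repeats[[as.character(k)]]
    p <- 1L
    while (p + k * t - 1L <= L) {
      unit <- substr(seq, p, p + k - 1L)
      if (grepl("N", unit, fixed = TRUE) || !oracle_primitive(unit)) {
        p <- p + 1L
        next
      }
      cnt <- 1L
      while (p + (cnt + 1L) * k - 1L <= L &&
             substr(seq, p + cnt * k, p + (cnt + 1L) * k - 1L) == unit)
        cnt <- cnt + 1L
      if (cnt >= t) {
        cand[[length(cand) + 1L]] <-
          list(start = p, end = p + cnt * k - 1L, unit = unit, k = k,
               reps = cnt)
        p <- p + cnt * k
      } else p <- p + 1L
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), k = integer(0),
                      reps = integer(0)))
  df <- do.call(rbind, lapply(cand, as.data.frame))
  df <- df[order(df$k, df$start), ]
  keep <- rep(FALSE, nrow(df))
  acc <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= acc$end & df$end[i] >= acc$start)) {
      keep[i] <- TRUE
      acc <- rbind(acc, df[i, c("start", "end")])
    }
  }
  df <- df[keep, ]
  df[order(df$start, df$k), ]
}

# Uniform random DNA string.
rand_dna <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# Deterministic repeat-free spacer of exact length n: a period-11 pattern
# containing no tandem repeat of a 1-6 bp unit at calling thresholds.
spacer <- function(n) substr(strrep("ACGGATCGTTC", ceiling(n / 11) + 1L), 1L, n)

# Naive primer-pair chooser: enumerate every (fwd start, fwd len, rev end,
# rev len) with nested loops, apply each constraint directly, rank by the
# documented total order.  Returns NULL or a list(fwd_start, fwd_len,
# rev_end, rev_len).
oracle_design <- function(seq, locus_start, locus_end, spec) {
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
                          collapse = "")
  tm <- function(p) {
    gc <- sum(strsplit(p, "")[[1]] %in% c("G", "C"))
    n <- nchar(p)
    if (n < 14) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }
  qual <- function(p) {
    !grepl(sprintf("([ACGT])\\1{%d}", spec$max_homopolymer), p, perl = TRUE) &&
      !grepl(sprintf("(G{%d}|C{%d})$", spec$max_3prime_gc_run + 1,
                     spec$max_3prime_gc_run + 1), p, perl = TRUE)
  }
  ok_primer <- function(p) !grepl("N", p, fixed = TRUE) &&
    tm(p) >= spec$tm_min && tm(p) <= spec$tm_max && qual(p)
  L <- nchar(seq)
  # tabulate acceptable single primers first, then pair exhaustively
  fwd <- list()
  for (fl in spec$min_len:spec$max_len) {
    for (fs in seq_len(max(0, locus_start - fl))) {
      fp <- substr(seq, fs, fs + fl - 1)
      if (ok_primer(fp))
        fwd[[length(fwd) + 1]] <- list(fs = fs, fl = fl, tm = tm(fp))
    }
  }
  rev <- list()
  for (rl in spec$min_len:spec$max_len) {
    if (locus_end + rl > L) next
    for (re in seq(locus_end + rl, L)) {
      rp <- rc(substr(seq, re - rl + 1, re))
      if (ok_primer(rp))
        rev[[length(rev) + 1]] <- list(re = re, rl = rl, tm = tm(rp))
    }
  }
  best <- NULL; best_key <- NULL
  mid <- (spec$tm_min + spec$tm_max) / 2
  for (f in fwd) {
    for (r in rev) {
      prod <- r$re - f$fs + 1
      if (prod < spec$product_min || prod > spec$product_max) next
      if (abs(f$tm - r$tm) > spec$tm_diff_max) next
      key <- c(abs((f$tm + r$tm) / 2 - mid),
               abs(f$fl - spec$opt_len) + abs(r$rl - spec$opt_len),
               f$fs, r$re, f$fl, r$rl)
      if (is.null(best_key) || order_key_lt(key, best_key)) {
        best <- list(fwd_start = f$fs, fwd_len = f$fl, rev_end = r$re,
                     rev_len = r$rl)
        best_key <- key
      }
    }
  }
  best
}

order_key_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Build a records + loci fixture with designable flanks for marker tests.
make_design_fixture <- function(n = 10, seed = 42, flank = 170) {
  set.seed(seed)
  seqs <- character(n); ids <- sprintf("fx%03d", seq_len(n))
  for (i in seq_len(n)) {
    repeat {
      left <- rand_dna(flank)
      right <- rand_dna(flank)
      s <- paste0(left, strrep("AG", 6 + (i %% 4)), right)
      if (nrow(ssrminer::find_perfect_ssrs(s, "x")) == 1L) break
    }
    seqs[i] <- s
  }
  records <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  loci <- ssrminer::find_ssrs(records)
  list(records = records, loci = loci)
}
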