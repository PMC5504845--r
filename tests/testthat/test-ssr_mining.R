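test_that("per-unit-length thresholds gate locus calls", {
  flank <- strrep("C", 8)
  eleven_a <- paste0(flank, strrep("A", 11), flank)
  ten_a <- paste0(flank, strrep("A", 10), flank)
  expect_equal(nrow(find_perfect_ssrs(ten_a, "t")), 0L)
  hit <- find_perfect_ssrs(eleven_a, "t")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$class, "A/T")
  expect_equal(hit$repeats, 11L)

  ag6 <- paste0(flank, strrep("AG", 6), flank)
  hit2 <- find_perfect_ssrs(ag6, "t")
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$class, "AG/CT")
  expect_equal(hit2$repeats, 6L)
  expect_equal(hit2$end - hit2$start + 1L, 12L)
  expect_equal(nrow(find_perfect_ssrs(paste0(flank, strrep("AG", 5), flank),
                                      "t")), 0L)
})

test_that("homopolymer runs are reported with their primitive unit", {
  run <- paste0(strrep("G", 6), strrep("A", 12), strrep("C", 6))
  hit <- find_perfect_ssrs(run, "t")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_len, 1L)
  expect_equal(hit$motif, "A")
  expect_equal(hit$repeats, 12L)
})

test_that("N breaks perfection and no locus spans an N", {
  s <- paste0(strrep("C", 6), strrep("A", 6), "N", strrep("A", 6),
              strrep("C", 6))
  expect_equal(nrow(find_perfect_ssrs(s, "t")), 0L)
  s2 <- paste0(strrep("A", 11), "N", strrep("A", 11))
  hits <- find_perfect_ssrs(s2, "t")
  expect_equal(nrow(hits), 2L)
  expect_true(all(!grepl("N", substring(s2, hits$start, hits$end))))
})

test_that("loci at sequence boundaries are still reported", {
  hit <- find_perfect_ssrs(paste0(strrep("AG", 6), spacer(20)), "t")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$left_flank, 0L)
})

# Permissive thresholds make repeats common in uniform random sequence, so
# the property tests below exercise the scanner densely.
low_cfg <- threshold_config(min_repeats = c(`1` = 5L, `2` = 3L, `3` = 3L,
                                            `4` = 2L, `5` = 2L, `6` = 2L))

test_that("every emitted locus is perfect and maximal", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:60) {
    s <- rand_dna(sample(200:800, 1), alpha = c("A", "C", "G", "T", "A", "T"))
    loci <- find_perfect_ssrs(s, "r", low_cfg)
    n_checked <- n_checked + nrow(loci)
    for (j in seq_len(nrow(loci))) {
      with(loci[j, ], {
        expect_equal(substr(s, start, end), strrep(motif, repeats))
        # right extension by one unit breaks perfection or leaves the sequence
        rext <- substr(s, end + 1L, end + unit_len)
        expect_true(nchar(rext) < unit_len || rext != motif)
        # left extension likewise, unless it would overlap another locus
        lext <- substr(s, start - unit_len, start - 1L)
        others <- loci[-j, , drop = FALSE]
        overlaps_other <- any(others$seq_id == seq_id &
                                others$end >= start - unit_len &
                                others$start <= start - 1L)
        expect_true(start - unit_len < 1L || lext != motif || overlaps_other)
      })
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("scanner equals the per-position brute-force oracle on random sequences", {
  set.seed(202)
  for (i in 1:120) {
    # permissive thresholds give dense loci so the check has teeth
    s <- rand_dna(sample(100:600, 1), alpha = c("A", "C", "G", "T", "A", "T"))
    got <- find_perfect_ssrs(s, "r", low_cfg)
    want <- oracle_scan(s, low_cfg$min_repeats)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want) > 0L) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
      expect_equal(got$motif, want$unit, info = s)
      expect_equal(got$repeats, want$reps, info = s)
    }
  }
  # and at the default marker thresholds
  set.seed(203)
  for (i in 1:40) {
    s <- rand_dna(sample(200:800, 1), alpha = c("A", "A", "A", "T", "T", "G"))
    got <- find_perfect_ssrs(s, "r")
    want <- oracle_scan(s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
    expect_equal(got$motif, want$unit, info = s)
  }
})

test_that("reported intervals never overlap and are sorted", {
  set.seed(303)
  for (i in 1:40) {
    s <- rand_dna(sample(300:900, 1), alpha = c("A", "T", "A", "T", "C", "G"))
    loci <- find_perfect_ssrs(s, "r", low_cfg)
    if (nrow(loci) > 1L) {
      expect_true(all(diff(loci$start) > 0L))
      expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
    }
  }
})

test_that("compound merging chains loci by gap and flags motif mixtures", {
  cfg <- threshold_config(max_compound_gap = 100L)
  seqs <- c(
    gap0 = paste0(strrep("C", 6), strrep("AG", 6), strrep("AAT", 5),
                  strrep("C", 6)),
    gapbig = paste0(strrep("C", 6), strrep("AG", 6), spacer(101),
                    strrep("AAT", 5), strrep("C", 6)),
    gapok = paste0(strrep("C", 6), strrep("AG", 6), spacer(100),
                   strrep("AAT", 5), strrep("C", 6)))
  loci <- find_ssrs(seqs, cfg)
  by_seq <- split(loci, loci$seq_id)
  expect_equal(unique(by_seq$gap0$compound_id), "gap0.c1")
  expect_equal(unique(by_seq$gap0$compound_type), "mixed")
  expect_true(all(is.na(by_seq$gapbig$compound_id)))
  expect_equal(unique(by_seq$gapok$compound_id), "gapok.c1")

  same <- paste0(strrep("C", 6), strrep("AG", 6), spacer(10),
                 strrep("GA", 7), strrep("C", 6))
  lsame <- find_ssrs(c(s = same), cfg)
  expect_equal(unique(lsame$compound_type), "same_motif")
})

test_that("three-locus chains follow the interval-chaining oracle", {
  cfg <- threshold_config(max_compound_gap = 100L)
  s <- paste0(strrep("C", 6), strrep("AG", 6), strrep("C", 2),
              strrep("AAT", 5), spacer(200), strrep("AAAG", 5),
              strrep("C", 6))
  loci <- find_ssrs(c(u = s), cfg)
  expect_equal(nrow(loci), 3L)
  expect_equal(is.na(loci$compound_id), c(FALSE, FALSE, TRUE))
  expect_equal(loci$compound_id[1], loci$compound_id[2])
  expect_error(merge_compound(loci[c(2, 1, 3), ], cfg), "sorted")
})

test_that("repeat summaries conserve totals and bin counts correctly", {
  seqs <- c(
    s1 = paste0(strrep("C", 6), strrep("AG", 6), strrep("T", 6)),
    s2 = paste0(strrep("C", 6), strrep("AG", 6), strrep("T", 6)),
    s3 = paste0(strrep("C", 6), strrep("AG", 6), strrep("T", 6)),
    s4 = paste0(strrep("C", 6), strrep("AAG", 5), strrep("T", 6)),
    s5 = paste0(strrep("C", 6), strrep("AAG", 5), strrep("T", 6)))
  summ <- summarize_ssrs(find_ssrs(seqs))
  tab <- summ$table
  expect_equal(summ$grand_total, 5L)
  expect_equal(tab$`6`[tab$class == "AG/CT"], 3L)
  expect_equal(tab$`5`[tab$class == "AAG/CTT"], 2L)
  bins <- repeat_cols <- setdiff(names(tab), c("unit_len", "class", "total"))
  expect_equal(rowSums(tab[, bins, drop = FALSE]), tab$total,
               ignore_attr = TRUE)
  expect_equal(sum(summ$unit_len_totals), summ$grand_total)
  empty <- summarize_ssrs(find_ssrs(c(x = "ACGTACGTAC")))
  expect_equal(empty$grand_total, 0L)
})

test_that("mono-nucleotide threshold loci land in the >10 bin", {
  s <- c(m = paste0(strrep("C", 6), strrep("A", 11), strrep("G", 6)))
  tab <- summarize_ssrs(find_ssrs(s))$table
  expect_equal(tab$`>10`[tab$class == "A/T"], 1L)
})

test_that("rare classes pool into Others per unit length", {
  s <- c(x = paste0(strrep("T", 6), strrep("CGG", 5), strrep("A", 6)))
  summ <- summarize_ssrs(find_ssrs(s))
  expect_equal(summ$table$class, "Others")
  expect_equal(summ$table$unit_len, 3L)
  expect_equal(summ$grand_total, 1L)
})

test_that("unigene tallies distinguish independent and compound SSRs", {
  cfg <- threshold_config(max_compound_gap = 100L)
  one <- find_ssrs(c(u = paste0(strrep("C", 6), strrep("AG", 6),
                                strrep("T", 6))), cfg)
  expect_equal(unname(count_ssr_unigenes(one)), c(1L, 0L, 0L))

  far <- find_ssrs(c(u = paste0(strrep("C", 6), strrep("AG", 6),
                                spacer(101), strrep("AAT", 5),
                                strrep("T", 6))), cfg)
  expect_equal(unname(count_ssr_unigenes(far)), c(1L, 1L, 0L))

  near <- find_ssrs(c(u = paste0(strrep("C", 6), strrep("AG", 6),
                                 spacer(100), strrep("AAT", 5),
                                 strrep("T", 6))), cfg)
  expect_equal(unname(count_ssr_unigenes(near)), c(1L, 0L, 1L))

  expect_error(count_ssr_unigenes(one[, setdiff(names(one), "compound_type")]),
               "compound annotation")
})

test_that("compound gap sweep reproduces per-gap tallies", {
  s <- c(u = paste0(strrep("C", 6), strrep("AG", 6), spacer(50),
                    strrep("AAT", 5), strrep("T", 6)))
  loci <- find_ssrs(s)
  expect_equal(nrow(loci), 2L)
  g <- loci$start[2] - loci$end[1] - 1L
  sweep <- compound_gap_sweep(loci, gaps = c(0L, g - 1L, g, 150L))
  expect_equal(sweep$n_compound_unigenes, c(0L, 0L, 1L, 1L))
  expect_equal(sweep$n_with_2plus, c(1L, 1L, 0L, 0L))
})

test_that("locus TSV round-trips through write/read", {
  fx <- make_design_fixture(n = 3, seed = 9)
  p <- tempfile(fileext = ".tsv")
  write_loci_tsv(fx$loci, p)
  back <- read_loci_tsv(p)
  for (col in c("seq_id", "start", "end", "motif", "class", "unit_len",
                "repeats", "left_flank", "right_flank"))
    expect_equal(back[[col]], fx$loci[[col]], info = col)
})
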