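toy_genotypes <- function() {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tmk1\tmk2",
               "acc1\t180/184\t200",
               "acc2\t-\t200/204"), p)
  p
}

test_that("genotype parsing expands shorthand and masks missing calls", {
  g <- read_genotypes(toy_genotypes())
  expect_equal(g$accessions, c("acc1", "acc2"))
  expect_equal(g$markers, c("mk1", "mk2"))
  expect_equal(unname(g$a1[, "mk1"]), c("180", NA))
  expect_equal(unname(g$a2[, "mk1"]), c("184", NA))
  expect_equal(unname(g$a1[, "mk2"]), c("200", "200"))
  expect_equal(unname(g$a2[, "mk2"]), c("200", "204"))
})

test_that("genotype parsing rejects malformed tables", {
  p <- tempfile()
  writeLines(c("accession\tmk1\tmk2", "acc1\t180/184"), p)
  expect_error(read_genotypes(p), "ragged")
  p2 <- tempfile()
  writeLines(c("accession\tmk1", "acc1\t180/"), p2)
  expect_error(read_genotypes(p2), "malformed")
  p3 <- tempfile()
  writeLines(c("accession\tmk1", "acc1\t/184"), p3)
  expect_error(read_genotypes(p3), "malformed")
})

test_that("genotype tables round-trip through write/read", {
  sim <- simulate_genotypes(geno_sim_plan(n_accessions = 25, seed = 4,
                                          missing_rate = 0.1))
  p <- tempfile(fileext = ".tsv")
  write_genotypes(sim$genotypes, p)
  back <- read_genotypes(p)
  expect_identical(back$a1, sim$genotypes$a1)
  expect_identical(back$a2, sim$genotypes$a2)
})

test_that("allele frequencies tally the 2n allele observations", {
  g <- parse_genotype_calls(
    matrix(c("a/a", "a/b"), ncol = 1), c("x", "y"), "m")
  expect_equal(allele_frequencies(g, "m"), c(a = 0.75, b = 0.25))
  g2 <- parse_genotype_calls(
    matrix(c("a", "a", "a"), ncol = 1), c("x", "y", "z"), "m")
  expect_equal(allele_frequencies(g2, "m"), c(a = 1.0))
  expect_equal(sum(allele_frequencies(g, "m")), 1, tolerance = 1e-12)
  g3 <- parse_genotype_calls(matrix("-", ncol = 1), "x", "m")
  expect_error(allele_frequencies(g3, "m"), "no scored calls")
})

test_that("observed heterozygosity counts differing pairs over scored calls", {
  g <- parse_genotype_calls(
    matrix(c("a/b", "c/d", "-"), ncol = 1), c("x", "y", "z"), "m")
  expect_equal(observed_heterozygosity(g, "m"), 1.0)
  g2 <- parse_genotype_calls(
    matrix(c("a/b", "a/a"), ncol = 1), c("x", "y"), "m")
  expect_equal(observed_heterozygosity(g2, "m"), 0.5)
})

test_that("PIC matches its closed forms", {
  expect_equal(pic(c(a = 1.0)), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(1 / 3, 3)), 16 / 27)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "negative")
})

test_that("PIC is bounded by expected heterozygosity and in [0,1)", {
  set.seed(99)
  for (i in 1:500) {
    k <- sample(1:8, 1)
    p <- stats::rgamma(k, 1)
    p <- p / sum(p)
    v <- pic(p)
    he <- 1 - sum(p^2)
    expect_gte(v, 0)
    expect_lt(v, 1)
    expect_lte(v, he + 1e-12)
    if (k == 1) expect_equal(v, 0)
  }
})

test_that("PIC is maximized at equal frequencies for fixed allele count", {
  for (k in 2:4) {
    peak <- pic(rep(1 / k, k))
    set.seed(k)
    for (i in 1:200) {
      p <- stats::rgamma(k, 1); p <- p / sum(p)
      expect_lte(pic(p), peak + 1e-12)
    }
  }
})

test_that("Ho is invariant under allele relabeling and accession reordering", {
  sim <- simulate_genotypes(geno_sim_plan(n_accessions = 40, f = 0.3,
                                          seed = 12))
  g <- sim$genotypes
  ho <- observed_heterozygosity(g, "m1")
  relab <- g
  relab$a1 <- matrix(chartr("a", "z", g$a1), nrow = nrow(g$a1),
                     dimnames = dimnames(g$a1))
  relab$a2 <- matrix(chartr("a", "z", g$a2), nrow = nrow(g$a2),
                     dimnames = dimnames(g$a2))
  expect_equal(observed_heterozygosity(relab, "m1"), ho)
  perm <- sample(seq_along(g$accessions))
  shuf <- g
  shuf$accessions <- g$accessions[perm]
  shuf$a1 <- g$a1[perm, , drop = FALSE]
  shuf$a2 <- g$a2[perm, , drop = FALSE]
  expect_equal(observed_heterozygosity(shuf, "m1"), ho)
})

test_that("summarize_markers reports per-marker stats and panel moments", {
  g <- parse_genotype_calls(
    matrix(c("a", "a", "a", "a/b", "b/b", "a/b"), ncol = 2),
    c("x", "y", "z"), c("mono", "poly"))
  st <- summarize_markers(g)
  expect_equal(st$per_marker$na, c(1L, 2L))
  expect_equal(st$per_marker$ho, c(0, 2 / 3))
  expect_equal(st$per_marker$pic[1], 0)
  expect_equal(st$per_marker$n_scored, c(3L, 3L))
  expect_equal(st$panel["mean", "ho"], mean(c(0, 2 / 3)))
  expect_equal(st$panel["sd", "na"], stats::sd(c(1, 2)))
})

test_that("simulated panels recover (1-F)(1-sum p^2) within Monte Carlo error", {
  p <- c(0.5, 0.3, 0.2)
  for (f in c(0, 0.5, 1)) {
    sim <- simulate_genotypes(geno_sim_plan(
      n_accessions = 10000, freqs = list(m = p), f = f,
      missing_rate = 0, seed = 100 + round(10 * f)))
    ho <- observed_heterozygosity(sim$genotypes, "m")
    expected <- (1 - f) * (1 - sum(p^2))
    se <- sqrt(max(expected * (1 - expected), 1e-12) / 10000)
    if (f == 1) expect_equal(ho, 0)
    else expect_lt(abs(ho - expected), 3 * se + 1e-9)
  }
})
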