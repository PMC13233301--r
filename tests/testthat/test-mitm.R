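region_row <- function(chrom, start, end, probes = character()) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 probe_ids = list(probes))
}

test_that("interval overlap follows half-open semantics and the all-pairs definition", {
  # identical interval lists: one pair per region
  r <- dplyr::bind_rows(region_row("chr1", 100, 200), region_row("chr1", 500, 700))
  pairs <- overlap_dmrs(r, r)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$int_start, pairs$start_folate)

  # touching half-open intervals do not overlap
  expect_equal(nrow(overlap_dmrs(region_row("chr1", 100, 200),
                                 region_row("chr1", 200, 300))), 0)
  # same coordinates on different chromosomes do not overlap
  expect_equal(nrow(overlap_dmrs(region_row("chr1", 100, 200),
                                 region_row("chr2", 100, 200))), 0)

  # 500 random intervals per side vs the brute-force all-pairs oracle
  f <- random_regions(500, seed = 31)
  b <- random_regions(500, seed = 32)
  pairs <- overlap_dmrs(f, b)
  brute <- 0L
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(b))) {
    if (f$chrom[i] == b$chrom[j] &&
        max(f$start[i], b$start[j]) < min(f$end[i], b$end[j])) {
      brute <- brute + 1L
    }
  }
  expect_equal(nrow(pairs), brute)
  expect_gt(brute, 0)

  # swapping the two lists leaves the pair set unchanged
  swapped <- overlap_dmrs(b, f)
  expect_equal(nrow(swapped), nrow(pairs))
  key1 <- sort(paste(pairs$chrom, pairs$int_start, pairs$int_end))
  key2 <- sort(paste(swapped$chrom, swapped$int_start, swapped$int_end))
  expect_equal(key1, key2)
})

coef_table <- function(ids, est) {
  tibble::tibble(probe_id = ids, estimate = est)
}

test_that("direction assignment averages the right probes and filters discordance", {
  f_reg <- region_row("chr1", 100, 300, c("f1", "f2"))
  b_reg <- region_row("chr1", 200, 400, c("b1", "b2"))
  pairs <- overlap_dmrs(f_reg, b_reg)

  fol <- coef_table(c("f1", "f2"), c(1, 2))
  a_pos <- coef_table(c("b1", "b2"), c(0.5, 0.5))
  b_pos <- coef_table(c("b1", "b2"), c(0.3, 0.3))

  done <- assign_directions(pairs, fol, a_pos, b_pos)
  expect_equal(done$mean_folate, 1.5)
  expect_equal(done$folate_dir, "+")
  expect_equal(done$blast_dir, "+")
  expect_true(done$evaluable)
  expect_true(done$concordant)

  # cross-set sign disagreement: omitted from the denominator
  b_neg <- coef_table(c("b1", "b2"), c(-0.1, -0.1))
  mixed <- suppressMessages(assign_directions(pairs, fol, a_pos, b_neg))
  expect_equal(mixed$blast_dir, "discordant")
  expect_false(mixed$evaluable)

  # evaluable but discordant-direction pair
  fol_neg <- coef_table(c("f1", "f2"), c(-3, 1))  # mean -1
  disc <- assign_directions(pairs, fol_neg, a_pos, b_pos)
  expect_equal(disc$folate_dir, "-")
  expect_true(disc$evaluable)
  expect_false(disc$concordant)

  # exact-zero mean folate coefficient: indeterminate, omitted
  fol_zero <- coef_table(c("f1", "f2"), c(-1, 1))
  zero <- suppressMessages(assign_directions(pairs, fol_zero, a_pos, b_pos))
  expect_equal(zero$folate_dir, "indeterminate")
  expect_false(zero$evaluable)

  # no coverage at all: omitted with a message
  no_cov <- coef_table("other", 1)
  out <- suppressMessages(assign_directions(pairs, no_cov, a_pos, b_pos))
  expect_false(out$evaluable)
})

test_that("direction averaging uses each side's own member probes", {
  # folate region wider than the intersection; only folate members count
  f_reg <- region_row("chr1", 100, 1000, c("f1", "f2", "f3"))
  b_reg <- region_row("chr1", 900, 1200, c("b1",  "b2"))
  pairs <- overlap_dmrs(f_reg, b_reg)
  fol <- coef_table(c("f1", "f2", "f3"), c(-5, 1, 1))   # mean -1 over ALL members
  blast <- coef_table(c("b1", "b2"), c(1, 1))
  done <- assign_directions(pairs, fol, blast, blast)
  expect_equal(done$mean_folate, -1)
  expect_equal(done$folate_dir, "-")
})

test_that("negating one study's coefficients flips every verdict; both, none", {
  f <- random_regions(40, seed = 41)
  b <- random_regions(40, seed = 42)
  all_probes <- paste0("cg", seq_len(2000))
  set.seed(43)
  f$probe_ids <- replicate(40, sample(all_probes[1:1000], 3), simplify = FALSE)
  b$probe_ids <- replicate(40, sample(all_probes[1001:2000], 3), simplify = FALSE)
  fol <- coef_table(all_probes, rnorm(2000))
  ba <- coef_table(all_probes, rnorm(2000))
  bb <- ba  # keep the two sets concordant so pairs stay evaluable

  pairs <- overlap_dmrs(f, b)
  base <- assign_directions(pairs, fol, ba, bb)

  neg_one <- assign_directions(pairs, fol,
                               dplyr::mutate(ba, estimate = -estimate),
                               dplyr::mutate(bb, estimate = -estimate))
  neg_both <- assign_directions(dplyr::mutate(pairs),
                                dplyr::mutate(fol, estimate = -estimate),
                                dplyr::mutate(ba, estimate = -estimate),
                                dplyr::mutate(bb, estimate = -estimate))
  ev <- base$evaluable
  expect_true(any(ev))
  expect_equal(neg_one$concordant[ev], !base$concordant[ev])
  expect_equal(neg_both$concordant[ev], base$concordant[ev])
})

test_that("exact binomial concordance test equals enumeration for all n <= 40", {
  for (n in 1:40) {
    for (k in 0:n) {
      expect_equal(concordance_binomial(k, n), binom_two_sided_oracle(k, n),
                   tolerance = 1e-12)
    }
  }
  expect_equal(concordance_binomial(1, 2), 1)    # symmetric centre
  expect_true(is.na(concordance_binomial(0, 0))) # not evaluable sentinel
  expect_error(concordance_binomial(5, 3), "k <= n")
})

test_that("income stratification puts the boundary on the high side", {
  cov <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        ethnicity = c("hispanic", "hispanic", "nhw", "nhw"),
                        income = c(74999, 75000, 75001, 10000))
  expect_equal(run_subgroup(cov, income_side = "low"), c("a", "d"))
  expect_equal(run_subgroup(cov, income_side = "high"), c("b", "c"))
  expect_equal(run_subgroup(cov), cov$sample_id)  # all/all is the identity
  expect_equal(run_subgroup(cov, ethnicity = "hispanic", income_side = "low"),
               "a")
  expect_error(run_subgroup(cov, ethnicity = "other"), "empty")
})

test_that("concordance summaries carry counts, p-value and bias label", {
  mk_pairs <- function(k, n) {
    tibble::tibble(evaluable = rep(TRUE, n),
                   concordant = c(rep(TRUE, k), rep(FALSE, n - k)))
  }
  s <- summarize_concordance(mk_pairs(16, 18), "supplemental")
  expect_equal(s$k, 16L)
  expect_equal(s$n, 18L)
  expect_equal(round(s$p.value, 6), 0.001312)
  expect_equal(s$bias, "concordant")

  s2 <- summarize_concordance(mk_pairs(9, 31), "natural", "hispanic_low")
  expect_equal(round(s2$p.value, 5), 0.02945)
  expect_equal(s2$bias, "discordant")

  s3 <- summarize_concordance(tibble::tibble(evaluable = logical(),
                                             concordant = logical()), "total")
  expect_equal(s3$n, 0L)
  expect_true(is.na(s3$p.value))
  expect_equal(s3$bias, "not evaluable")
})
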