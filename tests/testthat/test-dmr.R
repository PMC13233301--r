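test_that("ACF estimation matches a brute-force all-pairs oracle", {
  set.seed(14)
  pos <- sort(sample(1:3000, 30))
  track <- tibble::tibble(probe_id = paste0("p", 1:30), chrom = "chr1",
                          pos = pos, p.value = runif(30))
  acf <- suppressMessages(estimate_acf(track, bin_width = 100, max_dist = 1000))

  z <- qnorm(1 - track$p.value)
  for (b in seq_len(nrow(acf))) {
    xs <- c(); ys <- c()
    for (i in 1:29) for (j in (i + 1):30) {
      d <- pos[j] - pos[i]
      if (d > (b - 1) * 100 && d <= b * 100) {
        xs <- c(xs, z[i]); ys <- c(ys, z[j])
      }
    }
    if (length(xs) >= 10) {
      expect_equal(acf$cor[b], max(0, cor(xs, ys)), tolerance = 1e-12)
      expect_false(acf$inherited[b])
    } else {
      expect_true(acf$inherited[b])
    }
  }
})

test_that("ACF is near zero on a uniform null and one under total dependence", {
  cfg <- synth_config(n_probes = 20000, seed = 15)
  man <- make_manifest(cfg)
  acf <- estimate_acf(null_track(man, 16))
  expect_true(all(acf$cor[!acf$inherited] < 0.05))

  # duplicated probes 1 bp apart with identical p: first-bin correlation 1
  set.seed(17)
  base <- seq(1000, by = 5000, length.out = 40)
  p <- runif(40)
  dup <- tibble::tibble(
    probe_id = paste0("d", 1:80), chrom = "chr1",
    pos = as.integer(rbind(base, base + 1)),
    p.value = as.numeric(rbind(p, p)))
  acf_dup <- suppressMessages(estimate_acf(dup))
  expect_equal(acf_dup$cor[1], 1)

  unsorted <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
                             pos = c(100L, 50L), p.value = c(0.5, 0.5))
  expect_error(estimate_acf(unsorted), "sorted")
})

test_that("Stouffer-Liptak combination has its closed-form special cases", {
  # identity correlation reduces to classical Stouffer
  set.seed(18)
  for (k in c(2, 5, 9)) {
    p <- runif(k)
    classical <- pnorm(sum(qnorm(1 - p)) / sqrt(k), lower.tail = FALSE)
    expect_equal(stouffer_liptak(p, diag(k)), classical, tolerance = 1e-12)
  }
  # single p unchanged
  expect_equal(stouffer_liptak(0.037), 0.037, tolerance = 1e-12)
  # total dependence: no free lunch
  expect_equal(stouffer_liptak(c(0.05, 0.05), matrix(1, 2, 2)), 0.05,
               tolerance = 1e-12)
  # non-positive-definite denominator falls back to independence
  corr <- matrix(c(1, -2, -2, 1), 2)
  expect_equal(stouffer_liptak(c(0.1, 0.1), corr),
               stouffer_liptak(c(0.1, 0.1), diag(2)))
  expect_error(stouffer_liptak(numeric()), "empty")
})

test_that("p-value smoothing equals an independent reimplementation", {
  set.seed(19)
  pos <- sort(sample(1:20000, 50))
  track <- tibble::tibble(probe_id = paste0("p", 1:50), chrom = "chr1",
                          pos = pos, p.value = runif(50))
  acf <- suppressMessages(estimate_acf(track))
  sm <- smooth_pvalues(track, acf, window = 1000)

  for (i in seq_len(50)) {
    idx <- which(abs(pos - pos[i]) <= 1000)
    if (length(idx) == 1) {
      expect_equal(sm$p_adj[i], track$p.value[i])
    } else {
      corr <- diag(length(idx))
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a != b) {
          d <- abs(pos[idx[a]] - pos[idx[b]])
          bin <- min(max(1, ceiling(d / 50)), nrow(acf))
          corr[a, b] <- acf$cor[bin]
        }
      }
      expect_equal(sm$p_adj[i], sl_oracle(track$p.value[idx], corr),
                   tolerance = 1e-10)
    }
  }

  # three co-located probes, total dependence: adjusted p stays put
  tri <- tibble::tibble(probe_id = c("a", "b", "c"), chrom = "chr1",
                        pos = c(100L, 101L, 102L), p.value = rep(0.01, 3))
  acf1 <- suppressMessages(estimate_acf(tri))
  acf1$cor[] <- 1
  sm_tri <- smooth_pvalues(tri, acf1)
  expect_equal(sm_tri$p_adj, rep(0.01, 3), tolerance = 1e-6)
})

test_that("seed-and-merge region finding applies the stated rules", {
  track <- tibble::tibble(
    probe_id = paste0("p", 1:4), chrom = "chr1",
    pos = c(10L, 110L, 310L, 2010L),
    p.value = c(0.2, 0.01, 0.02, 0.2),
    p_adj = c(0.2, 0.01, 0.02, 0.2))
  reg <- find_candidate_regions(track)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$probe_ids[[1]], c("p2", "p3"))
  expect_equal(reg$start, 109L)
  expect_equal(reg$end, 310L)

  # single qualifying probe with no qualifying neighbour within 1000 bp
  lone <- track
  lone$p_adj <- c(0.2, 0.01, 0.2, 0.2)
  expect_equal(nrow(find_candidate_regions(lone)), 0)

  # nothing below the seed threshold
  none <- track
  none$p_adj <- rep(0.5, 4)
  expect_equal(nrow(find_candidate_regions(none)), 0)

  # a gap over max_gap splits qualifying probes into two regions
  split_track <- tibble::tibble(
    probe_id = paste0("p", 1:4), chrom = "chr1",
    pos = c(10L, 110L, 2010L, 2110L),
    p.value = rep(0.01, 4), p_adj = rep(0.01, 4))
  expect_equal(nrow(find_candidate_regions(split_track)), 2)
})

test_that("region scoring and Sidak correction match closed forms", {
  track <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
                          pos = c(100L, 5000L), p.value = c(0.01, 0.01))
  acf0 <- suppressMessages(estimate_acf(track))
  acf0$cor[] <- 0
  region <- tibble::tibble(chrom = "chr1", start = 99L, end = 5000L,
                           probe_ids = list(c("a", "b")), n_probes = 2L)
  got <- score_region(region, track, acf0)
  expect_equal(got, pnorm(2 * qnorm(0.99) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)

  half <- tibble::tibble(probe_id = c("a", "b"), chrom = "chr1",
                         pos = c(100L, 5000L), p.value = c(0.5, 0.5))
  expect_equal(score_region(region, half, acf0), 0.5, tolerance = 1e-12)

  expect_equal(sidak_correct(0.3, 100, 100), 0.3)           # m = 1
  expect_equal(sidak_correct(0, 10, 1e6), 0)
  expect_equal(sidak_correct(0.01, 500, 50000), 1 - 0.99^100, tolerance = 1e-12)
  # monotone in p and in m
  ps <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_correct(ps, 500, 50000)) >= 0))
  expect_true(all(diff(sapply(c(1, 2, 5, 10) * 500,
                              function(tc) sidak_correct(0.01, 500, tc))) >= 0))
  expect_true(all(sidak_correct(ps, 500, 50000) >= ps - 1e-12))
  expect_error(sidak_correct(1.2, 10, 100), "0, 1")
})

test_that("DMR calling recovers a planted region and rejects the null", {
  cfg <- synth_config(n_probes = 5000, n_chromosomes = 2, seed = 23)
  man <- make_manifest(cfg)
  track <- null_track(man, 23)

  # plant one 5-probe region of very small raw p on chr1, picking a run of
  # consecutive probes whose gaps stay below the merge distance
  idx <- which(man$chrom == "chr1")
  ok <- vapply(seq_len(length(idx) - 4), function(i) {
    all(diff(man$pos[idx[i:(i + 4)]]) <= 1000)
  }, logical(1))
  run <- idx[which(ok)[50] + 0:4]
  expect_true(all(diff(man$pos[run]) <= 1000))
  track$p.value[run] <- 1e-6
  dmrs <- call_dmrs(track)
  expect_equal(nrow(dmrs), 1)
  expect_true(all(man$probe_id[run] %in% dmrs$probe_ids[[1]]))
  expect_lte(dmrs$start, man$pos[run[1]] - 1)
  expect_gte(dmrs$end, man$pos[run[5]])

  # returned regions never overlap one another
  set.seed(24)
  busy <- track
  busy$p.value <- pmin(track$p.value, runif(nrow(track))^3)
  d2 <- call_dmrs(busy)
  if (nrow(d2) > 1) {
    by_chrom <- split(d2, d2$chrom)
    for (ch in by_chrom) {
      if (nrow(ch) > 1) expect_true(all(ch$start[-1] >= head(ch$end, -1)))
    }
  }
})
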