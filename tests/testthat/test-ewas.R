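test_that("missingness filter drops probes and samples at the 5% rule", {
  set.seed(1)
  beta <- matrix(runif(20 * 40), 20, 40,
                 dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:40)))
  # probe 1 missing in 10% of samples -> dropped at the 5% threshold
  beta_na <- beta
  beta_na[1, 1:4] <- NA
  out <- filter_and_impute(beta_na, max_missing = 0.05)
  expect_false("p01" %in% rownames(out))
  expect_equal(nrow(out), 19)

  # matrix with no missing values is returned unchanged
  expect_identical(filter_and_impute(beta), beta)

  # sample pass: a sample missing >5% of probes is dropped
  beta_na2 <- beta
  beta_na2[1:2, 1] <- NA
  out2 <- filter_and_impute(beta_na2, max_missing = 0.05)
  expect_false("s01" %in% colnames(out2))
  expect_equal(nrow(out2), 20)

  expect_error(filter_and_impute(matrix(NA_real_, 3, 3)), "empty matrix")
})

test_that("kNN imputation equals the hand-computed neighbour mean", {
  # 5x5 toy, one missing cell, k = 2
  set.seed(7)
  beta <- matrix(runif(25), 5, 5,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:5)))
  beta[2, 3] <- NA
  out <- filter_and_impute(beta, max_missing = 0.3, k = 2)

  # oracle: complete probes ranked by Euclidean distance over the observed
  # samples of probe 2; imputed value is their mean at the missing sample
  complete <- setdiff(1:5, 2)
  obs <- setdiff(1:5, 3)
  d <- sapply(complete, function(i) sqrt(sum((beta[i, obs] - beta[2, obs])^2)))
  nn <- complete[order(d)[1:2]]
  expect_equal(out[2, 3], mean(beta[nn, 3]))
  expect_equal(out[-2, ], beta[-2, ])
})

test_that("beta/M transform has the stated fixed points and shape", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  m <- beta_to_m(b)
  expect_true(all(diff(m) > 0))                       # strictly increasing
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))       # odd about 0.5
  expect_equal(m_to_beta(beta_to_m(b)), b)
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))
})

test_that("per-probe regression matches the normal-equations oracle", {
  set.seed(3)
  n <- 8
  dose <- rnorm(n)
  y <- 0.4 * dose + rnorm(n)
  m <- matrix(y, 1, n, dimnames = list("cg1", paste0("s", 1:n)))
  cov <- tibble::tibble(sample_id = colnames(m), dose = dose)

  res <- ewas_fit(m, cov, term = "dose")
  orc <- ols_oracle(y, cbind(1, dose))
  expect_equal(res$estimate, orc$coef[2], tolerance = 1e-10)
  expect_equal(res$std.error, orc$se[2], tolerance = 1e-10)
  expect_equal(res$p.value, 2 * pt(-abs(orc$coef[2] / orc$se[2]), orc$df),
               tolerance = 1e-10)
})

test_that("degenerate designs and probes are handled as specified", {
  set.seed(4)
  m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("cg", 1:4), paste0("s", 1:10)))
  cov <- tibble::tibble(sample_id = colnames(m), dose = rep(1, 10),
                        sex = rep(c("M", "F"), 5))
  expect_error(ewas_fit(m, cov, term = "dose"), "rank deficient")

  cov$dose <- rnorm(10)
  m["cg2", ] <- 0.3  # zero-variance probe
  res <- ewas_fit(m, cov, term = "dose", adjust = "sex")
  row <- res[res$probe_id == "cg2", ]
  expect_equal(row$estimate, 0)
  expect_equal(row$p.value, 1)
  expect_true(row$degenerate)
  expect_false(any(res$degenerate[res$probe_id != "cg2"]))
})

test_that("coefficients are invariant to sample ordering", {
  cfg <- tiny_config()
  man <- make_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  m <- beta_to_m(sim$beta[1:200, ])
  res1 <- ewas_fit(m, sim$covariates, "dose_total", adjust = c("case", "sex"))
  perm <- sample(ncol(m))
  res2 <- ewas_fit(m[, perm], sim$covariates[perm, ], "dose_total",
                   adjust = c("case", "sex"))
  expect_equal(res1$estimate, res2$estimate, tolerance = 1e-12)
  expect_equal(res1$p.value, res2$p.value, tolerance = 1e-12)
})

test_that("supplemental dose coding: ordinal default, factor behind the flag", {
  cfg <- tiny_config()
  man <- make_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  m <- beta_to_m(sim$beta[1:50, ])
  res_ord <- ewas_fit(m, sim$covariates, "dose_supplemental")
  # oracle for one probe: regression on the 0..3 score
  score <- match(sim$covariates$dose_supplemental, c(0, 194, 360, 540)) - 1
  orc <- ols_oracle(m[1, ], cbind(1, score))
  expect_equal(res_ord$estimate[1], orc$coef[2], tolerance = 1e-10)

  res_fac <- ewas_fit(m, sim$covariates, "dose_supplemental",
                      supplemental_coding = "factor")
  expect_false(isTRUE(all.equal(res_ord$estimate, res_fac$estimate)))

  bad <- sim$covariates
  bad$dose_supplemental[1] <- 100
  expect_error(ewas_fit(m, bad, "dose_supplemental"), "0, 194, 360, 540")
})

test_that("blast model estimates blast-vs-control while controlling subtype", {
  cfg <- tiny_config(delta_beta_disease = 0.2)
  man <- make_manifest(cfg)
  bl <- simulate_blast_sets(cfg, man)
  res <- ewas_fit_blast(beta_to_m(bl$beta_b), bl$covariates_b, manifest = man)
  expect_s3_class(res, "ewas_result")
  expect_equal(nrow(res), nrow(bl$beta_b))

  # planted disease regions carry the planted sign in the fitted effect
  dis <- bl$truth$regions[bl$truth$regions$type %in% c("disease", "overlap"), ]
  for (i in seq_len(nrow(dis))) {
    est <- res$estimate[match(dis$probe_ids[[i]], res$probe_id)]
    expect_equal(sign(mean(est)), dis$disease_sign[i])
  }

  one_group <- bl$covariates_b
  one_group$group <- "blast"
  expect_error(ewas_fit_blast(beta_to_m(bl$beta_b), one_group),
               "both blasts and controls")
})

test_that("genomic inflation matches its definition", {
  expect_equal(genomic_inflation(rep(0.5, 3)), 1)
  expect_equal(genomic_inflation(c(0.5, 0.5, 0.5)), 1)
  set.seed(8)
  lam <- genomic_inflation(runif(1e5))
  expect_gt(lam, 0.98)
  expect_lt(lam, 1.02)
  expect_error(genomic_inflation(numeric()), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
})
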