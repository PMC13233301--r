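# Small shared scenario used across test files
tiny_config <- function(...) {
  args <- list(n_probes = 3000, n_chromosomes = 3, n_cohort_samples = 120,
               n_blast_a = 40, n_control_a = 6, n_blast_b = 20,
               n_control_b = 10, n_exposure_regions = 4,
               n_disease_regions = 4, n_overlap_regions = 8,
               region_n_probes = c(4L, 6L), seed = 11L)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# independent least-squares oracle: explicit normal equations
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  list(coef = unname(drop(b)), se = unname(se), df = df)
}

# independent Stouffer-Liptak evaluation, written directly from the formula
sl_oracle <- function(p, corr) {
  z <- qnorm(1 - p)
  denom <- length(p) + 2 * sum(corr[upper.tri(corr)])
  pnorm(sum(z) / sqrt(denom), lower.tail = FALSE)
}

# doubled-smaller-tail binomial p by exhaustive pmf enumeration
binom_two_sided_oracle <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# uniform-p track over a manifest
null_track <- function(manifest, seed) {
  set.seed(seed)
  tibble::tibble(probe_id = manifest$probe_id, chrom = manifest$chrom,
                 pos = manifest$pos, p.value = runif(nrow(manifest)))
}

# random internally non-overlapping interval list on a few chromosomes
random_regions <- function(n, seed, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  per <- split(seq_len(n), sample(chroms, n, replace = TRUE))
  out <- lapply(names(per), function(ch) {
    m <- length(per[[ch]])
    w <- sample(50:400, m, replace = TRUE)
    gap <- sample(0:500, m, replace = TRUE)
    start <- cumsum(gap + c(0, head(w, -1)))
    tibble::tibble(chrom = ch, start = start, end = start + w,
                   probe_ids = replicate(m, character(), simplify = FALSE))
  })
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}
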