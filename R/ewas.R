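#' Filter high-missingness probes/samples and impute the rest
#'
#' Applies the matrix QC rule used before modelling: probes with more than
#' `max_missing` missing values are dropped, then samples, then probes are
#' re-checked (this order is fixed so the filter is deterministic). Remaining
#' missing entries are imputed by the mean of the `k` nearest complete probes,
#' nearest by Euclidean distance over the samples where the target probe is
#' observed.
#'
#' @param beta Numeric matrix (probes x samples), values in \eqn{[0, 1]} or NA.
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @param k Number of neighbour probes used for imputation (default 10).
#' @return Filtered, complete beta matrix.
#' @export
filter_and_impute <- function(beta, max_missing = 0.05, k = 10) {
  if (max_missing < 0 || max_missing >= 1) abort("`max_missing` must be in [0, 1)")
  keep_p <- rowMeans(is.na(beta)) <= max_missing
  beta <- beta[keep_p, , drop = FALSE]
  if (nrow(beta) == 0) abort("empty matrix: every probe exceeded the missingness threshold")
  keep_s <- colMeans(is.na(beta)) <= max_missing
  beta <- beta[, keep_s, drop = FALSE]
  if (ncol(beta) == 0) abort("empty matrix: every sample exceeded the missingness threshold")
  keep_p2 <- rowMeans(is.na(beta)) <= max_missing
  beta <- beta[keep_p2, , drop = FALSE]
  if (nrow(beta) == 0) abort("empty matrix: every probe exceeded the missingness threshold")

  na_rows <- which(rowSums(is.na(beta)) > 0)
  if (length(na_rows) == 0) return(beta)

  complete <- which(rowSums(is.na(beta)) == 0)
  if (length(complete) == 0) {
    abort("no complete probes available as imputation neighbours")
  }
  kk <- min(k, length(complete))
  comp_mat <- beta[complete, , drop = FALSE]
  for (i in na_rows) {
    obs <- !is.na(beta[i, ])
    d2 <- colSums((t(comp_mat[, obs, drop = FALSE]) - beta[i, obs])^2)
    nn <- complete[order(d2)[seq_len(kk)]]
    miss <- which(!obs)
    beta[i, miss] <- colMeans(beta[nn, miss, drop = FALSE])
  }
  beta
}

# shared vectorised OLS over all probe rows against one design matrix;
# returns the marginal t-test for one design column
fit_lm_matrix <- function(m, X, term) {
  n <- ncol(m)
  q <- ncol(X)
  if (n != nrow(X)) abort("sample count of M matrix and design disagree")
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):q]]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  if (n <= q) abort("fewer samples than design columns")
  j <- match(term, colnames(X))
  if (is.na(j)) abort(sprintf("term `%s` not found in design", term))

  XtXi <- chol2inv(chol(crossprod(X)))
  B <- m %*% (X %*% XtXi)          # probes x q
  resid <- m - B %*% t(X)
  df <- n - q
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi[j, j])
  est <- B[, j]
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), df)

  degenerate <- matrixStats_row_var_zero(m)
  est[degenerate] <- 0
  se[degenerate] <- NA_real_
  tstat[degenerate] <- NA_real_
  pval[degenerate] <- 1

  tibble::tibble(
    probe_id = rownames(m),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(tstat),
    p.value = pmin(pmax(unname(pval), .Machine$double.xmin), 1),
    n = n,
    degenerate = unname(degenerate)
  )
}

# rows with zero variance give an exact fit and an undefined t statistic
matrixStats_row_var_zero <- function(m) {
  rng <- apply(m, 1, function(x) diff(range(x)))
  rng == 0
}

new_ewas_result <- function(tbl, model, term, manifest = NULL) {
  if (!is.null(manifest)) {
    tbl <- dplyr::left_join(tbl, manifest[, c("probe_id", "chrom", "pos")],
                            by = "probe_id")
    tbl <- dplyr::relocate(tbl, "probe_id", "chrom", "pos")
    tbl <- dplyr::arrange(tbl, .data$chrom, .data$pos)
  }
  structure(tbl, class = c("ewas_result", class(tbl)),
            model = model, term = term)
}

#' Per-probe multivariable linear regression on M-values
#'
#' Fits one ordinary least squares model per probe,
#' `M ~ term + adjustment covariates + components`, and reports the
#' coefficient, standard error and two-sided t-test p-value for the term of
#' interest. The 4-level supplemental dose is coded as an ordinal score
#' 0..3 with a single slope by default, so every probe carries one signed
#' effect for downstream direction averaging; set
#' `supplemental_coding = "factor"` for dummy coding (the reported row is
#' then the top-dose contrast).
#'
#' @param m M-value matrix (probes x samples) from [beta_to_m()].
#' @param covariates Tibble with one row per sample, same order as `m`
#'   columns.
#' @param term Name of the covariate column tested (e.g. `"dose_total"`).
#' @param adjust Character vector of adjustment columns (categorical columns
#'   are expanded to dummies).
#' @param components Optional numeric matrix (samples x components) of
#'   adjustment scores, e.g. from [refactor_components()] and
#'   [ancestry_components()].
#' @param manifest Optional probe manifest; when given, `chrom`/`pos` are
#'   attached so the result can feed [call_dmrs()] directly.
#' @param supplemental_coding `"ordinal"` (default) or `"factor"`; only
#'   relevant when `term` is the supplemental dose.
#' @return An `ewas_result` tibble: `probe_id`, `estimate` (M-value units per
#'   unit of term), `std.error`, `statistic`, `p.value`, `n`, `degenerate`.
#' @export
ewas_fit <- function(m, covariates, term, adjust = NULL, components = NULL,
                     manifest = NULL,
                     supplemental_coding = c("ordinal", "factor")) {
  supplemental_coding <- match.arg(supplemental_coding)
  if (!term %in% names(covariates)) {
    abort(sprintf("term `%s` not found in covariates", term))
  }
  dat <- covariates
  term_col <- term
  if (grepl("supplemental", term)) {
    lev <- c(0, 194, 360, 540)
    if (!all(dat[[term]] %in% lev)) {
      abort("supplemental doses must be one of 0, 194, 360, 540")
    }
    if (supplemental_coding == "ordinal") {
      dat[[term]] <- match(dat[[term]], lev) - 1
    } else {
      present <- lev[lev %in% dat[[term]]]
      dat[[term]] <- factor(dat[[term]], levels = present)
      term_col <- paste0(term, present[length(present)])
    }
  }
  fm <- stats::reformulate(c(term, adjust))
  X <- stats::model.matrix(fm, data = dat)
  if (!is.null(components)) {
    components <- as.matrix(components)
    if (nrow(components) != ncol(m)) abort("components rows must match samples")
    X <- cbind(X, components)
  }
  # model.matrix keeps numeric terms' names; categorical term gets suffix
  if (!term_col %in% colnames(X)) {
    cand <- grep(paste0("^", term_col), colnames(X), value = TRUE)
    if (length(cand) == 0) abort(sprintf("term `%s` missing after encoding", term))
    term_col <- cand[length(cand)]
  }
  res <- fit_lm_matrix(m, X, term_col)
  new_ewas_result(res, model = paste0("ewas:", term), term = term,
                  manifest = manifest)
}

#' Blast-vs-control EWAS with subtype adjustment
#'
#' Fits per-probe models of M-values on a blast indicator while controlling
#' for leukemia subtype and batch. Subtype is coded with sum-to-zero
#' contrasts among blasts (controls carry zeros), which keeps the
#' blast-vs-control column estimable — naive dummy coding of subtype would
#' be collinear with the indicator. The reported effect is the blast
#' indicator (M-value difference, blasts minus controls, at the average
#' subtype).
#'
#' @param m M-value matrix (probes x samples).
#' @param covariates Tibble with `group` (`"blast"`/`"control"`), `subtype`
#'   and `batch` columns.
#' @inheritParams ewas_fit
#' @return An `ewas_result` tibble, as [ewas_fit()].
#' @export
ewas_fit_blast <- function(m, covariates, manifest = NULL) {
  need <- c("group", "subtype", "batch")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols)) {
    abort(paste("covariates missing columns:", paste(missing_cols, collapse = ", ")))
  }
  blast <- as.numeric(covariates$group == "blast")
  if (all(blast == 1) || all(blast == 0)) abort("need both blasts and controls")

  X <- cbind(`(Intercept)` = 1, blast = blast)
  sub <- covariates$subtype[blast == 1]
  lev <- sort(unique(sub))
  if (length(lev) > 1) {
    C <- stats::contr.sum(length(lev))
    rownames(C) <- lev
    S <- matrix(0, nrow(covariates), ncol(C),
                dimnames = list(NULL, paste0("subtype", seq_len(ncol(C)))))
    S[blast == 1, ] <- C[covariates$subtype[blast == 1], , drop = FALSE]
    X <- cbind(X, S)
  }
  if (length(unique(covariates$batch)) > 1) {
    Bm <- stats::model.matrix(~batch, data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, Bm)
  }
  res <- fit_lm_matrix(m, X, "blast")
  new_ewas_result(res, model = "ewas:blast", term = "blast", manifest = manifest)
}

#' Genomic inflation factor lambda
#'
#' Ratio of the median association chi-square statistic (1 df) to its null
#' median 0.4549364. Lambda near 1 indicates a well-calibrated test;
#' epigenome-wide comparisons of distinct cell populations routinely show
#' lambda far above 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return The scalar inflation factor.
#' @examples
#' genomic_inflation(runif(1000))
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) == 0) abort("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  median(qchisq(1 - pvals, df = 1)) / qchisq(0.5, df = 1)
}

#' Count Bonferroni-significant probes
#'
#' Report statistic: number of probes with p below `alpha / n_tested`.
#'
#' @param pvals P-value vector.
#' @param alpha Family-wise level (default 0.05).
#' @return Integer count.
#' @export
n_bonferroni_significant <- function(pvals, alpha = 0.05) {
  sum(pvals < alpha / length(pvals))
}
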