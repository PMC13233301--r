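#' Overlap exposure DMRs with disease DMRs
#'
#' Emits one pair for every (exposure region, disease region) combination
#' sharing at least one base on the same chromosome, under half-open
#' interval semantics — touching intervals such as [100, 200) and [200, 300)
#' do not overlap. Each overlapping pair is one counting unit for the
#' concordance test.
#'
#' @param folate_regions,blast_regions Region tibbles with `chrom`, `start`,
#'   `end`, `probe_ids` (e.g. from [call_dmrs()]); each list must be
#'   internally non-overlapping.
#' @return Tibble of pairs with `_folate` / `_blast` suffixed region columns
#'   plus the intersection interval `int_start`, `int_end`.
#' @export
overlap_dmrs <- function(folate_regions, blast_regions) {
  f <- tibble::as_tibble(folate_regions)
  b <- tibble::as_tibble(blast_regions)
  if (nrow(f) == 0 || nrow(b) == 0) {
    return(tibble::tibble())
  }
  pairs <- dplyr::inner_join(
    dplyr::rename_with(f, ~ paste0(.x, "_folate"), -"chrom"),
    dplyr::rename_with(b, ~ paste0(.x, "_blast"), -"chrom"),
    by = "chrom", relationship = "many-to-many"
  )
  pairs <- dplyr::filter(pairs,
                         .data$start_folate < .data$end_blast,
                         .data$start_blast < .data$end_folate)
  pairs$int_start <- pmax(pairs$start_folate, pairs$start_blast)
  pairs$int_end <- pmin(pairs$end_folate, pairs$end_blast)
  dplyr::arrange(pairs, .data$chrom, .data$int_start)
}

mean_coef <- function(probes, ewas) {
  idx <- match(probes, ewas$probe_id)
  found <- !is.na(idx)
  if (!any(found)) return(NA_real_)
  mean(ewas$estimate[idx[found]])
}

#' Assign region directions and the concordance verdict to overlap pairs
#'
#' The exposure (folate) direction is the sign of the mean exposure
#' coefficient over the folate region's own member probes; the disease
#' direction is derived from Set A and Set B coefficient means over the
#' blast region's member probes. Pairs where Set A and Set B disagree in
#' sign are marked discordant between sets and excluded from the evaluable
#' denominator, as are pairs with an exact-zero mean or with no coefficient
#' coverage.
#'
#' @param pairs Output of [overlap_dmrs()].
#' @param folate_ewas `ewas_result` for the exposure model.
#' @param blast_a,blast_b `ewas_result`s for the two blast sets.
#' @return The pairs tibble completed with `mean_folate`, `mean_a`,
#'   `mean_b`, `folate_dir`, `blast_dir`, `evaluable` and `concordant`.
#' @export
assign_directions <- function(pairs, folate_ewas, blast_a, blast_b) {
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, mean_folate = numeric(), mean_a = numeric(),
                         mean_b = numeric(), folate_dir = character(),
                         blast_dir = character(), evaluable = logical(),
                         concordant = logical()))
  }
  pairs$mean_folate <- vapply(pairs$probe_ids_folate, mean_coef, numeric(1),
                              ewas = folate_ewas)
  pairs$mean_a <- vapply(pairs$probe_ids_blast, mean_coef, numeric(1),
                         ewas = blast_a)
  pairs$mean_b <- vapply(pairs$probe_ids_blast, mean_coef, numeric(1),
                         ewas = blast_b)

  sgn <- function(x) ifelse(is.na(x), NA, sign(x))
  sa <- sgn(pairs$mean_a)
  sb <- sgn(pairs$mean_b)
  sf <- sgn(pairs$mean_folate)

  pairs$folate_dir <- dplyr::case_when(
    is.na(sf) | sf == 0 ~ "indeterminate",
    sf > 0 ~ "+",
    TRUE ~ "-"
  )
  pairs$blast_dir <- dplyr::case_when(
    is.na(sa) | is.na(sb) | sa == 0 | sb == 0 ~ "indeterminate",
    sa != sb ~ "discordant",
    sa > 0 ~ "+",
    TRUE ~ "-"
  )
  pairs$evaluable <- pairs$folate_dir %in% c("+", "-") &
    pairs$blast_dir %in% c("+", "-")
  n_dropped <- sum(!pairs$evaluable)
  if (n_dropped > 0) {
    inform(sprintf(
      "assign_directions: %d of %d pairs omitted (cross-set discordant or indeterminate)",
      n_dropped, nrow(pairs)))
  }
  pairs$concordant <- ifelse(pairs$evaluable,
                             pairs$folate_dir == pairs$blast_dir, NA)
  pairs
}

#' Exact two-sided binomial test of direction concordance
#'
#' Tests whether `k` concordant pairs out of `n` evaluable overlaps depart
#' from the chance rate 1/2, with the two-sided p-value defined as the
#' doubled smaller tail capped at 1:
#' \eqn{p = \min(1, 2\min\{P(X \le k), P(X \ge k)\})},
#' \eqn{X \sim \mathrm{Bin}(n, 1/2)}.
#'
#' @param k Concordant count.
#' @param n Total evaluable overlaps; `n = 0` returns `NA` ("not
#'   evaluable") rather than an error.
#' @return Two-sided exact p-value (or `NA` when `n = 0`).
#' @examples
#' concordance_binomial(16, 18)
#' @export
concordance_binomial <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 0 || k > n) {
    abort("need scalar counts with 0 <= k <= n")
  }
  if (n == 0) return(NA_real_)
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Select the samples belonging to a demographic subgroup
#'
#' Filters a covariate table by ethnicity and/or an income split at
#' `income_cut` dollars: `"low"` means strictly below the cut, `"high"`
#' means at or above it (an income of exactly the cut is high).
#'
#' @param covariates Covariate tibble with `sample_id`, `ethnicity`,
#'   `income`.
#' @param ethnicity Ethnicity label to keep, or `NULL` for all.
#' @param income_side `"low"`, `"high"`, or `NULL` for all.
#' @param income_cut Dollar threshold (default 75000).
#' @return Character vector of sample ids; errors if the subgroup is empty
#'   (such strata are excluded from analysis rather than run on no data).
#' @export
run_subgroup <- function(covariates, ethnicity = NULL, income_side = NULL,
                         income_cut = 75000) {
  keep <- rep(TRUE, nrow(covariates))
  if (!is.null(ethnicity)) keep <- keep & covariates$ethnicity == ethnicity
  if (!is.null(income_side)) {
    income_side <- match.arg(income_side, c("low", "high"))
    side <- if (income_side == "low") {
      covariates$income < income_cut
    } else {
      covariates$income >= income_cut
    }
    keep <- keep & side
  }
  ids <- covariates$sample_id[keep]
  if (length(ids) == 0) {
    abort("subgroup is empty; analysis not completed for this stratum")
  }
  ids
}

#' Summarise concordance for one folate source and subgroup
#'
#' Counts evaluable and concordant overlap pairs, computes the exact
#' binomial p-value and labels the direction of bias when significant.
#'
#' @param pairs Completed pairs from [assign_directions()].
#' @param source Folate source label.
#' @param subgroup Subgroup label (default `"all"`).
#' @param alpha Significance level for the bias label (default 0.05).
#' @return One-row `concordance_summary` tibble: `source`, `subgroup`, `k`,
#'   `n`, `p.value`, `bias` (`"concordant"`, `"discordant"`, `"none"`, or
#'   `"not evaluable"`).
#' @export
summarize_concordance <- function(pairs, source, subgroup = "all",
                                  alpha = 0.05) {
  n <- if (nrow(pairs) == 0) 0L else sum(pairs$evaluable)
  k <- if (n == 0) 0L else sum(pairs$concordant[pairs$evaluable])
  p <- concordance_binomial(k, n)
  bias <- "none"
  if (n == 0) {
    bias <- "not evaluable"
  } else if (!is.na(p) && p < alpha) {
    bias <- if (k / n > 0.5) "concordant" else "discordant"
  }
  structure(
    tibble::tibble(source = source, subgroup = subgroup,
                   k = as.integer(k), n = as.integer(n),
                   p.value = p, bias = bias),
    class = c("concordance_summary", "tbl_df", "tbl", "data.frame"))
}
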