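#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an EWAS result
#'
#' Returns the per-probe coefficient table as a plain tibble with a `term`
#' column, in broom column conventions.
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return Tibble with `probe_id`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy ewas_result
#' @export
tidy.ewas_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$term <- attr(x, "term")
  dplyr::relocate(out, "term", .after = "probe_id")
}

#' One-row model summary of an EWAS result
#'
#' @param x An `ewas_result`.
#' @param ... Unused.
#' @return Tibble with probe count, sample size, genomic inflation lambda
#'   and the Bonferroni-significant probe count.
#' @method glance ewas_result
#' @export
glance.ewas_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    n_samples = x$n[1],
    lambda = genomic_inflation(x$p.value),
    n_bonferroni = n_bonferroni_significant(x$p.value)
  )
}

#' @rdname tidy.ewas_result
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname glance.ewas_result
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x),
    lambda = genomic_inflation(x$p.value),
    n_bonferroni = n_bonferroni_significant(x$p.value)
  )
}

#' Tidy the concordance table out of a pipeline report
#'
#' @param x A `mitm_report`.
#' @param ... Unused.
#' @return The concordance summary tibble.
#' @method tidy mitm_report
#' @export
tidy.mitm_report <- function(x, ...) x$concordance

#' @rdname tidy.mitm_report
#' @return For `glance()`: one row with model lambdas and DMR counts.
#' @method glance mitm_report
#' @export
glance.mitm_report <- function(x, ...) {
  tibble::tibble(
    n_meta_probes = nrow(x$meta),
    lambda_meta = x$lambdas$lambda[x$lambdas$model == "blast_meta"],
    n_blast_dmrs = nrow(x$blast_dmrs),
    n_folate_dmrs = sum(vapply(x$folate_dmrs, nrow, numeric(1))),
    n_evaluable_overlaps = sum(x$concordance$n)
  )
}
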