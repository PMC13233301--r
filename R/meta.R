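#' Pair two EWAS result tables on shared probes
#'
#' Inner join on `probe_id`; probes absent from either set are excluded and
#' the excluded count reported via a message, mirroring the restriction of a
#' cross-platform meta-analysis to the probes both arrays measure.
#'
#' @param res_a,res_b `ewas_result` tibbles (e.g. Set A on a 450k-like
#'   array, Set B on an EPIC-like array).
#' @return Paired tibble with `_a` / `_b` suffixed columns.
#' @export
align_probes <- function(res_a, res_b) {
  keep <- intersect(names(res_a), c("probe_id", "chrom", "pos", "estimate",
                                    "std.error", "p.value", "n"))
  a <- tibble::as_tibble(res_a)[, keep]
  b <- tibble::as_tibble(res_b)[, intersect(names(res_b),
                                            c("probe_id", "estimate",
                                              "std.error", "p.value", "n"))]
  paired <- dplyr::inner_join(a, b, by = "probe_id", suffix = c("_a", "_b"))
  if (nrow(paired) == 0) abort("no shared probes between the two result sets")
  dropped <- nrow(a) + nrow(b) - 2 * nrow(paired)
  if (dropped > 0) {
    inform(sprintf("align_probes: %d probes present in only one set were dropped",
                   dropped))
  }
  paired
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Combines the two per-probe results with the weighted-z scheme: each study
#' contributes \eqn{z_i = \mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1 - p_i/2)}
#' and the combined statistic is
#' \eqn{Z = (\sqrt{n_A} z_A + \sqrt{n_B} z_B)/\sqrt{n_A + n_B}} with
#' two-sided p-value \eqn{2(1 - \Phi(|Z|))}. This scheme pools evidence
#' without assuming the two platforms' effect sizes share a variance scale;
#' `scheme = "ivw"` gives the inverse-variance-weighted alternative.
#'
#' @param paired Output of [align_probes()].
#' @param scheme `"samplesize"` (default) or `"ivw"`.
#' @return Tibble with `probe_id` (plus `chrom`/`pos` when present), `z`,
#'   `p.value`, `sign_a`, `sign_b`, `n_total`.
#' @export
stouffer_meta <- function(paired, scheme = c("samplesize", "ivw")) {
  scheme <- match.arg(scheme)
  p_a <- clip_p(paired$p.value_a)
  p_b <- clip_p(paired$p.value_b)
  z_a <- sign(paired$estimate_a) * qnorm(p_a / 2, lower.tail = FALSE)
  z_b <- sign(paired$estimate_b) * qnorm(p_b / 2, lower.tail = FALSE)

  if (scheme == "samplesize") {
    z <- (sqrt(paired$n_a) * z_a + sqrt(paired$n_b) * z_b) /
      sqrt(paired$n_a + paired$n_b)
  } else {
    w_a <- 1 / paired$std.error_a^2
    w_b <- 1 / paired$std.error_b^2
    est <- (w_a * paired$estimate_a + w_b * paired$estimate_b) / (w_a + w_b)
    z <- est * sqrt(w_a + w_b)
  }

  out <- tibble::tibble(
    probe_id = paired$probe_id,
    z = z,
    p.value = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
    sign_a = sign(paired$estimate_a),
    sign_b = sign(paired$estimate_b),
    n_total = paired$n_a + paired$n_b
  )
  if (all(c("chrom", "pos") %in% names(paired))) {
    out <- dplyr::bind_cols(out[, "probe_id"],
                            paired[, c("chrom", "pos")],
                            out[, -1])
  }
  structure(out, class = c("meta_result", class(out)))
}
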