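#' Configuration for the synthetic methylation study
#'
#' Bundles every knob of the simulator into one validated object. The
#' defaults emulate the design of the motivating study: a birth cohort of 394
#' neonatal blood-spot samples with folate exposure doses, and two leukemic
#' blast datasets — Set A (227 blasts vs 6 sorted pre-B controls, restricted
#' to 450k-style shared probes) and Set B (37 blasts vs 10 controls, full
#' EPIC-style probe set).
#'
#' @param n_probes Total probes on the EPIC-like array.
#' @param n_chromosomes Number of chromosomes the probes are spread over.
#' @param probe_spacing_mean Mean inter-probe gap in base pairs; gaps are
#'   exponential, so a planted region occasionally spans more than the 1000 bp
#'   merge distance and is legitimately split by the DMR caller.
#' @param frac_shared_probes Fraction of probes present on both arrays
#'   (450k-like and EPIC-like).
#' @param n_cohort_samples Birth-cohort sample count.
#' @param n_blast_a,n_control_a Set A blast / control counts.
#' @param n_blast_b,n_control_b Set B blast / control counts.
#' @param n_cell_types Latent nucleated cell types mixed in cohort samples.
#' @param n_exposure_regions Regions carrying only an exposure effect.
#' @param n_disease_regions Regions carrying only a blast-vs-control effect.
#' @param n_overlap_regions Regions carrying both effects; these are the
#'   meet-in-the-middle truth.
#' @param region_n_probes Length-2 integer range for probes per planted region.
#' @param delta_beta_exposure Beta-scale shift per 1 SD of exposure dose at
#'   exposure-region probes (converted to an additive M-scale effect at a 0.5
#'   baseline).
#' @param delta_beta_disease Beta-scale blast-vs-control difference at
#'   disease-region probes.
#' @param concordance_fraction Fraction of overlap regions planted with
#'   same-sign exposure and disease effects.
#' @param noise_sd Residual SD on the M scale.
#' @param frac_set_discordant Fraction of disease-affected regions whose Set B
#'   effect sign is flipped relative to Set A (exercises the cross-set
#'   discordance filter).
#' @param n_ancestry_probes Number of ancestry-informative probes.
#' @param missing_rate Fraction of beta entries set missing in the cohort.
#' @param exposure_source Dose column driving the planted exposure effect.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `synth_config` list.
#' @examples
#' cfg <- synth_config(n_probes = 2000, seed = 7)
#' cfg$n_cohort_samples
#' @export
synth_config <- function(n_probes = 20000,
                         n_chromosomes = 5,
                         probe_spacing_mean = 500,
                         frac_shared_probes = 0.7,
                         n_cohort_samples = 394,
                         n_blast_a = 227, n_control_a = 6,
                         n_blast_b = 37, n_control_b = 10,
                         n_cell_types = 3,
                         n_exposure_regions = 10,
                         n_disease_regions = 10,
                         n_overlap_regions = 20,
                         region_n_probes = c(5L, 8L),
                         delta_beta_exposure = 0.1,
                         delta_beta_disease = 0.2,
                         concordance_fraction = 0.9,
                         noise_sd = 0.5,
                         frac_set_discordant = 0,
                         n_ancestry_probes = 300,
                         missing_rate = 0,
                         exposure_source = "total",
                         seed = 1L) {
  cfg <- list(
    n_probes = check_count(n_probes, "n_probes"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    probe_spacing_mean = probe_spacing_mean,
    frac_shared_probes = check_fraction(frac_shared_probes, "frac_shared_probes"),
    n_cohort_samples = check_count(n_cohort_samples, "n_cohort_samples"),
    n_blast_a = check_count(n_blast_a, "n_blast_a"),
    n_control_a = check_count(n_control_a, "n_control_a"),
    n_blast_b = check_count(n_blast_b, "n_blast_b"),
    n_control_b = check_count(n_control_b, "n_control_b"),
    n_cell_types = check_count(n_cell_types, "n_cell_types"),
    n_exposure_regions = check_count(n_exposure_regions, "n_exposure_regions", min = 0),
    n_disease_regions = check_count(n_disease_regions, "n_disease_regions", min = 0),
    n_overlap_regions = check_count(n_overlap_regions, "n_overlap_regions", min = 0),
    region_n_probes = as.integer(region_n_probes),
    delta_beta_exposure = delta_beta_exposure,
    delta_beta_disease = delta_beta_disease,
    concordance_fraction = check_fraction(concordance_fraction, "concordance_fraction"),
    noise_sd = noise_sd,
    frac_set_discordant = check_fraction(frac_set_discordant, "frac_set_discordant"),
    n_ancestry_probes = check_count(n_ancestry_probes, "n_ancestry_probes"),
    missing_rate = check_fraction(missing_rate, "missing_rate"),
    exposure_source = match.arg(exposure_source,
                                c("total", "food", "fortified", "natural", "supplemental")),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(cfg$region_n_probes) != 2 || any(cfg$region_n_probes < 2) ||
      cfg$region_n_probes[1] > cfg$region_n_probes[2]) {
    abort("`region_n_probes` must be an increasing length-2 range with minimum >= 2")
  }
  if (!is.numeric(probe_spacing_mean) || probe_spacing_mean <= 0) {
    abort("`probe_spacing_mean` must be positive")
  }
  if (cfg$delta_beta_exposure < 0 || cfg$delta_beta_exposure >= 0.5 ||
      cfg$delta_beta_disease < 0 || cfg$delta_beta_disease >= 0.5) {
    abort("delta_beta effects must lie in [0, 0.5) so beta stays inside (0, 1)")
  }
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be positive")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d probes on %d chromosomes (%.0f%% shared across arrays)\n",
              x$n_probes, x$n_chromosomes, 100 * x$frac_shared_probes))
  cat(sprintf("  cohort n = %d; Set A %d + %d; Set B %d + %d\n",
              x$n_cohort_samples, x$n_blast_a, x$n_control_a,
              x$n_blast_b, x$n_control_b))
  cat(sprintf("  planted regions: %d exposure / %d disease / %d overlap (concordance %.2f)\n",
              x$n_exposure_regions, x$n_disease_regions, x$n_overlap_regions,
              x$concordance_fraction))
  invisible(x)
}
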