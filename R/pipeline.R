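#' Assemble a pipeline configuration
#'
#' The driver runs either from a synthetic scenario (a [synth_config()]) or
#' from files on disk (manifest, beta matrices, covariate tables, ancestry
#' probe list, in the package's TSV dialect).
#'
#' @param scenario A [synth_config()], or `NULL` when running from files.
#' @param paths Named list of file paths (`manifest`, `cohort_beta`,
#'   `cohort_covariates`, `blast_a_beta`, `blast_a_covariates`,
#'   `blast_b_beta`, `blast_b_covariates`, `ancestry_probes`); ignored when
#'   `scenario` is given.
#' @param sources Folate sources to analyse, a subset of
#'   `c("total", "food", "fortified", "natural", "supplemental")`.
#' @param subgroups List of subgroup specs, each a list with optional
#'   `ethnicity`, `income_side` and a `label`.
#' @param max_missing Missingness threshold for [filter_and_impute()].
#' @param n_cell_pcs,n_ancestry_pcs Number of adjustment components.
#' @param dmr Named list of [call_dmrs()] arguments overriding its defaults.
#' @param seed Seed used when simulating the scenario.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL,
                            sources = c("total", "food", "fortified",
                                        "natural", "supplemental"),
                            subgroups = list(),
                            max_missing = 0.05,
                            n_cell_pcs = 10, n_ancestry_pcs = 10,
                            dmr = list(), seed = 1L) {
  sources <- match.arg(sources, several.ok = TRUE)
  if (length(sources) == 0) abort("at least one folate source is required")
  if (is.null(scenario) && is.null(paths)) {
    abort("either a synthetic `scenario` or input `paths` must be given")
  }
  structure(list(scenario = scenario, paths = paths, sources = sources,
                 subgroups = subgroups, max_missing = max_missing,
                 n_cell_pcs = n_cell_pcs, n_ancestry_pcs = n_ancestry_pcs,
                 dmr = dmr, seed = check_count(seed, "seed", min = 0)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; a `scenario:` block holds
#' [synth_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scenario <- if (!is.null(raw$scenario)) do.call(synth_config, raw$scenario)
  args <- raw[setdiff(names(raw), "scenario")]
  args$scenario <- scenario
  do.call(pipeline_config, args)
}

meta_track <- function(meta) {
  tibble::tibble(probe_id = meta$probe_id, chrom = meta$chrom,
                 pos = meta$pos, p.value = meta$p.value)
}

#' Run the full meet-in-the-middle pipeline
#'
#' Executes filter/impute, component derivation, the folate EWAS for each
#' requested source, the two blast EWAS, their meta-analysis, DMR calling on
#' every track, and overlap + concordance summaries per source (and per
#' subgroup). Fully reproducible given the configuration seed.
#'
#' @param config A [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return A `mitm_report` list: inputs, per-source EWAS results and DMRs,
#'   blast results, meta-analysis, lambda table, Bonferroni counts and
#'   hypo/hyper split, overlap pairs and the concordance summary tibble.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", load_pipeline_inputs(config))
  manifest <- inputs$manifest

  cohort_beta <- stage("filter_impute",
                       filter_and_impute(inputs$cohort_beta, config$max_missing))
  cohort_m <- beta_to_m(cohort_beta)

  cell_pcs <- stage("cell_components",
                    refactor_components(cohort_beta,
                                        n_components = config$n_cell_pcs))
  anc_pcs <- stage("ancestry_components",
                   ancestry_components(cohort_beta, inputs$ancestry_probes,
                                       n_components = config$n_ancestry_pcs))
  comps <- cbind(cell_pcs, anc_pcs)

  covariates <- inputs$cohort_covariates
  fit_source <- function(src, sample_ids = NULL) {
    sel <- if (is.null(sample_ids)) seq_len(ncol(cohort_m)) else
      match(sample_ids, colnames(cohort_m))
    ewas_fit(cohort_m[, sel, drop = FALSE],
             covariates[match(colnames(cohort_m)[sel], covariates$sample_id), ],
             term = paste0("dose_", src),
             adjust = c("case", "sex", "batch"),
             components = comps[sel, , drop = FALSE],
             manifest = manifest)
  }

  folate_ewas <- lapply(setNames(config$sources, config$sources), function(src) {
    stage(paste0("folate_ewas_", src), fit_source(src))
  })

  blast_a_beta <- stage("filter_impute_a",
                        filter_and_impute(inputs$blast_a_beta, config$max_missing))
  blast_b_beta <- stage("filter_impute_b",
                        filter_and_impute(inputs$blast_b_beta, config$max_missing))
  blast_a <- stage("blast_ewas_a",
                   ewas_fit_blast(beta_to_m(blast_a_beta),
                                  inputs$blast_a_covariates, manifest = manifest))
  blast_b <- stage("blast_ewas_b",
                   ewas_fit_blast(beta_to_m(blast_b_beta),
                                  inputs$blast_b_covariates, manifest = manifest))
  meta <- stage("meta", stouffer_meta(align_probes(blast_a, blast_b)))

  dmr_args <- config$dmr
  call_track <- function(track) do.call(call_dmrs, c(list(track), dmr_args))

  blast_dmrs <- stage("blast_dmrs", call_track(meta_track(meta)))
  folate_dmrs <- lapply(folate_ewas, function(res) call_track(res))

  split <- hypo_hyper_split(meta)

  lambdas <- tibble::tibble(
    model = c("blast_set_a", "blast_set_b", "blast_meta",
              paste0("folate_", config$sources)),
    lambda = c(genomic_inflation(blast_a$p.value),
               genomic_inflation(blast_b$p.value),
               genomic_inflation(meta$p.value),
               vapply(folate_ewas, function(r) genomic_inflation(r$p.value),
                      numeric(1))),
    n_probes = c(nrow(blast_a), nrow(blast_b), nrow(meta),
                 vapply(folate_ewas, nrow, numeric(1))),
    n_bonferroni = c(n_bonferroni_significant(blast_a$p.value),
                     n_bonferroni_significant(blast_b$p.value),
                     n_bonferroni_significant(meta$p.value),
                     vapply(folate_ewas,
                            function(r) n_bonferroni_significant(r$p.value),
                            numeric(1)))
  )

  mitm_one <- function(src, f_dmrs, f_ewas, subgroup_label) {
    pairs <- assign_directions(overlap_dmrs(f_dmrs, blast_dmrs),
                               f_ewas, blast_a, blast_b)
    list(pairs = pairs,
         summary = summarize_concordance(pairs, src, subgroup_label))
  }

  overlaps <- list()
  summaries <- list()
  for (src in config$sources) {
    res <- stage(paste0("mitm_", src),
                 mitm_one(src, folate_dmrs[[src]], folate_ewas[[src]], "all"))
    overlaps[[paste(src, "all", sep = ".")]] <- res$pairs
    summaries[[length(summaries) + 1L]] <- res$summary
  }

  for (sg in config$subgroups) {
    label <- sg$label %||% paste(c(sg$ethnicity, sg$income_side), collapse = "_")
    ids <- stage(paste0("subgroup_", label),
                 run_subgroup(covariates, ethnicity = sg$ethnicity,
                              income_side = sg$income_side))
    ids <- intersect(ids, colnames(cohort_m))
    for (src in config$sources) {
      res <- stage(paste0("mitm_", src, "_", label), {
        f_ewas <- fit_source(src, sample_ids = ids)
        f_dmrs <- call_track(f_ewas)
        mitm_one(src, f_dmrs, f_ewas, label)
      })
      overlaps[[paste(src, label, sep = ".")]] <- res$pairs
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }

  structure(list(
    config = config,
    manifest = manifest,
    truth = inputs$truth,
    folate_ewas = folate_ewas,
    blast_a = blast_a, blast_b = blast_b, meta = meta,
    folate_dmrs = folate_dmrs, blast_dmrs = blast_dmrs,
    lambdas = lambdas,
    hypo_hyper = split,
    overlaps = overlaps,
    concordance = dplyr::bind_rows(summaries)
  ), class = "mitm_report")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    cfg <- config$scenario
    manifest <- make_manifest(cfg)
    truth <- make_truth(cfg, manifest)
    cohort <- simulate_cohort(cfg, manifest, truth)
    blasts <- simulate_blast_sets(cfg, manifest, truth)
    list(manifest = manifest, truth = truth,
         cohort_beta = cohort$beta, cohort_covariates = cohort$covariates,
         blast_a_beta = blasts$beta_a, blast_a_covariates = blasts$covariates_a,
         blast_b_beta = blasts$beta_b, blast_b_covariates = blasts$covariates_b,
         ancestry_probes = truth$ancestry_probes)
  } else {
    p <- config$paths
    list(manifest = read_manifest_tsv(p$manifest), truth = NULL,
         cohort_beta = read_beta_tsv(p$cohort_beta),
         cohort_covariates = readr::read_tsv(p$cohort_covariates,
                                             show_col_types = FALSE),
         blast_a_beta = read_beta_tsv(p$blast_a_beta),
         blast_a_covariates = readr::read_tsv(p$blast_a_covariates,
                                              show_col_types = FALSE),
         blast_b_beta = read_beta_tsv(p$blast_b_beta),
         blast_b_covariates = readr::read_tsv(p$blast_b_covariates,
                                              show_col_types = FALSE),
         ancestry_probes = readLines(p$ancestry_probes))
  }
}

#' Split Bonferroni-significant probes by methylation direction
#'
#' Among probes passing the Bonferroni threshold, counts those with a
#' negative meta z-score (hypomethylated in blasts) and positive
#' (hypermethylated).
#'
#' @param meta A [stouffer_meta()] result.
#' @param alpha Family-wise level before division by the probe count.
#' @return Tibble with `hypo`, `hyper` and `n_significant`.
#' @export
hypo_hyper_split <- function(meta, alpha = 0.05) {
  sig <- meta$p.value < alpha / nrow(meta)
  tibble::tibble(hypo = sum(sig & meta$z < 0),
                 hyper = sum(sig & meta$z > 0),
                 n_significant = sum(sig))
}

#' Two-sample t-test from summary statistics
#'
#' Cohort-table comparisons often have to be reproduced from printed means,
#' SDs and group sizes. The default is the Welch (unequal-variance) test
#' with Welch-Satterthwaite degrees of freedom; `var_equal = TRUE` gives the
#' pooled-variance variant.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @examples
#' welch_t_from_summary(277.8, 145.2, 41, 203.0, 84.5, 37)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) abort("need n >= 2 in both groups")
  if (sd1 <= 0 || sd2 <= 0) abort("need positive SDs")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  tibble::tibble(statistic = tstat, df = df,
                 p.value = 2 * pt(-abs(tstat), df))
}

#' Expected-vs-observed quantile coordinates for a QQ plot
#'
#' @param pvals P-value vector.
#' @return Tibble with `expected` and `observed` \eqn{-\log_{10}} p
#'   coordinates; expected quantiles are \eqn{-\log_{10}((i - 0.5)/n)}.
#' @export
qq_data <- function(pvals) {
  n <- length(pvals)
  tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                 observed = -log10(sort(clip_p(pvals))))
}

#' Write a pipeline report bundle to disk
#'
#' Emits every intermediate as a plain-text artifact: per-model EWAS and
#' meta TSVs, QQ coordinates, the lambda table, DMR BED files, overlap
#' TSVs, the concordance summary and a run log, so each summary number is
#' recomputable from retained files.
#'
#' @param report A `mitm_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mitm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(dir, paste0(...))

  write_ewas <- function(res, name) {
    out <- tibble::as_tibble(res)
    readr::write_tsv(out, path(name, ".tsv"))
    readr::write_tsv(qq_data(res$p.value), path(name, "_qq.tsv"))
  }
  for (src in names(report$folate_ewas)) {
    write_ewas(report$folate_ewas[[src]], paste0("ewas_folate_", src))
  }
  write_ewas(report$blast_a, "ewas_blast_a")
  write_ewas(report$blast_b, "ewas_blast_b")
  readr::write_tsv(tibble::as_tibble(report$meta), path("meta_blast.tsv"))
  readr::write_tsv(qq_data(report$meta$p.value), path("meta_blast_qq.tsv"))
  readr::write_tsv(report$lambdas, path("lambda_table.tsv"))
  readr::write_tsv(report$hypo_hyper, path("hypo_hyper.tsv"))

  write_dmr_bed(report$blast_dmrs, path("dmr_blast.bed"))
  for (src in names(report$folate_dmrs)) {
    write_dmr_bed(report$folate_dmrs[[src]], path("dmr_folate_", src, ".bed"))
  }
  for (nm in names(report$overlaps)) {
    ov <- report$overlaps[[nm]]
    if (nrow(ov) > 0) {
      ov$probe_ids_folate <- vapply(ov$probe_ids_folate, paste, "", collapse = ",")
      ov$probe_ids_blast <- vapply(ov$probe_ids_blast, paste, "", collapse = ",")
    }
    readr::write_tsv(ov, path("overlaps_", nm, ".tsv"))
  }
  readr::write_tsv(report$concordance, path("concordance_summary.tsv"))

  log_lines <- c(
    sprintf("mitmethyl run log (%s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("sources: %s", paste(report$config$sources, collapse = ", ")),
    sprintf("seed: %d", report$config$seed),
    sprintf("dmr params: %s",
            if (length(report$config$dmr)) {
              paste(names(report$config$dmr), unlist(report$config$dmr),
                    sep = "=", collapse = ", ")
            } else "defaults"),
    sprintf("probes in meta-analysis: %d", nrow(report$meta)),
    sprintf("blast DMRs: %d", nrow(report$blast_dmrs))
  )
  writeLines(log_lines, path("run_log.txt"))
  invisible(dir)
}

#' @export
print.mitm_report <- function(x, ...) {
  cat("<mitm_report>\n")
  cat(sprintf("  sources: %s\n", paste(x$config$sources, collapse = ", ")))
  cat(sprintf("  meta probes: %d; blast DMRs: %d\n",
              nrow(x$meta), nrow(x$blast_dmrs)))
  cat("  concordance summary:\n")
  print(x$concordance)
  invisible(x)
}
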