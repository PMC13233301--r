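#' Generate a probe manifest for the synthetic arrays
#'
#' Probes are laid down per chromosome with exponential inter-probe gaps of
#' mean `probe_spacing_mean`, then flagged for array membership: a fraction
#' `frac_shared_probes` sit on both the 450k-like and EPIC-like arrays, the
#' remainder are EPIC-only. Positions are 1-based point coordinates, strictly
#' increasing within a chromosome.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with columns `probe_id`, `chrom`, `pos`, `on_450k`,
#'   `on_epic`, sorted by (chrom, pos).
#' @examples
#' man <- make_manifest(synth_config(n_probes = 1000, seed = 3))
#' head(man)
#' @export
make_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  per_chrom <- diff(round(seq(0, cfg$n_probes, length.out = cfg$n_chromosomes + 1)))
  rows <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    n <- per_chrom[ci]
    gaps <- pmax(2, round(rexp(n, rate = 1 / cfg$probe_spacing_mean)))
    tibble::tibble(
      chrom = sprintf("chr%d", ci),
      pos = 10000L + cumsum(as.integer(gaps))
    )
  })
  man <- dplyr::bind_rows(rows)
  man$probe_id <- sprintf("cg%07d", seq_len(nrow(man)))
  man$on_450k <- runif(nrow(man)) < cfg$frac_shared_probes
  man$on_epic <- TRUE
  man[, c("probe_id", "chrom", "pos", "on_450k", "on_epic")]
}

# Additive effects are planted on the M scale; an effect quoted as a
# beta-scale shift delta is converted at the 0.5 baseline where
# beta_to_m(0.5) = 0, i.e. effect_m = log2((0.5+delta)/(0.5-delta)).
delta_beta_to_m <- function(delta) beta_to_m(0.5 + delta)

#' Plant the ground truth shared by the cohort and blast simulators
#'
#' Selects non-overlapping runs of consecutive manifest probes as planted
#' regions of three kinds (exposure-only, disease-only, overlap), assigns
#' signed M-scale effects, and fixes the latent structure (cell-type
#' methylation profiles, ancestry-informative probes and their loadings) that
#' both simulators share. Deterministic given `cfg$seed`, so
#' [simulate_cohort()] and [simulate_blast_sets()] agree on where the truth
#' lives.
#'
#' @inheritParams make_manifest
#' @param manifest Output of [make_manifest()].
#' @return A `mitm_truth` list: `regions` tibble (with 0-based half-open
#'   `start`/`end`, member `probe_ids` list-column, signed effects and the
#'   `concordant` flag for overlap regions), `ancestry_probes`,
#'   `ancestry_loadings`, `baseline_m`, and `cell_profiles` (probes x cell
#'   types, M scale).
#' @export
make_truth <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)

  n_reg <- cfg$n_exposure_regions + cfg$n_disease_regions + cfg$n_overlap_regions
  len_choices <- seq(cfg$region_n_probes[1], cfg$region_n_probes[2])
  lens <- len_choices[sample.int(length(len_choices), n_reg, replace = TRUE)]
  used <- rep(FALSE, nrow(manifest))
  chrom <- manifest$chrom
  starts <- integer(n_reg)
  placed <- 0L
  tries <- 0L
  while (placed < n_reg && tries < 50L * n_reg) {
    tries <- tries + 1L
    L <- lens[placed + 1L]
    i <- sample.int(nrow(manifest) - L, 1L)
    idx <- i:(i + L - 1L)
    # 3-probe buffer keeps planted regions from merging into one another
    buf <- max(1L, i - 3L):min(nrow(manifest), i + L + 2L)
    if (chrom[i] == chrom[i + L - 1L] && !any(used[buf])) {
      used[buf] <- TRUE
      placed <- placed + 1L
      starts[placed] <- i
    }
  }
  if (placed < n_reg) {
    abort("could not place all planted regions; increase n_probes or shrink regions")
  }

  type <- rep(c("exposure", "disease", "overlap"),
              times = c(cfg$n_exposure_regions, cfg$n_disease_regions,
                        cfg$n_overlap_regions))
  exposure_sign <- ifelse(type %in% c("exposure", "overlap"),
                          sample(c(-1, 1), n_reg, replace = TRUE), 0)
  disease_sign <- ifelse(type == "disease",
                         sample(c(-1, 1), n_reg, replace = TRUE), 0)
  concordant <- rep(NA, n_reg)
  is_ov <- type == "overlap"
  same_sign <- runif(sum(is_ov)) < cfg$concordance_fraction
  disease_sign[is_ov] <- exposure_sign[is_ov] * ifelse(same_sign, 1, -1)
  concordant[is_ov] <- disease_sign[is_ov] == exposure_sign[is_ov]

  has_disease <- type %in% c("disease", "overlap")
  set_discordant <- has_disease & runif(n_reg) < cfg$frac_set_discordant

  regions <- tibble::tibble(
    region_id = sprintf("truth_%03d", seq_len(n_reg)),
    chrom = chrom[starts],
    start = manifest$pos[starts] - 1L,
    end = manifest$pos[starts + lens - 1L],
    probe_ids = lapply(seq_len(n_reg), function(r) {
      manifest$probe_id[starts[r]:(starts[r] + lens[r] - 1L)]
    }),
    n_probes = lens,
    type = type,
    exposure_sign = exposure_sign,
    exposure_effect = exposure_sign * delta_beta_to_m(cfg$delta_beta_exposure),
    disease_sign = disease_sign,
    disease_effect = disease_sign * delta_beta_to_m(cfg$delta_beta_disease),
    concordant = concordant,
    set_discordant = set_discordant
  )
  regions <- dplyr::arrange(regions, .data$chrom, .data$start)

  in_region <- unique(unlist(regions$probe_ids))
  free <- setdiff(manifest$probe_id, in_region)
  ancestry_probes <- sample(free, min(cfg$n_ancestry_probes, length(free)))

  # bimodal-ish baseline typical of array methylation, kept off the rails
  baseline_beta <- 0.1 + 0.8 * stats::rbeta(nrow(manifest), 0.8, 0.8)
  baseline_m <- beta_to_m(baseline_beta)
  # each latent cell type deviates at its own ~30% of probes; composition is
  # the dominant low-rank structure of the matrix, as in whole-blood arrays
  cell_profiles <- vapply(seq_len(cfg$n_cell_types), function(ct) {
    informative <- runif(nrow(manifest)) < 0.3
    baseline_m + informative * rnorm(nrow(manifest), 0, 2)
  }, numeric(nrow(manifest)))
  rownames(cell_profiles) <- manifest$probe_id

  loadings <- setNames(
    sample(c(-1, 1), length(ancestry_probes), replace = TRUE) *
      rnorm(length(ancestry_probes), 1, 0.25),
    ancestry_probes
  )

  structure(list(regions = regions,
                 ancestry_probes = ancestry_probes,
                 ancestry_loadings = loadings,
                 baseline_m = setNames(baseline_m, manifest$probe_id),
                 cell_profiles = cell_profiles),
            class = "mitm_truth")
}

# Dirichlet draw via independent gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = length(alpha))
  sweep(g, 2, colSums(g), "/")
}

# dose columns loosely matched to the cohort's reported folate means/SDs
# (fortified ~ lognormal(mean 204, sd 194); natural ~ lognormal(mean 277,
# sd 154); food = fortified + natural; total = food + supplemental)
draw_doses <- function(n, hispanic) {
  ln_pars <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  pf <- ln_pars(203.5, 193.9)
  pn <- ln_pars(277.4, 154.3)
  mult <- ifelse(hispanic, 1.25, 0.95)
  fortified <- rlnorm(n, pf["meanlog"], pf["sdlog"]) * mult
  natural <- rlnorm(n, pn["meanlog"], pn["sdlog"]) * mult
  supplemental <- sample(c(0, 194, 360, 540), n, replace = TRUE,
                         prob = c(281, 27, 14, 72) / 394)
  food <- fortified + natural
  tibble::tibble(
    dose_total = food + supplemental,
    dose_food = food,
    dose_fortified = fortified,
    dose_natural = natural,
    dose_supplemental = supplemental
  )
}

# standardised driver for the planted exposure effect; the 4-level
# supplemental dose is mapped to its ordinal score first
dose_driver <- function(covariates, source) {
  x <- covariates[[paste0("dose_", source)]]
  if (source == "supplemental") {
    x <- match(x, c(0, 194, 360, 540)) - 1
  }
  as.numeric(scale(x))
}

#' Simulate the birth cohort: beta matrix, covariates, ground truth
#'
#' Each sample's M-value profile is a convex mixture of latent cell-type
#' profiles, plus a batch shift, an ancestry shift at the informative probes,
#' the planted exposure effect (effect x standardised dose at
#' exposure-region probes), and Gaussian noise, then mapped back to the beta
#' scale and clipped into (0, 1).
#'
#' @inheritParams make_truth
#' @param truth Optional pre-computed [make_truth()] result.
#' @return List with `beta` (probes x samples matrix), `covariates` tibble
#'   (case, sex, batch, ethnicity, income and the five dose columns, with
#'   supplemental doses drawn from \{0, 194, 360, 540\}), `truth`, and
#'   `cell_props` / `ancestry` tibbles of the latent per-sample structure.
#' @export
simulate_cohort <- function(cfg, manifest, truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(truth)) truth <- make_truth(cfg, manifest)
  set.seed(cfg$seed + 2L)

  n <- cfg$n_cohort_samples
  ids <- sprintf("cohort_%03d", seq_len(n))
  ethnicity <- sample(c("hispanic", "nhw", "other"), n, replace = TRUE,
                      prob = c(175, 160, 59) / 394)
  covariates <- tibble::tibble(
    sample_id = ids,
    case = as.integer(seq_len(n) %in% sample.int(n, round(n * 189 / 394))),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(219, 175) / 394),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    ethnicity = ethnicity,
    income = round(rlnorm(n, meanlog = log(60000), sdlog = 0.5))
  )
  covariates <- dplyr::bind_cols(covariates,
                                 draw_doses(n, ethnicity == "hispanic"))

  # modest Dirichlet concentration so composition varies strongly between
  # samples (cell types x samples)
  props <- rdirichlet(n, alpha = seq(cfg$n_cell_types, 1) / 2)
  m <- truth$cell_profiles %*% props
  colnames(m) <- ids

  batch_eff <- rnorm(nrow(manifest), 0, 0.15)
  m[, covariates$batch == "b2"] <- m[, covariates$batch == "b2"] + batch_eff

  anc_coord <- (ethnicity == "hispanic") + rnorm(n, 0, 0.15)
  ai <- match(truth$ancestry_probes, manifest$probe_id)
  m[ai, ] <- m[ai, ] + outer(truth$ancestry_loadings, anc_coord)

  z <- dose_driver(covariates, cfg$exposure_source)
  exp_regions <- truth$regions[truth$regions$type %in% c("exposure", "overlap"), ]
  for (r in seq_len(nrow(exp_regions))) {
    pi <- match(exp_regions$probe_ids[[r]], manifest$probe_id)
    m[pi, ] <- m[pi, ] + exp_regions$exposure_effect[r] * rep(z, each = length(pi))
  }

  m <- m + rnorm(length(m), 0, cfg$noise_sd)
  beta <- clip_beta(m_to_beta(m))
  rownames(beta) <- manifest$probe_id

  if (cfg$missing_rate > 0) {
    beta[runif(length(beta)) < cfg$missing_rate] <- NA_real_
  }

  cp <- as.data.frame(t(props))
  names(cp) <- sprintf("cell%d", seq_len(cfg$n_cell_types))

  list(beta = beta,
       covariates = covariates,
       truth = truth,
       cell_props = dplyr::bind_cols(tibble::tibble(sample_id = ids), cp),
       ancestry = tibble::tibble(sample_id = ids, coord = anc_coord))
}

#' Simulate the two blast datasets
#'
#' Set A (450k-like) is restricted to shared probes; Set B (EPIC-like) keeps
#' all probes. Blast samples carry the planted disease effect at
#' disease-region probes with the same sign in both sets, unless the truth
#' table marks a region set-discordant, in which case Set B's sign is
#' flipped. Subtype labels are assigned to blasts only.
#'
#' @inheritParams simulate_cohort
#' @return List with `beta_a`, `covariates_a`, `beta_b`, `covariates_b`, and
#'   `truth`. Covariate tibbles carry `sample_id`, `group` (blast/control),
#'   `subtype` and `batch`.
#' @export
simulate_blast_sets <- function(cfg, manifest, truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(truth)) truth <- make_truth(cfg, manifest)
  set.seed(cfg$seed + 3L)

  dis_regions <- truth$regions[truth$regions$type %in% c("disease", "overlap"), ]
  subtypes <- c("hyperdiploid", "t1221", "other")
  subtype_eff <- lapply(subtypes, function(s) {
    hit <- runif(nrow(manifest)) < 0.05
    hit * rnorm(nrow(manifest), 0, 0.3)
  })
  names(subtype_eff) <- subtypes

  one_set <- function(n_blast, n_control, prefix, flip_discordant) {
    n <- n_blast + n_control
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    group <- rep(c("blast", "control"), c(n_blast, n_control))
    subtype <- ifelse(group == "blast",
                      sample(subtypes, n, replace = TRUE, prob = c(0.35, 0.25, 0.4)),
                      "control")
    covs <- tibble::tibble(sample_id = ids, group = group, subtype = subtype,
                           batch = sample(c("b1", "b2"), n, replace = TRUE))

    m <- matrix(truth$baseline_m, nrow(manifest), n)
    dimnames(m) <- list(manifest$probe_id, ids)
    for (s in subtypes) {
      sel <- subtype == s
      if (any(sel)) m[, sel] <- m[, sel] + subtype_eff[[s]]
    }
    batch_eff <- rnorm(nrow(manifest), 0, 0.15)
    m[, covs$batch == "b2"] <- m[, covs$batch == "b2"] + batch_eff

    is_blast <- group == "blast"
    for (r in seq_len(nrow(dis_regions))) {
      eff <- dis_regions$disease_effect[r]
      if (flip_discordant && dis_regions$set_discordant[r]) eff <- -eff
      pi <- match(dis_regions$probe_ids[[r]], manifest$probe_id)
      m[pi, is_blast] <- m[pi, is_blast] + eff
    }
    m <- m + rnorm(length(m), 0, cfg$noise_sd)
    beta <- clip_beta(m_to_beta(m))
    list(beta = beta, covariates = covs)
  }

  a <- one_set(cfg$n_blast_a, cfg$n_control_a, "setA", flip_discordant = FALSE)
  b <- one_set(cfg$n_blast_b, cfg$n_control_b, "setB", flip_discordant = TRUE)
  shared <- manifest$probe_id[manifest$on_450k]

  list(beta_a = a$beta[shared, , drop = FALSE],
       covariates_a = a$covariates,
       beta_b = b$beta,
       covariates_b = b$covariates,
       truth = truth)
}

#' Write a synthetic scenario to plain-text fixture files
#'
#' Materialises the manifest, beta matrices, covariate tables, truth table
#' and ancestry-probe list as TSV files under `dir`.
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixtures <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- make_manifest(cfg)
  truth <- make_truth(cfg, manifest)
  cohort <- simulate_cohort(cfg, manifest, truth)
  blasts <- simulate_blast_sets(cfg, manifest, truth)

  path <- function(f) file.path(dir, f)
  write_beta_tsv(cohort$beta, path("cohort_beta.tsv"))
  write_beta_tsv(blasts$beta_a, path("blast_a_beta.tsv"))
  write_beta_tsv(blasts$beta_b, path("blast_b_beta.tsv"))
  readr::write_tsv(manifest, path("manifest.tsv"))
  readr::write_tsv(cohort$covariates, path("cohort_covariates.tsv"))
  readr::write_tsv(blasts$covariates_a, path("blast_a_covariates.tsv"))
  readr::write_tsv(blasts$covariates_b, path("blast_b_covariates.tsv"))
  tr <- truth$regions
  tr$probe_ids <- vapply(tr$probe_ids, paste, "", collapse = ",")
  readr::write_tsv(tr, path("truth_regions.tsv"))
  writeLines(truth$ancestry_probes, path("ancestry_probes.txt"))
  invisible(list.files(dir, full.names = TRUE))
}
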