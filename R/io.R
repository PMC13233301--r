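#' Read and write beta matrices as TSV
#'
#' Beta matrices travel as tab-separated files with probe rows and sample
#' columns; the first column (`probe_id`) holds row names.
#'
#' @param path File path.
#' @return `read_beta_tsv()` returns a numeric matrix (probes x samples).
#' @export
read_beta_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_beta_tsv
#' @param beta Numeric matrix with probe rownames and sample colnames.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- tibble::as_tibble(beta, rownames = "probe_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a probe manifest TSV
#'
#' @param path File with columns `probe_id`, `chrom`, `pos`, `on_450k`,
#'   `on_epic`.
#' @return Manifest tibble sorted by (chrom, pos).
#' @export
read_manifest_tsv <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "chrom", "pos", "on_450k", "on_epic")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    abort(paste("manifest is missing columns:", paste(missing, collapse = ", ")))
  }
  dplyr::arrange(man, .data$chrom, .data$pos)
}

#' Write DMRs as a BED6+ file
#'
#' Standard half-open BED coordinates; score column is -log10 of the Sidak
#' p-value, followed by `n_probes`, combined p and Sidak p.
#'
#' @param regions DMR tibble from [call_dmrs()].
#' @param path Output file.
#' @export
write_dmr_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = regions$region_id,
    score = round(-log10(clip_p(regions$sidak_p)), 4),
    strand = ".",
    n_probes = regions$n_probes,
    combined_p = regions$combined_p,
    sidak_p = regions$sidak_p
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
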