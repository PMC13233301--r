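#' Standardise a per-probe p-value track
#'
#' Coerces an EWAS or meta-analysis result into the minimal track the DMR
#' caller needs: `probe_id`, `chrom`, `pos`, `p.value`, sorted by
#' (chrom, pos). Manifest positions are 1-based point coordinates; region
#' intervals produced downstream are 0-based half-open.
#'
#' @param x Tibble containing `probe_id`, `chrom`, `pos` and a `p.value`
#'   column.
#' @return Sorted track tibble.
#' @export
as_pval_track <- function(x) {
  need <- c("probe_id", "chrom", "pos", "p.value")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste("track is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  tr <- tibble::as_tibble(x)[, need]
  if (any(is.na(tr$p.value)) || any(tr$p.value <= 0 | tr$p.value > 1)) {
    abort("track p-values must lie in (0, 1]")
  }
  dplyr::arrange(tr, .data$chrom, .data$pos)
}

check_sorted_track <- function(track) {
  bad <- unlist(tapply(track$pos, track$chrom, function(p) any(diff(p) < 0)))
  if (any(bad)) abort("track must be sorted by (chrom, pos)")
}

#' Estimate the spatial autocorrelation of a p-value track
#'
#' Computes, for each base-pair distance bin, the Pearson correlation of the
#' probit-transformed p-values \eqn{z = \Phi^{-1}(1-p)} over all
#' same-chromosome probe pairs whose distance falls in the bin. This is the
#' correlation model the spatially corrected combination uses. Negative
#' correlations are truncated at 0; bins with fewer than 10 pairs inherit
#' the previous bin's value (the lag-0 correlation, defined as 1, seeds the
#' first bin).
#'
#' @param track Sorted track from [as_pval_track()].
#' @param bin_width Bin width in base pairs (default 50).
#' @param max_dist Largest pair distance considered (default 1000, the DMR
#'   merge distance).
#' @return An `acf_estimate` tibble: `bin_end`, `cor`, `n_pairs`,
#'   `inherited`.
#' @export
estimate_acf <- function(track, bin_width = 50, max_dist = 1000) {
  check_sorted_track(track)
  n_bins <- ceiling(max_dist / bin_width)
  z <- qnorm(clip_p(track$p.value), lower.tail = FALSE)

  dists <- vector("list", 64)
  zi <- vector("list", 64)
  zj <- vector("list", 64)
  cnt <- 0L
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    zc <- z[sel]
    n <- length(pos)
    if (n < 2) next
    # bounded window: for each probe collect partners within max_dist
    hi <- 1L
    for (i in seq_len(n - 1L)) {
      while (hi < n && pos[hi + 1L] - pos[i] <= max_dist) hi <- hi + 1L
      if (hi > i) {
        cnt <- cnt + 1L
        j <- (i + 1L):hi
        dists[[cnt]] <- pos[j] - pos[i]
        zi[[cnt]] <- rep(zc[i], length(j))
        zj[[cnt]] <- zc[j]
      }
    }
  }
  d <- unlist(dists)
  x <- unlist(zi)
  y <- unlist(zj)
  bin <- if (length(d)) pmax(1L, as.integer(ceiling(d / bin_width))) else integer()

  cors <- rep(NA_real_, n_bins)
  n_pairs <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    n_pairs[b] <- length(idx)
    if (length(idx) >= 10) {
      if (sd(x[idx]) == 0 || sd(y[idx]) == 0) {
        cors[b] <- 1  # degenerate duplicated values: total dependence
      } else {
        cors[b] <- stats::cor(x[idx], y[idx])
      }
    }
  }
  inherited <- is.na(cors)
  prev <- 1  # lag-0 correlation
  for (b in seq_len(n_bins)) {
    if (is.na(cors[b])) cors[b] <- prev else prev <- cors[b]
  }
  if (any(inherited)) {
    inform(sprintf("estimate_acf: %d of %d bins had < 10 pairs and inherit the previous bin",
                   sum(inherited), n_bins))
  }
  structure(
    tibble::tibble(bin_end = seq_len(n_bins) * bin_width,
                   cor = pmax(cors, 0),
                   n_pairs = n_pairs,
                   inherited = inherited),
    class = c("acf_estimate", "tbl_df", "tbl", "data.frame"),
    bin_width = bin_width, max_dist = max_dist
  )
}

# correlation for arbitrary distances; beyond max_dist the last bin's value
# is held (used when scoring regions wider than the estimation range)
acf_lookup <- function(acf, dist) {
  bw <- attr(acf, "bin_width")
  idx <- pmax(1L, as.integer(ceiling(dist / bw)))
  idx <- pmin(idx, nrow(acf))
  acf$cor[idx]
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Combines p-values through \eqn{z_i = \Phi^{-1}(1 - p_i)} with
#' \eqn{Z = \sum z_i / \sqrt{k + 2\sum_{i<j} \sigma_{ij}}}, returning
#' \eqn{1 - \Phi(Z)}. With an identity correlation matrix this reduces to
#' the classical Stouffer combination; under total dependence it returns the
#' shared p-value unchanged. A non-positive denominator falls back to the
#' independence value `k`.
#'
#' @param pvals P-values, all from the same one-sided convention.
#' @param corr Correlation matrix matching `pvals` (unit diagonal). Defaults
#'   to identity.
#' @return Combined p-value.
#' @examples
#' stouffer_liptak(c(0.05, 0.05), diag(2))
#' @export
stouffer_liptak <- function(pvals, corr = diag(length(pvals))) {
  k <- length(pvals)
  if (k == 0) abort("empty p-value list")
  corr <- as.matrix(corr)
  if (!all(dim(corr) == k)) abort("`corr` must be k x k")
  z <- qnorm(clip_p(pvals), lower.tail = FALSE)
  denom <- k + 2 * sum(corr[upper.tri(corr)])
  if (denom <= 0) denom <- k
  Z <- sum(z) / sqrt(denom)
  max(pnorm(Z, lower.tail = FALSE), .Machine$double.xmin)
}

#' Neighbourhood-smooth a p-value track
#'
#' Replaces each probe's p-value by the Stouffer-Liptak combination of all
#' probes within `window` base pairs on the same chromosome (itself
#' included), with pairwise correlations read from the distance-binned ACF.
#' Isolated probes keep their raw p-value.
#'
#' @param track Sorted track from [as_pval_track()].
#' @param acf An [estimate_acf()] result.
#' @param window Half-width of the smoothing window in bp (default 1000).
#' @return The track with an added `p_adj` column.
#' @export
smooth_pvalues <- function(track, acf, window = 1000) {
  check_sorted_track(track)
  p_adj <- numeric(nrow(track))
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    pos <- track$pos[sel]
    p <- track$p.value[sel]
    n <- length(pos)
    lo <- 1L
    hi <- 1L
    for (i in seq_len(n)) {
      while (pos[i] - pos[lo] > window) lo <- lo + 1L
      if (hi < i) hi <- i
      while (hi < n && pos[hi + 1L] - pos[i] <= window) hi <- hi + 1L
      idx <- lo:hi
      if (length(idx) == 1L) {
        p_adj[sel[i]] <- p[i]
      } else {
        d <- abs(outer(pos[idx], pos[idx], "-"))
        corr <- matrix(acf_lookup(acf, d), length(idx))
        diag(corr) <- 1
        p_adj[sel[i]] <- stouffer_liptak(p[idx], corr)
      }
    }
  }
  track$p_adj <- p_adj
  track
}

#' Seed-and-merge candidate region finding
#'
#' Probes whose adjusted p-value falls below `seed_p` are seeds; successive
#' qualifying probes on the same chromosome are merged into one region while
#' the distance between them is at most `max_gap`; regions with fewer than
#' `min_probes` members are discarded. Intervals are 0-based half-open,
#' spanning the first to last member probe.
#'
#' @param track Track with a `p_adj` column from [smooth_pvalues()].
#' @param seed_p Seed (and extension) threshold, default 0.05.
#' @param max_gap Maximum inter-probe distance in bp, default 1000.
#' @param min_probes Minimum member probes per region, default 2.
#' @return Tibble of unscored regions (possibly empty): `chrom`, `start`,
#'   `end`, `probe_ids` list-column, `n_probes`.
#' @export
find_candidate_regions <- function(track, seed_p = 0.05, max_gap = 1000,
                                   min_probes = 2) {
  if (!"p_adj" %in% names(track)) abort("track lacks `p_adj`; run smooth_pvalues() first")
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch & track$p_adj < seed_p)
    if (length(sel) == 0) next
    pos <- track$pos[sel]
    grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (g in unique(grp)) {
      members <- sel[grp == g]
      if (length(members) < min_probes) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch,
        start = min(track$pos[members]) - 1L,
        end = max(track$pos[members]),
        probe_ids = list(track$probe_id[members]),
        n_probes = length(members)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), probe_ids = list(),
                          n_probes = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Score a region by combining its members' raw p-values
#'
#' Stouffer-Liptak combination over the member probes' raw p-values with
#' pairwise correlations taken from the ACF (held at the last bin's value
#' beyond its estimation range).
#'
#' @param region One-row region tibble from [find_candidate_regions()].
#' @param track Raw p-value track.
#' @param acf An [estimate_acf()] result.
#' @return Combined p-value for the region.
#' @export
score_region <- function(region, track, acf) {
  idx <- match(region$probe_ids[[1]], track$probe_id)
  if (any(is.na(idx))) abort("region members missing from track")
  pos <- track$pos[idx]
  d <- abs(outer(pos, pos, "-"))
  corr <- matrix(acf_lookup(acf, d), length(idx))
  diag(corr) <- 1
  stouffer_liptak(track$p.value[idx], corr)
}

#' Sidak multiple-testing correction for a region p-value
#'
#' Corrects a region's combined p for the number of effective tests
#' \eqn{m = \max(1, \lfloor \mathrm{total\_covered} / \mathrm{region\_len}
#' \rfloor)} via \eqn{1 - (1-p)^m}, where `total_covered` is the genomic
#' span covered by the tested track.
#'
#' @param p Combined region p-value in \eqn{[0, 1]}.
#' @param region_len Region width in bp (>= 1).
#' @param total_covered Total tested span in bp.
#' @return Corrected p-value in \eqn{[0, 1]}.
#' @examples
#' sidak_correct(0.01, 500, 50000)  # 1 - 0.99^100
#' @export
sidak_correct <- function(p, region_len, total_covered) {
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (any(region_len < 1) || any(total_covered < region_len)) {
    abort("need region_len >= 1 and total_covered >= region_len")
  }
  m <- pmax(1, floor(total_covered / region_len))
  -expm1(m * log1p(-p))
}

#' Call differentially methylated regions from a p-value track
#'
#' The full spatially corrected pipeline: estimate the distance-binned
#' autocorrelation of the track, smooth each probe's p-value over its
#' `max_gap` neighbourhood, find seed-and-merge candidate regions, score each
#' region on the raw p-values, and keep regions whose Sidak-corrected p falls
#' below `sidak_alpha`.
#'
#' @param x Track input accepted by [as_pval_track()].
#' @param seed_p Seed/extension threshold on smoothed p (default 0.05).
#' @param max_gap Merge distance and smoothing window in bp (default 1000).
#' @param min_probes Minimum member probes (default 2).
#' @param bin_width ACF bin width in bp (default 50).
#' @param sidak_alpha Significance threshold on the corrected p (default
#'   0.05).
#' @return Tibble of significant regions sorted by (chrom, start):
#'   `region_id`, `chrom`, `start`, `end`, `n_probes`, `probe_ids`,
#'   `combined_p`, `sidak_p`. The number of pre-filter candidates is kept in
#'   attribute `n_candidates`.
#' @export
call_dmrs <- function(x, seed_p = 0.05, max_gap = 1000, min_probes = 2,
                      bin_width = 50, sidak_alpha = 0.05) {
  track <- as_pval_track(x)
  acf <- estimate_acf(track, bin_width = bin_width, max_dist = max_gap)
  smoothed <- smooth_pvalues(track, acf, window = max_gap)
  cand <- find_candidate_regions(smoothed, seed_p = seed_p, max_gap = max_gap,
                                 min_probes = min_probes)
  total_covered <- sum(tapply(track$pos, track$chrom,
                              function(p) max(p) - min(p) + 1))
  if (nrow(cand) > 0) {
    cand$combined_p <- vapply(seq_len(nrow(cand)), function(i) {
      score_region(cand[i, ], track, acf)
    }, numeric(1))
    cand$sidak_p <- sidak_correct(cand$combined_p,
                                  region_len = cand$end - cand$start,
                                  total_covered = total_covered)
  } else {
    cand$combined_p <- numeric()
    cand$sidak_p <- numeric()
  }
  n_candidates <- nrow(cand)
  res <- cand[cand$sidak_p < sidak_alpha, , drop = FALSE]
  res <- dplyr::arrange(res, .data$chrom, .data$start)
  res <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("dmr_%04d", seq_len(nrow(res)))), res)
  attr(res, "n_candidates") <- n_candidates
  structure(res, class = c("dmr_regions", class(res)))
}
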