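#' Pairwise differences between two consensus haplotypes
#'
#' Counts the sites called (non-missing) in both samples and, among those,
#' the sites where the called bases differ. These two numbers drive the
#' TMRCA estimator: two lineages accumulate substitutions independently
#' since their split, so the expected number of differences over `n`
#' jointly called sites is `2 * mu * n * T`.
#'
#' With `exclude_damage_pairs = TRUE`, mismatches of C/T or G/A form are
#' treated as non-comparable (dropped from both `d` and `n_overlap`) — a
#' sensitivity mode that removes the base-pair classes deamination can
#' fake.
#'
#' @param a,b [consensus_sequence()] results.
#' @param exclude_damage_pairs Drop transition-type mismatches (default
#'   `FALSE`).
#' @return List with `n_overlap`, `d`, `relative_divergence`
#'   (`d / (2 * n_overlap)`, `NA` when `n_overlap = 0`), `usable`.
#' @export
pairwise_differences <- function(a, b, exclude_damage_pairs = FALSE) {
  stopifnot(inherits(a, "consensus_seq"), inherits(b, "consensus_seq"))
  i <- match(a$positions, b$positions)
  hit <- !is.na(i)
  ba <- a$base[hit]
  bb <- b$base[i[hit]]
  mism <- ba != bb
  if (exclude_damage_pairs) {
    transition <- (ba == "C" & bb == "T") | (ba == "T" & bb == "C") |
      (ba == "G" & bb == "A") | (ba == "A" & bb == "G")
    drop <- mism & transition
    ba <- ba[!drop]; bb <- bb[!drop]
    mism <- mism[!drop]
  }
  n <- length(ba)
  d <- sum(mism)
  list(n_overlap = n, d = d,
       relative_divergence = if (n > 0) d / (2 * n) else NA_real_,
       usable = n > 0)
}

#' Calibrate the relative rate against an outgroup anchor
#'
#' Relative divergence `d / (2n)` is proportional to TMRCA with an unknown
#' constant (the effective substitution rate of the filtered consensus
#' sites). Rather than assuming a rate, the constant is fitted so that the
#' mean calibrated TMRCA over anchor pairs — each pairing an outgroup
#' sample (e.g. haplogroup A0, the deepest split among extant Y lineages)
#' with a non-anchor sample — equals the anchor's split time, 161,300
#' years by default.
#'
#' @param pairs List of [pairwise_differences()] results for the
#'   anchor-vs-rest pairs (or a data.frame with `n_overlap` and `d`
#'   columns).
#' @param anchor_years Anchor split time in years.
#' @param anchor_label Optional anchor group label carried in reports.
#' @return Object of class `calibration_anchor`: `c_years` (years per unit
#'   relative divergence), `anchor_years`, `anchor_label`, `n_pairs`.
#' @export
calibrate <- function(pairs, anchor_years = 161300, anchor_label = NULL) {
  if (anchor_years <= 0) stop_nry("anchor_years must be positive")
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(k)
      list(n_overlap = pairs$n_overlap[k], d = pairs$d[k]))
  }
  rel <- vapply(pairs, function(p) {
    if (p$n_overlap > 0) p$d / (2 * p$n_overlap) else NA_real_
  }, 0)
  rel <- rel[!is.na(rel)]
  if (!length(rel)) stop_nry("no usable anchor pairs (all have n_overlap = 0)")
  if (mean(rel) == 0) stop_nry("anchor pairs show zero divergence; cannot calibrate")
  structure(list(c_years = anchor_years / mean(rel),
                 anchor_years = anchor_years,
                 anchor_label = anchor_label, n_pairs = length(rel)),
            class = "calibration_anchor")
}

#' @export
print.calibration_anchor <- function(x, ...) {
  cat(sprintf(
    "<calibration_anchor>%s %s years at divergence 1 (anchor %.1f kya, %d pair(s))\n",
    if (is.null(x$anchor_label)) "" else paste0(" [", x$anchor_label, "]"),
    format(round(x$c_years), big.mark = ","), x$anchor_years / 1000,
    x$n_pairs))
  invisible(x)
}

#' Calibrated TMRCA with exact Poisson confidence interval
#'
#' Maps a pair's relative divergence through the calibration:
#' `TMRCA = c * d / (2 * n_overlap)`. The 95% CI treats the difference
#' count `d` as Poisson and transforms the exact (Garwood) interval
#' endpoints through the same linear map, so pairs with fewer overlapping
#' sites naturally get wider intervals; `d = 0` yields a zero lower bound
#' and a positive upper bound.
#'
#' @param pair A [pairwise_differences()] result with `n_overlap > 0`.
#' @param calibration A [calibrate()] result.
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `pairwise_tmrca`: `n_overlap`, `d`,
#'   `relative_divergence`, `tmrca_years`, `ci_low`, `ci_high`,
#'   `ci_level`.
#' @export
estimate_tmrca <- function(pair, calibration, ci_level = 0.95) {
  stopifnot(inherits(calibration, "calibration_anchor"))
  if (pair$n_overlap <= 0) stop_nry("pair has no jointly called sites")
  if (ci_level <= 0 || ci_level >= 1) stop_nry("ci_level must be in (0, 1)")
  alpha <- 1 - ci_level
  d <- pair$d
  d_lo <- if (d == 0) 0 else qgamma(alpha / 2, d)
  d_hi <- qgamma(1 - alpha / 2, d + 1)
  scale <- calibration$c_years / (2 * pair$n_overlap)
  structure(list(n_overlap = pair$n_overlap, d = d,
                 relative_divergence = d / (2 * pair$n_overlap),
                 tmrca_years = scale * d,
                 ci_low = scale * d_lo, ci_high = scale * d_hi,
                 ci_level = ci_level),
            class = "pairwise_tmrca")
}

#' @export
print.pairwise_tmrca <- function(x, ...) {
  cat(sprintf(
    "<pairwise_tmrca> %.1f kya [%.1f, %.1f] (%d diffs / %s sites)\n",
    x$tmrca_years / 1000, x$ci_low / 1000, x$ci_high / 1000, x$d,
    format(x$n_overlap, big.mark = ",")))
  invisible(x)
}

#' All calibrated pairwise TMRCAs between two sample sets
#'
#' Convenience pipeline: for every cross pair of consensus haplotypes,
#' computes overlap and differences, applies the calibration, and attaches
#' sample metadata. Consensuses tagged `mode = "snp-panel"` are refused
#' unless `allow_snp_panel = TRUE`, because SNP panels target known
#' segregating sites and so bias the per-site divergence upward; shotgun
#' and NRY-capture data are unbiased in this respect.
#'
#' @param consensuses Named list of [consensus_sequence()] results.
#' @param calibration A [calibrate()] result.
#' @param sites Optional data.frame `sample`, `site` giving the sampling
#'   site of each individual (for same-site exclusion downstream).
#' @param allow_snp_panel Override the SNP-panel refusal (default FALSE).
#' @param ci_level Confidence level.
#' @param exclude_damage_pairs Passed to [pairwise_differences()].
#' @return Data.frame, one row per unordered pair: ids, `n_overlap`, `d`,
#'   `tmrca_years`, `ci_low`, `ci_high`, `same_site`.
#' @export
tmrca_pairs <- function(consensuses, calibration, sites = NULL,
                        allow_snp_panel = FALSE, ci_level = 0.95,
                        exclude_damage_pairs = FALSE) {
  ids <- names(consensuses) %||%
    vapply(consensuses, function(x) x$sample %||% NA_character_, "")
  modes <- vapply(consensuses, function(x) x$mode %||% NA_character_, "")
  if (!allow_snp_panel && any(modes == "snp-panel", na.rm = TRUE)) {
    stop_nry("SNP-panel consensuses bias TMRCA (panels target known ",
             "segregating sites); drop them or set allow_snp_panel = TRUE. ",
             "Offending: ",
             paste(ids[which(modes == "snp-panel")], collapse = ", "))
  }
  site_of <- function(id) {
    if (is.null(sites)) NA_character_
    else sites$site[match(id, sites$sample)]
  }
  out <- list()
  n <- length(consensuses)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pd <- pairwise_differences(consensuses[[i]], consensuses[[j]],
                                 exclude_damage_pairs = exclude_damage_pairs)
      if (!pd$usable) next
      est <- estimate_tmrca(pd, calibration, ci_level = ci_level)
      out[[length(out) + 1]] <- data.frame(
        sample_a = ids[i], sample_b = ids[j],
        n_overlap = pd$n_overlap, d = pd$d,
        tmrca_years = est$tmrca_years,
        ci_low = est$ci_low, ci_high = est$ci_high,
        same_site = !is.na(site_of(ids[i])) && !is.na(site_of(ids[j])) &&
          site_of(ids[i]) == site_of(ids[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop_nry("no usable pairs (no joint coverage)")
  do.call(rbind, out)
}

#' Mean TMRCA between two clades
#'
#' Summarizes the pairwise TMRCAs for all cross-group pairs, excluding
#' pairs of individuals from the same sampling site (close kin and shared
#' local history depress pairwise divergence), and reports the mean
#' estimate alongside the per-pair confidence intervals for plotting.
#'
#' @param pairs A [tmrca_pairs()] data.frame.
#' @param groups Data.frame `sample`, `group` assigning each sample to a
#'   clade.
#' @param group_a,group_b The two clade labels to compare.
#' @param exclude_same_site Drop same-site pairs (default TRUE).
#' @return List with `mean_tmrca_years`, `n_pairs`, `pairs` (retained
#'   rows).
#' @export
clade_summary <- function(pairs, groups, group_a, group_b,
                          exclude_same_site = TRUE) {
  ga <- groups$sample[groups$group == group_a]
  gb <- groups$sample[groups$group == group_b]
  cross <- (pairs$sample_a %in% ga & pairs$sample_b %in% gb) |
    (pairs$sample_a %in% gb & pairs$sample_b %in% ga)
  kept <- pairs[cross, , drop = FALSE]
  if (exclude_same_site) kept <- kept[!kept$same_site, , drop = FALSE]
  if (!nrow(kept)) {
    stop_nry("no retained ", group_a, "-", group_b, " pairs",
             if (exclude_same_site) " after same-site exclusion" else "")
  }
  list(mean_tmrca_years = mean(kept$tmrca_years), n_pairs = nrow(kept),
       pairs = kept)
}
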