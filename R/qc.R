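#' Heterozygosity-based contamination screen
#'
#' The NRY is haploid, so an uncontaminated male sample should show a
#' single base at every site; the proportion of covered sites exhibiting
#' more than one distinct base is therefore a direct contamination signal.
#' Samples are passed when heterozygosity falls below `threshold`
#' (default 0.1%).
#'
#' By default a site counts as heterozygous as soon as two distinct bases
#' are each seen in at least one read (the literal criterion); setting
#' `min_minor_reads = 2` requires the minor base to be supported by two
#' reads, damping single-read deamination artefacts.
#'
#' @param pileup An [nry_pileup].
#' @param min_depth Minimum depth for a site to be assessed (default 1:
#'   every covered site).
#' @param threshold Pass threshold on the heterozygosity proportion.
#' @param min_minor_reads Reads required for the minor base (default 1).
#' @return Object of class `het_result`: `sample`, `sites_assessed`,
#'   `het_sites`, `heterozygosity` (NA when no site is assessable),
#'   `pass`, `threshold`, `reason`.
#' @export
heterozygosity <- function(pileup, min_depth = 1, threshold = 0.001,
                           min_minor_reads = 1) {
  stopifnot(inherits(pileup, "nry_pileup"))
  if (min_depth < 1) stop_nry("min_depth must be >= 1")
  depth <- rowSums(pileup$counts)
  assess <- depth >= min_depth
  n <- sum(assess)
  if (n == 0) {
    return(structure(list(sample = pileup$sample, sites_assessed = 0L,
                          het_sites = 0L, heterozygosity = NA_real_,
                          pass = FALSE, threshold = threshold,
                          reason = "no sites at required depth"),
                     class = "het_result"))
  }
  cnt <- pileup$counts[assess, , drop = FALSE]
  het <- rowSums(cnt >= min_minor_reads) >= 2 & rowSums(cnt >= 1) >= 2
  structure(list(sample = pileup$sample, sites_assessed = n,
                 het_sites = sum(het), heterozygosity = sum(het) / n,
                 pass = sum(het) / n < threshold, threshold = threshold,
                 reason = NA_character_),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  if (is.na(x$heterozygosity)) {
    cat("<het_result> not assessable:", x$reason, "\n")
  } else {
    cat(sprintf("<het_result>%s %d/%d het sites (%.4f%%) -> %s at %.2f%%\n",
                if (is.null(x$sample)) "" else paste0(" ", x$sample, ":"),
                x$het_sites, x$sites_assessed, 100 * x$heterozygosity,
                if (x$pass) "PASS" else "FAIL", 100 * x$threshold))
  }
  invisible(x)
}
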