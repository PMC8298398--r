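#' Haplogroup hierarchy
#'
#' The ISOGG-style haplogroup tree as a child -> parent label map. Used to
#' walk root-to-terminal paths during haplogroup assignment and to gather
#' the SNPs defining a clade and its near-descendant branches.
#'
#' @param parents Named character vector: `names()` are child haplogroup
#'   labels, values their parents. Exactly one label must appear only as a
#'   parent: the root.
#' @return An object of class `hg_tree` with elements `parent` (named
#'   vector), `root` and `children` (list).
#' @examples
#' tr <- hg_tree(c(H1 = "H", H2 = "H", H2a = "H2"))
#' tr$root  # "H"
#' @export
hg_tree <- function(parents) {
  if (is.null(names(parents)) || any(!nzchar(names(parents)))) {
    stop_nry("parents must be a fully named character vector")
  }
  child <- names(parents)
  if (anyDuplicated(child)) stop_nry("duplicate child labels")
  root <- setdiff(unique(parents), child)
  if (length(root) != 1) {
    stop_nry("tree must have exactly one root; found: ",
             paste(root, collapse = ", "))
  }
  # cycle check: every child must reach the root
  for (x in child) {
    seen <- character()
    cur <- x
    while (cur != root) {
      if (cur %in% seen) stop_nry("cycle involving label ", cur)
      seen <- c(seen, cur)
      cur <- unname(parents[cur])
      if (is.na(cur)) stop_nry("label ", seen[length(seen)], " has no parent")
    }
  }
  structure(list(parent = parents, root = root,
                 children = split(child, parents[child])),
            class = "hg_tree")
}

#' @export
print.hg_tree <- function(x, ...) {
  cat(sprintf("<hg_tree> root %s, %d labels\n", x$root,
              length(x$parent) + 1))
  invisible(x)
}

#' Haplogroup tree of a simulated lineage tree
#'
#' @param tree A [simulate_tree()] result.
#' @return An [hg_tree] over the simulated haplogroup labels.
#' @export
as_haplogroup_tree <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  nonroot <- which(!is.na(tree$parent))
  hg_tree(setNames(tree$label[tree$parent[nonroot]], tree$label[nonroot]))
}

#' SNPs defining a clade and its near-downstream branches
#'
#' Collects the catalogue SNPs whose haplogroup label is `root_label` or a
#' descendant at most `depth` branches below it. With `depth = 3` this is
#' the "within three branches downstream of each terminal SNP" criterion
#' used when scoring how well an assay covers the diagnostic SNPs of a
#' haplogroup.
#'
#' @param tree An [hg_tree].
#' @param snps A [snp_table()].
#' @param root_label Haplogroup at which to root the collection.
#' @param depth Number of downstream branches to include (>= 0).
#' @return The subset of `snps` on the selected labels.
#' @export
haplogroup_snp_set <- function(tree, snps, root_label, depth = 3) {
  stopifnot(inherits(tree, "hg_tree"))
  if (depth < 0) stop_nry("depth must be >= 0")
  known <- c(tree$root, names(tree$parent))
  if (!root_label %in% known) stop_nry("unknown haplogroup label: ", root_label)
  labels <- root_label
  frontier <- root_label
  d <- 0
  while (d < depth && length(frontier)) {
    frontier <- unlist(tree$children[frontier], use.names = FALSE)
    labels <- c(labels, frontier)
    d <- d + 1
  }
  snps[snps$haplogroup %in% labels, , drop = FALSE]
}

#' Fraction of catalogue SNPs inside target regions
#'
#' @param snps A non-empty [snp_table()].
#' @param regions A [target_regions] object.
#' @return Proportion in `[0, 1]` of SNPs whose position falls in the
#'   regions.
#' @export
coverage_fraction <- function(snps, regions) {
  if (!nrow(snps)) stop_nry("coverage fraction undefined for an empty catalogue")
  mean(in_regions(snps$position, regions))
}

#' Normalize a covered-site count per sequencing effort
#'
#' Counts of NRY sites or catalogue SNPs covered are comparable across
#' libraries only after scaling by sequencing effort; the convention here
#' is sites covered per five million quality-filtered mapped reads.
#'
#' @param count Sites or SNPs covered at least once.
#' @param mapped_reads Quality-filtered mapped reads for the library (> 0).
#' @param unit Reads per normalization unit (default 5e6).
#' @return `count * unit / mapped_reads`.
#' @export
normalize_per_unit <- function(count, mapped_reads, unit = 5e6) {
  if (any(mapped_reads <= 0)) stop_nry("mapped_reads must be positive")
  count * unit / mapped_reads
}

#' Shotgun sequencing effort equivalent to one capture unit
#'
#' A fold-enrichment of `fold` per normalization unit means that matching
#' the sites covered by one unit of capture sequencing requires
#' `fold * unit` shotgun reads (e.g. a 15.2x enrichment per 5 million
#' reads implies ~76 million shotgun reads).
#'
#' @param fold Mean fold increase of capture over shotgun.
#' @param unit Reads per normalization unit.
#' @return Number of shotgun reads.
#' @export
equivalent_shotgun_reads <- function(fold, unit = 5e6) {
  if (any(fold <= 0)) stop_nry("fold must be positive")
  fold * unit
}

#' Library sequencing statistics table
#'
#' @param library Library ids.
#' @param mode Sequencing mode per library: `"shotgun"`, `"snp-panel"` or
#'   `"nry-capture"`.
#' @param mapped_reads Quality-filtered mapped read counts.
#' @param sites_covered NRY sites covered at least once.
#' @param isogg_snps_covered Catalogue SNPs covered at least once.
#' @param endogenous_pct Shotgun endogenous-DNA percentage in `[0, 100]`.
#' @return A data.frame of class `library_stats`.
#' @export
library_stats <- function(library, mode, mapped_reads, sites_covered,
                          isogg_snps_covered, endogenous_pct) {
  mode <- match.arg(mode, c("shotgun", "snp-panel", "nry-capture"),
                    several.ok = TRUE)
  df <- data.frame(library = as.character(library), mode = mode,
                   mapped_reads = mapped_reads,
                   sites_covered = sites_covered,
                   isogg_snps_covered = isogg_snps_covered,
                   endogenous_pct = endogenous_pct,
                   stringsAsFactors = FALSE)
  if (any(df$mapped_reads < 0) || any(df$sites_covered < 0) ||
      any(df$isogg_snps_covered < 0)) {
    stop_nry("counts must be >= 0")
  }
  if (any(df$endogenous_pct < 0 | df$endogenous_pct > 100)) {
    stop_nry("endogenous_pct must lie in [0, 100]")
  }
  class(df) <- c("library_stats", "data.frame")
  df
}

#' Filter libraries for empirical assay comparison
#'
#' Empirical mode comparisons use only samples with shotgun endogenous DNA
#' above a floor (default 0.1%), to avoid libraries whose coverage is
#' dominated by noise.
#'
#' @param stats A [library_stats()] table.
#' @param min_endogenous_pct Minimum shotgun endogenous percentage.
#' @return The filtered table.
#' @export
filter_library_stats <- function(stats, min_endogenous_pct = 0.1) {
  stats[stats$endogenous_pct > min_endogenous_pct, , drop = FALSE]
}

#' Paired fold-enrichment test between sequencing modes
#'
#' For libraries sequenced under two modes, computes the per-library fold
#' increase in normalized covered sites (mode A over mode B) and tests for
#' enrichment with a one-sample t-test of the log-folds against zero (on
#' the log scale folds are symmetric about 0 under no enrichment).
#'
#' @param a,b Positive normalized counts under the two modes, paired by
#'   library (>= 3 pairs).
#' @param ids Optional library ids for error messages.
#' @return List with `folds`, `mean_fold`, `p_value`, `n`.
#' @export
enrichment_tests <- function(a, b, ids = NULL) {
  if (length(a) != length(b)) stop_nry("a and b must be paired")
  if (length(a) < 3) stop_nry("need at least 3 library pairs")
  bad <- which(b <= 0 | a <= 0)
  if (length(bad)) {
    ids <- ids %||% as.character(bad)
    stop_nry("non-positive normalized counts for: ",
             paste(ids[bad], collapse = ", "))
  }
  folds <- a / b
  lf <- log(folds)
  p <- if (stats::sd(lf) == 0) {
    if (all(lf == 0)) 1 else 0   # degenerate: all folds identical
  } else {
    t.test(lf, mu = 0)$p.value
  }
  list(folds = folds, mean_fold = mean(folds), p_value = p, n = length(a))
}

#' Correlation of endogenous DNA percentage with an enrichment response
#'
#' Checks whether an assay's benefit depends on sample preservation: the
#' product-moment correlation (or rank correlation) between per-library
#' endogenous-DNA percentage and a response such as fold increase or SNPs
#' covered, with a two-sided p-value.
#'
#' @param endogenous_pct Endogenous percentages (>= 4 libraries).
#' @param response Response values, same length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `estimate`, `p_value`, `n`, `method`.
#' @export
endogenous_correlation <- function(endogenous_pct, response,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(endogenous_pct) != length(response)) {
    stop_nry("inputs must be paired")
  }
  if (length(endogenous_pct) < 4) stop_nry("need at least 4 libraries")
  if (stats::sd(endogenous_pct) == 0 || stats::sd(response) == 0) {
    stop_nry("zero variance: correlation undefined")
  }
  ct <- cor.test(endogenous_pct, response, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(response), method = method)
}

#' Expected waiting time between substitutions on one lineage
#'
#' With substitution rate `mu` (substitutions/site/year) over `L` sites, a
#' single lineage accumulates substitutions as a Poisson process of rate
#' `mu * L` per year, so the mean waiting time between substitutions is
#' `1 / (mu * L)`. For the ~10.4 Mb mappable NRY at NRY rates this is on
#' the order of a century; for the 16.6 kb mitogenome at mtDNA rates, a
#' few millennia — the arithmetic behind the NRY's resolution advantage.
#'
#' @param mu Substitution rate per site per year (> 0).
#' @param L Number of sites (> 0).
#' @return Expected years between substitutions.
#' @examples
#' expected_waiting_years(7.77e-10, 10445000)  # ~123 years
#' @export
expected_waiting_years <- function(mu, L) {
  if (any(mu <= 0) || any(L <= 0)) stop_nry("mu and L must be positive")
  1 / (mu * L)
}
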