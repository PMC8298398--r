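#' Three-state genotype matrix for diagnostic-SNP search
#'
#' Samples by positions, each cell `"ancestral"`, `"derived"` or `NA`
#' (missing), polarized against the reference genome (hs37d5 chrY
#' coordinates in this workflow): the reference base is the ancestral
#' state, the observed alternate the derived state. Each sample belongs to
#' the candidate clade (`"ingroup"`) or not (`"outgroup"`).
#'
#' @param geno Character matrix (samples x positions) of
#'   `"ancestral"`/`"derived"`/`NA`; rownames = sample ids, colnames =
#'   1-based positions.
#' @param groups Character vector (`"ingroup"`/`"outgroup"`) per sample.
#' @param ref,alt Reference and alternate base per position.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, groups, ref, alt) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c("ancestral", "derived", NA))) {
    stop_nry("cells must be 'ancestral', 'derived' or NA")
  }
  if (length(groups) != nrow(geno)) stop_nry("one group label per sample")
  if (!all(groups %in% c("ingroup", "outgroup"))) {
    stop_nry("groups must be 'ingroup' or 'outgroup'")
  }
  if (length(ref) != ncol(geno) || length(alt) != ncol(geno)) {
    stop_nry("one ref and alt allele per position")
  }
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% BASES) || !all(alt %in% BASES) || any(ref == alt)) {
    stop_nry("ref/alt must be distinct ACGT bases at every position")
  }
  if (is.null(colnames(geno))) stop_nry("geno needs position colnames")
  structure(list(geno = geno, groups = groups,
                 positions = as.numeric(colnames(geno)),
                 ref = ref, alt = alt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sample(s) (%d ingroup) x %d position(s)\n",
              nrow(x$geno), sum(x$groups == "ingroup"), ncol(x$geno)))
  invisible(x)
}

.is_damage_pair <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "G" & alt == "A")
}

#' Find diagnostic SNPs for a candidate clade
#'
#' A site is diagnostic for the ingroup when (1) no ingroup sample is
#' ancestral there, (2) more than one ingroup sample is covered, (3) no
#' outgroup sample is derived, and (4) more than one outgroup sample is
#' covered. Because post-mortem deamination mimics C>T (and complementary
#' G>A) substitutions, sites whose ref-to-alt pair has that form are kept
#' only when they match a previously known catalogue SNP; all results are
#' annotated known/novel by exact position + allele-pair match.
#'
#' @param matrix A [genotype_matrix()] with >= 2 samples in each group.
#' @param known Optional [snp_table()] of previously discovered SNPs.
#' @return Data.frame of class `diagnostic_snps`: `position`, `ref`,
#'   `alt`, `ingroup_derived`, `ingroup_covered`, `outgroup_covered`,
#'   `damage_pair`, `known`, `annotation` (catalogue haplogroup or
#'   `"novel"`).
#' @export
find_diagnostic_sites <- function(matrix, known = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  ing <- matrix$geno[matrix$groups == "ingroup", , drop = FALSE]
  out <- matrix$geno[matrix$groups == "outgroup", , drop = FALSE]
  if (nrow(ing) < 2 || nrow(out) < 2) {
    stop_nry("need >= 2 ingroup and >= 2 outgroup samples ",
             "(coverage rules are unsatisfiable otherwise)")
  }
  ing_anc <- colSums(ing == "ancestral", na.rm = TRUE)
  ing_cov <- colSums(!is.na(ing))
  ing_der <- colSums(ing == "derived", na.rm = TRUE)
  out_der <- colSums(out == "derived", na.rm = TRUE)
  out_cov <- colSums(!is.na(out))
  pass <- ing_anc == 0 & ing_cov > 1 & out_der == 0 & out_cov > 1
  dmg <- .is_damage_pair(matrix$ref, matrix$alt)
  res <- data.frame(position = matrix$positions,
                    ref = matrix$ref, alt = matrix$alt,
                    ingroup_derived = ing_der, ingroup_covered = ing_cov,
                    outgroup_covered = out_cov, damage_pair = dmg,
                    row.names = NULL, stringsAsFactors = FALSE)[pass, ,
                                                               drop = FALSE]
  res <- .match_known(res, known)
  res <- res[!res$damage_pair | res$known, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("diagnostic_snps", "data.frame")
  res
}

# exact position + allele-pair match against one catalogue
.match_known <- function(res, known) {
  res$known <- logical(nrow(res))
  res$annotation <- rep("novel", nrow(res))
  if (!is.null(known) && nrow(res)) {
    key <- paste(known$position, known$ancestral, known$derived)
    i <- match(paste(res$position, res$ref, res$alt), key)
    res$known <- !is.na(i)
    res$annotation[res$known] <- known$haplogroup[i[res$known]]
  }
  res
}

#' Annotate diagnostic SNPs against known-SNP catalogues
#'
#' Matches each candidate against one or more catalogues (e.g. ISOGG and
#' YFull snapshots) by exact position and allele pair, and summarizes how
#' many are already known inside the candidate clade, known but attached
#' to another clade, or novel. A SNP at a catalogued position with a
#' different allele pair stays novel.
#'
#' @param snps A [find_diagnostic_sites()] result.
#' @param catalogues A [snp_table()] or list of them.
#' @param clade_prefix Haplogroup prefix defining "in-clade" (e.g. `"H2"`);
#'   when `NULL` every known hit counts as in-clade.
#' @return List with `snps` (annotated; first catalogue hit wins) and
#'   `summary` (counts: `known_in_clade`, `known_out_of_clade`, `novel`).
#' @export
annotate_known <- function(snps, catalogues, clade_prefix = NULL) {
  if (inherits(catalogues, "snp_table")) catalogues <- list(catalogues)
  snps$known <- logical(nrow(snps))
  snps$annotation <- rep("novel", nrow(snps))
  for (cat in catalogues) {
    pending <- !snps$known
    if (!any(pending)) break
    upd <- .match_known(snps[pending, , drop = FALSE], cat)
    snps$known[pending] <- upd$known
    snps$annotation[pending] <- upd$annotation
  }
  in_clade <- if (is.null(clade_prefix)) snps$known
              else snps$known & startsWith(snps$annotation, clade_prefix)
  list(snps = snps,
       summary = c(known_in_clade = sum(in_clade),
                   known_out_of_clade = sum(snps$known & !in_clade),
                   novel = sum(!snps$known)))
}

#' Per-position derived/missing report for a group
#'
#' Reports, for each requested position, how many samples of a group are
#' derived out of the group size, in the "x/N derived, rest missing"
#' convention: by diagnostic rule (1), any group member that is not
#' derived at a reported site is uncovered there, never ancestral (an
#' ancestral observation is flagged).
#'
#' @param matrix A [genotype_matrix()].
#' @param positions Positions to report (must be in the matrix).
#' @param group `"ingroup"` (default) or `"outgroup"`.
#' @return Data.frame with `position`, `derived` (x), `group_size` (N),
#'   `missing`, `ancestral` (should be 0 for diagnostic sites) and
#'   `label` (`"x/N"`).
#' @export
missingness_report <- function(matrix, positions, group = "ingroup") {
  stopifnot(inherits(matrix, "genotype_matrix"))
  i <- match(positions, matrix$positions)
  if (any(is.na(i))) {
    stop_nry("position(s) not in matrix: ",
             paste(positions[is.na(i)], collapse = ", "))
  }
  g <- matrix$geno[matrix$groups == group, i, drop = FALSE]
  n <- nrow(g)
  der <- colSums(g == "derived", na.rm = TRUE)
  anc <- colSums(g == "ancestral", na.rm = TRUE)
  data.frame(position = positions, derived = der, group_size = n,
             missing = n - der - anc, ancestral = anc,
             label = sprintf("%d/%d", der, n),
             row.names = NULL, stringsAsFactors = FALSE)
}
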