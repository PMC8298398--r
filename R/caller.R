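#' Tally derived/ancestral reads at catalogue SNPs
#'
#' For every catalogue SNP covered by at least one read, records the number
#' of reads supporting the derived and ancestral alleles, reads matching
#' neither, and the difference (derived minus ancestral) — the signed
#' statistic used to trace a sample's path through the haplogroup tree. A
#' positive difference is evidence for the derived allele. Calls whose
#' ancestral-to-derived pair is C>T or G>A are flagged as deamination
#' candidates, and when the pileup carries read-end offsets the smallest
#' offset among derived-supporting reads is recorded (derived calls seen
#' only near read termini are the classic damage artefact).
#'
#' @param pileup An [nry_pileup].
#' @param snps A [snp_table()].
#' @return Object of class `sample_calls`: `sample`, `calls` (one row per
#'   covered SNP), `covered_fraction` (covered catalogue SNPs / catalogue
#'   size) and `n_catalogue`.
#' @export
tally_snp_calls <- function(pileup, snps) {
  stopifnot(inherits(pileup, "nry_pileup"))
  i <- match(snps$position, pileup$positions)
  hit <- which(!is.na(i))
  rows <- i[hit]
  derived_count <- pileup$counts[cbind(rows, match(snps$derived[hit], BASES))]
  ancestral_count <- pileup$counts[cbind(rows, match(snps$ancestral[hit], BASES))]
  depth <- rowSums(pileup$counts)[rows]
  calls <- data.frame(
    name = snps$name[hit],
    haplogroup = snps$haplogroup[hit],
    position = snps$position[hit],
    ancestral = snps$ancestral[hit],
    derived = snps$derived[hit],
    derived_count = derived_count,
    ancestral_count = ancestral_count,
    other_count = depth - derived_count - ancestral_count,
    difference = derived_count - ancestral_count,
    damage_candidate = (snps$ancestral[hit] == "C" & snps$derived[hit] == "T") |
      (snps$ancestral[hit] == "G" & snps$derived[hit] == "A"),
    min_end_offset = rep(NA_real_, length(hit)),
    stringsAsFactors = FALSE)
  if (!is.null(pileup$offsets) && nrow(calls)) {
    off <- pileup$offsets
    key <- paste(off$position, off$base)
    mins <- tapply(off$offset, key, min)
    calls$min_end_offset <-
      unname(mins[paste(calls$position, calls$derived)])
  }
  structure(list(sample = pileup$sample, calls = calls,
                 covered_fraction = nrow(calls) / max(nrow(snps), 1),
                 n_catalogue = nrow(snps)),
            class = "sample_calls")
}

#' @export
print.sample_calls <- function(x, ...) {
  cat(sprintf("<sample_calls>%s %d/%d catalogue SNPs covered (%.1f%%)\n",
              if (is.null(x$sample)) "" else paste0(" ", x$sample, ":"),
              nrow(x$calls), x$n_catalogue, 100 * x$covered_fraction))
  invisible(x)
}

#' Assign a Y haplogroup from SNP tallies
#'
#' Aggregates the signed differences of all SNPs on each haplogroup branch
#' and walks the tree from the root, descending only into branches whose
#' aggregate support reaches `min_support`; the call is the deepest node so
#' reached. Branches carrying both positive- and negative-difference SNPs
#' are listed in the conflict report (a "transitional" signal worth manual
#' review — on clean data it indicates catalogue or reference problems, on
#' ancient data often deamination), but do not by themselves block a call.
#' A sample with no supported branch at all is returned unassigned.
#'
#' @param table A [tally_snp_calls()] result.
#' @param tree An [hg_tree]. Haplogroup labels present in the table but
#'   absent from the tree are ignored with a warning.
#' @param min_support Minimum aggregate difference for a branch to count as
#'   supported (default 1 read).
#' @return List of class `hg_assignment`: `haplogroup` (label or NA),
#'   `path` (root-to-call labels), `support` (per-branch aggregate table),
#'   `conflicts` (branches with mixed signs), `assigned`, `reason`.
#' @export
call_haplogroup <- function(table, tree, min_support = 1) {
  stopifnot(inherits(table, "sample_calls"), inherits(tree, "hg_tree"))
  calls <- table$calls
  if (!nrow(calls)) {
    return(structure(list(haplogroup = NA_character_, path = character(),
                          support = NULL, conflicts = NULL, assigned = FALSE,
                          reason = "no catalogue SNPs covered"),
                     class = "hg_assignment"))
  }
  known <- c(tree$root, names(tree$parent))
  unknown <- setdiff(unique(calls$haplogroup), known)
  if (length(unknown)) {
    warning(length(unknown), " haplogroup label(s) not in tree ignored: ",
            paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    calls <- calls[calls$haplogroup %in% known, , drop = FALSE]
  }
  agg <- stats::aggregate(difference ~ haplogroup, data = calls, FUN = sum)
  support <- setNames(agg$difference, agg$haplogroup)
  pos <- tapply(calls$difference > 0, calls$haplogroup, any)
  neg <- tapply(calls$difference < 0, calls$haplogroup, any)
  conflicts <- names(pos)[pos & neg]
  supported <- function(lab) !is.na(support[lab]) && support[lab] >= min_support
  # depth-first walk from the root through supported branches; deepest node
  # wins, ties broken by cumulative support then label
  best <- list(label = NA_character_, depth = -1, cum = -Inf,
               path = character())
  walk <- function(lab, depth, cum, path) {
    if (depth > best$depth || (depth == best$depth && cum > best$cum)) {
      best <<- list(label = lab, depth = depth, cum = cum, path = path)
    }
    for (ch in sort(tree$children[[lab]] %||% character())) {
      if (supported(ch)) {
        walk(ch, depth + 1, cum + support[ch], c(path, ch))
      }
    }
  }
  root_sup <- if (supported(tree$root)) unname(support[tree$root]) else 0
  walk(tree$root, 0, root_sup, tree$root)
  assigned <- best$depth > 0 || supported(tree$root)
  structure(list(
    haplogroup = if (assigned) best$label else NA_character_,
    path = if (assigned) best$path else character(),
    support = data.frame(haplogroup = names(support),
                         support = unname(support),
                         conflict = names(support) %in% conflicts,
                         row.names = NULL, stringsAsFactors = FALSE),
    conflicts = conflicts, assigned = assigned,
    reason = if (assigned) NA_character_ else "no positively supported branch"),
    class = "hg_assignment")
}

#' @export
print.hg_assignment <- function(x, ...) {
  if (x$assigned) {
    cat(sprintf("<hg_assignment> %s (path: %s)%s\n", x$haplogroup,
                paste(x$path, collapse = " > "),
                if (length(x$conflicts))
                  sprintf("; %d conflicted branch(es)", length(x$conflicts))
                else ""))
  } else {
    cat("<hg_assignment> unassigned:", x$reason, "\n")
  }
  invisible(x)
}

#' Export the two per-sample SNP report files
#'
#' Writes the pair of CSV reports used for manual haplogroup review: one
#' restricted to SNPs with positive differences (the easy read of the
#' root-to-terminal path) and one of all covered SNPs regardless of sign
#' (for checking that basal branches are merely uncovered rather than
#' contradicted, and for spotting mixed-sign branches). Both are sorted by
#' haplogroup then position and carry the allele pair, counts, difference,
#' damage flag and minimum derived read-end offset.
#'
#' @param table A [tally_snp_calls()] result.
#' @param positive_path,all_path Output CSV paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
export_reports <- function(table, positive_path, all_path) {
  stopifnot(inherits(table, "sample_calls"))
  calls <- table$calls
  calls <- calls[order(calls$haplogroup, calls$position), , drop = FALSE]
  write.csv(calls[calls$difference > 0, , drop = FALSE], positive_path,
            row.names = FALSE)
  write.csv(calls, all_path, row.names = FALSE)
  invisible(c(positive = positive_path, all = all_path))
}

#' Flag derived calls that may be deamination artefacts
#'
#' Returns the calls a human would manually inspect: deamination-candidate
#' allele pairs (C>T / G>A) supported by fewer than `min_reads` derived
#' reads, all of them close to a read end (minimum derived-read offset
#' below `min_offset`). Calls without offset information are treated as
#' near-end (conservative).
#'
#' @param table A [tally_snp_calls()] result.
#' @param min_reads Derived calls with at least this many reads are trusted
#'   (default 2: a single supporting read is suspect).
#' @param min_offset Trust calls whose derived reads start at least this
#'   many bp from the read end (default 5).
#' @return The flagged subset of the calls data.frame.
#' @export
flag_damage_suspects <- function(table, min_reads = 2, min_offset = 5) {
  stopifnot(inherits(table, "sample_calls"))
  if (min_reads < 1 || min_offset < 0) {
    stop_nry("min_reads must be >= 1 and min_offset >= 0")
  }
  calls <- table$calls
  offs <- ifelse(is.na(calls$min_end_offset), 0, calls$min_end_offset)
  calls[calls$damage_candidate & calls$derived_count > 0 &
          calls$derived_count < min_reads & offs < min_offset, ,
        drop = FALSE]
}
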