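#' Consensus base call at one site
#'
#' The consensus filter for low-coverage haploid data: a site needs at
#' least two reads, and the majority base is called only when the minor
#' allele fraction `1 - max(counts)/depth` is strictly below
#' `max_minor_frac` (default 10%; a 9:1 site is masked). Ties for the
#' majority are masked.
#'
#' @param counts Named integer vector of base counts over A,C,G,T.
#' @param min_depth Minimum reads (default 2).
#' @param max_minor_frac Strict upper bound on the minor-allele fraction.
#' @return A single base or `NA_character_` (missing).
#' @examples
#' consensus_call(c(A = 19, C = 0, G = 1, T = 0))  # "A"
#' consensus_call(c(A = 9, C = 0, G = 1, T = 0))   # NA: minor fraction 0.10
#' @export
consensus_call <- function(counts, min_depth = 2, max_minor_frac = 0.10) {
  counts <- counts[BASES]
  counts[is.na(counts)] <- 0
  depth <- sum(counts)
  if (depth < min_depth) return(NA_character_)
  mx <- max(counts)
  if (sum(counts == mx) > 1) return(NA_character_)
  # integer comparison avoids the 9:1 boundary slipping through in floating
  # point: minor fraction < f  <=>  depth - mx < f * depth
  if (depth - mx >= max_minor_frac * depth - 1e-9) return(NA_character_)
  BASES[which.max(counts)]
}

#' Consensus haplotype of a pileup
#'
#' Vectorized application of [consensus_call()] over every covered site.
#'
#' @param pileup An [nry_pileup].
#' @param min_depth,max_minor_frac As in [consensus_call()].
#' @param mode Optional data-source tag (`"shotgun"`, `"nry-capture"` or
#'   `"snp-panel"`) carried to TMRCA estimation, which refuses SNP-panel
#'   consensuses by default because panels target known segregating sites.
#' @return Object of class `consensus_seq`: `sample`, `positions` (called
#'   sites only) and `base`.
#' @export
consensus_sequence <- function(pileup, min_depth = 2, max_minor_frac = 0.10,
                               mode = NA_character_) {
  stopifnot(inherits(pileup, "nry_pileup"))
  cnt <- pileup$counts
  depth <- rowSums(cnt)
  mx <- do.call(pmax, as.data.frame(cnt))
  ntop <- rowSums(cnt == mx)
  ok <- depth >= min_depth & ntop == 1 &
    (depth - mx) < max_minor_frac * depth - 1e-9
  base <- BASES[max.col(cnt, ties.method = "first")]
  structure(list(sample = pileup$sample,
                 positions = pileup$positions[ok],
                 base = base[ok], mode = mode),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq>%s %d called site(s)%s\n",
              if (is.null(x$sample)) "" else paste0(" ", x$sample, ":"),
              length(x$positions),
              if (is.na(x$mode)) "" else paste0(" [", x$mode, "]")))
  invisible(x)
}

#' Build the segregating-site alignment matrix
#'
#' Assembles per-sample consensus haplotypes into a rectangular matrix over
#' segregating sites (positions where at least two distinct bases are
#' called across samples). Two filters are applied iteratively to a fixed
#' point, because each can invalidate the other: samples must cover at
#' least `min_seg_sites` segregating sites, and sites must be called in at
#' least two samples.
#'
#' @param consensuses List of [consensus_sequence()] results (>= 2), with
#'   unique sample ids.
#' @param min_seg_sites Minimum covered segregating sites per retained
#'   sample (the production default in this workflow is 1100; scale down
#'   for small simulations).
#' @return Object of class `alignment_matrix`: `samples`, `positions`,
#'   `mat` (character matrix, `NA` = missing), `seg_covered` (per-sample
#'   counts), `modes`.
#' @export
build_alignment <- function(consensuses, min_seg_sites = 1100) {
  if (length(consensuses) < 2) stop_nry("need at least 2 consensus sequences")
  ids <- vapply(consensuses, function(x)
    x$sample %||% NA_character_, "")
  if (any(is.na(ids)) || anyDuplicated(ids)) {
    stop_nry("consensus sequences must carry unique sample ids")
  }
  positions <- sort(unique(unlist(lapply(consensuses, `[[`, "positions"))))
  mat <- matrix(NA_character_, length(consensuses), length(positions),
                dimnames = list(ids, positions))
  for (k in seq_along(consensuses)) {
    mat[k, match(consensuses[[k]]$positions, positions)] <-
      consensuses[[k]]$base
  }
  repeat {
    covered <- colSums(!is.na(mat))
    distinct <- apply(mat, 2, function(col) length(unique(col[!is.na(col)])))
    seg <- distinct >= 2 & covered >= 2
    if (!any(seg)) {
      stop_nry("no segregating sites remain after the >=2-sample site filter")
    }
    mat2 <- mat[, seg, drop = FALSE]
    keep <- rowSums(!is.na(mat2)) >= min_seg_sites
    if (sum(keep) < 2) {
      stop_nry("fewer than 2 samples meet the ", min_seg_sites,
               " segregating-site minimum")
    }
    if (all(keep) && all(seg)) break
    mat <- mat[keep, seg, drop = FALSE]
  }
  modes <- vapply(consensuses, function(x) x$mode %||% NA_character_, "")
  keep_ids <- rownames(mat)
  structure(list(samples = keep_ids,
                 positions = as.numeric(colnames(mat)),
                 mat = mat,
                 seg_covered = rowSums(!is.na(mat)),
                 modes = setNames(modes, ids)[keep_ids]),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %d sample(s) x %d segregating site(s)\n",
              length(x$samples), length(x$positions)))
  invisible(x)
}

#' Write an alignment as FASTA plus a site-position sidecar
#'
#' One FASTA record per sample, columns ordered by position, missing cells
#' written as `N`; the mapping from alignment column to chrY position goes
#' to a tab-separated sidecar so external tree software can be fed the
#' FASTA alone.
#'
#' @param matrix An [build_alignment()] result.
#' @param path Output FASTA path.
#' @param sites_path Sidecar path (default `<path>.sites.tsv`).
#' @return `path`, invisibly. Warns if a sample is entirely missing.
#' @export
write_alignment <- function(matrix, path,
                            sites_path = paste0(path, ".sites.tsv")) {
  stopifnot(inherits(matrix, "alignment_matrix"))
  if (anyDuplicated(matrix$samples)) stop_nry("duplicate sample names")
  m <- matrix$mat
  m[is.na(m)] <- "N"
  all_n <- rowSums(m != "N") == 0
  if (any(all_n)) {
    warning("all-missing sample(s): ",
            paste(matrix$samples[all_n], collapse = ", "), call. = FALSE)
  }
  dna <- ape::as.DNAbin(tolower(m))
  ape::write.FASTA(dna, path)
  write.table(data.frame(column = seq_along(matrix$positions),
                         position = matrix$positions),
              sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an alignment written by [write_alignment()]
#'
#' @param path FASTA path.
#' @param sites_path Sidecar path.
#' @return An `alignment_matrix`.
#' @export
read_alignment <- function(path, sites_path = paste0(path, ".sites.tsv")) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  sites <- read.table(sites_path, header = TRUE, sep = "\t")
  m[m == "N"] <- NA_character_
  colnames(m) <- sites$position
  structure(list(samples = rownames(m), positions = sites$position,
                 mat = m, seg_covered = rowSums(!is.na(m)),
                 modes = setNames(rep(NA_character_, nrow(m)), rownames(m))),
            class = "alignment_matrix")
}

#' Neighbour-joining tree from pairwise mismatch distances
#'
#' Internal sanity surrogate for external maximum-likelihood tree building:
#' computes the pairwise mismatch proportion over jointly called sites for
#' every sample pair and runs neighbour joining on the resulting distance
#' matrix. Deterministic given the matrix.
#'
#' @param matrix An [build_alignment()] result with >= 3 samples.
#' @return Newick text (single-element character vector); the `phylo`
#'   object is attached as attribute `"phylo"`.
#' @export
pairwise_distance_tree <- function(matrix) {
  stopifnot(inherits(matrix, "alignment_matrix"))
  n <- length(matrix$samples)
  if (n < 3) stop_nry("need at least 3 samples for a tree")
  d <- base::matrix(0, n, n, dimnames = list(matrix$samples, matrix$samples))
  bad <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      joint <- !is.na(matrix$mat[i, ]) & !is.na(matrix$mat[j, ])
      if (!any(joint)) {
        bad <- c(bad, paste(matrix$samples[i], matrix$samples[j], sep = "-"))
        next
      }
      d[i, j] <- d[j, i] <-
        mean(matrix$mat[i, joint] != matrix$mat[j, joint])
    }
  }
  if (length(bad)) {
    stop_nry("pair(s) with no jointly covered sites: ",
             paste(bad, collapse = ", "))
  }
  phy <- ape::nj(stats::as.dist(d))
  newick <- ape::write.tree(phy)
  attr(newick, "phylo") <- phy
  newick
}
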