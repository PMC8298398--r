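#' Assay target regions on chrY
#'
#' A `target_regions` object stores the genomic intervals targeted by a
#' capture assay (or any other site set) in 0-based half-open coordinates,
#' the convention used by BED files. Overlapping or abutting input intervals
#' are merged on construction, so the stored intervals are disjoint and
#' sorted; `total_length()` is then the exact number of distinct targeted
#' positions.
#'
#' @param start,end Integer vectors of interval bounds, 0-based half-open
#'   (`start` inclusive, `end` exclusive), as in BED.
#' @param chrom Chromosome name (single string; the NRY workflows use `"Y"`).
#' @param label Optional assay name carried through reports.
#' @return An object of class `target_regions` with elements `chrom`,
#'   `intervals` (data.frame of merged `start`/`end`) and `label`.
#' @examples
#' tr <- target_regions(c(0L, 5L), c(10L, 20L))
#' total_length(tr)  # 20: the union of [0,10) and [5,20)
#' @export
target_regions <- function(start = integer(), end = integer(), chrom = "Y",
                           label = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop_nry("start and end must have equal length")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0)) {
    stop_nry("interval bounds must be non-negative numbers")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop_nry(sprintf("interval %d has end <= start (%g <= %g)",
                     bad, end[bad], start[bad]))
  }
  if (length(start)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
    ints <- data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  } else {
    ints <- data.frame(start = numeric(), end = numeric())
  }
  structure(list(chrom = chrom, intervals = ints, label = label),
            class = "target_regions")
}

#' @export
print.target_regions <- function(x, ...) {
  cat(sprintf("<target_regions> %s: %d interval(s), %s bp%s\n",
              x$chrom, nrow(x$intervals),
              format(total_length(x), big.mark = ","),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

#' Total targeted length of a region set
#'
#' @param regions A [target_regions] object.
#' @return Number of distinct positions covered by the (merged) intervals.
#' @export
total_length <- function(regions) {
  stopifnot(inherits(regions, "target_regions"))
  sum(regions$intervals$end - regions$intervals$start)
}

#' Read a 3-column BED file of target regions
#'
#' Parses whitespace-delimited `chrom start end` lines, validates them, and
#' returns the merged interval union. BED coordinates are 0-based half-open
#' and are kept that way; conversion to the 1-based SNP convention happens
#' only inside [in_regions()].
#'
#' @param path Path to a BED file. Blank lines and lines starting with
#'   `track`, `browser` or `#` are ignored.
#' @param label Optional assay label attached to the result.
#' @return A [target_regions] object.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop_nry("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^(track|browser)\\b|^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(target_regions(chrom = "Y", label = label))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n <- lengths(fields)
  if (any(n < 3)) {
    stop_nry(sprintf("malformed BED line %d: fewer than 3 fields",
                     lineno[which(n < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start != floor(start) |
    end != floor(end)
  if (any(bad)) {
    stop_nry(sprintf("malformed BED line %d: non-integer coordinates",
                     lineno[which(bad)[1]]))
  }
  if (any(end <= start)) {
    stop_nry(sprintf("BED line %d: end <= start", lineno[which(end <= start)[1]]))
  }
  if (length(unique(chrom)) > 1) {
    stop_nry("BED file spans multiple chromosomes; expected a single one")
  }
  target_regions(start, end, chrom = chrom[1], label = label)
}

#' Write target regions as BED
#'
#' @param regions A [target_regions] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "target_regions"))
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$intervals$start, scientific = FALSE, trim = TRUE),
                   end = format(regions$intervals$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Membership of 1-based positions in target regions
#'
#' SNP catalogues use 1-based positions while the intervals are 0-based
#' half-open; a position `p` lies in `[start, end)` iff `start <= p - 1 < end`.
#' This is the single place where the two conventions meet.
#'
#' @param positions Integer vector of 1-based positions.
#' @param regions A [target_regions] object.
#' @return Logical vector, one element per position.
#' @export
in_regions <- function(positions, regions) {
  stopifnot(inherits(regions, "target_regions"))
  if (!length(positions)) return(logical())
  if (!nrow(regions$intervals)) return(rep(FALSE, length(positions)))
  ir <- IRanges::IRanges(start = regions$intervals$start + 1,
                         end = regions$intervals$end)
  IRanges::countOverlaps(IRanges::IRanges(positions, positions), ir) > 0
}

#' Expand SNP positions into probe-sized windows
#'
#' Each SNP at 1-based position `p` contributes the interval covering the SNP
#' base plus `window_bp / 2` flanking bases on either side (121 positions for
#' the default 120-bp window), emulating the extra sequence recovered around
#' a targeted variant by tiled capture probes. Windows are clipped at
#' coordinate 0 and merged.
#'
#' @param snps A SNP table (see [read_snp_table()]) or any data.frame with a
#'   1-based `position` column.
#' @param window_bp Total added window width in bp; must be even and >= 0.
#'   Default 120 (60 bp on either side).
#' @param chrom,label Passed to [target_regions()].
#' @return A [target_regions] object.
#' @export
expand_windows <- function(snps, window_bp = 120, chrom = "Y", label = NULL) {
  if (window_bp < 0 || window_bp %% 2 != 0) {
    stop_nry("window_bp must be an even, non-negative number of bases")
  }
  p <- as.numeric(snps$position)
  if (!length(p)) return(target_regions(chrom = chrom, label = label))
  half <- window_bp / 2
  start <- pmax(0, p - 1 - half)
  end <- p + half
  target_regions(start, end, chrom = chrom, label = label)
}
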