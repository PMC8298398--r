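#' Per-position base pileups
#'
#' A compact per-sample pileup over chrY: for each covered 1-based position,
#' the number of reads supporting each base (strand-folded: upper and lower
#' case merged, since haplogroup SNP tables are strandless), and optionally,
#' for every read, the distance of the pileup position from the nearer end
#' of that read. End offsets support damage review: deamination concentrates
#' at read termini, so derived calls supported only near read ends deserve
#' less trust.
#'
#' @param positions Sorted 1-based positions with depth >= 1.
#' @param counts Integer matrix `length(positions) x 4`, columns `A,C,G,T`.
#' @param offsets Optional data.frame with columns `position`, `base`,
#'   `offset` — one row per read (so rows per position/base equal that
#'   base's count when offsets are tracked).
#' @param chrom Chromosome name.
#' @param sample Optional sample id.
#' @return An object of class `nry_pileup`.
#' @export
nry_pileup <- function(positions, counts, offsets = NULL, chrom = "Y",
                       sample = NULL) {
  positions <- as.numeric(positions)
  counts <- as.matrix(counts)
  colnames(counts) <- BASES
  if (nrow(counts) != length(positions)) {
    stop_nry("counts must have one row per position")
  }
  if (any(counts < 0)) stop_nry("negative base counts")
  depth <- rowSums(counts)
  keep <- depth > 0
  positions <- positions[keep]
  counts <- counts[keep, , drop = FALSE]
  o <- order(positions)
  structure(list(positions = positions[o],
                 counts = counts[o, , drop = FALSE],
                 offsets = offsets, chrom = chrom, sample = sample),
            class = "nry_pileup")
}

#' @export
print.nry_pileup <- function(x, ...) {
  cat(sprintf("<nry_pileup> %s%s: %d covered site(s), mean depth %.2f%s\n",
              x$chrom,
              if (is.null(x$sample)) "" else paste0(" [", x$sample, "]"),
              length(x$positions),
              if (length(x$positions)) mean(rowSums(x$counts)) else 0,
              if (is.null(x$offsets)) "" else ", with read-end offsets"))
  invisible(x)
}

#' Per-site depth of a pileup
#' @param pileup An `nry_pileup`.
#' @return Named numeric vector of depths (names = positions).
#' @export
pileup_depth <- function(pileup) {
  setNames(rowSums(pileup$counts), pileup$positions)
}

#' Base counts at one position
#' @param pileup An `nry_pileup`.
#' @param position A 1-based position.
#' @return Named integer vector over A,C,G,T (zeros if uncovered).
#' @export
pileup_site <- function(pileup, position) {
  i <- match(position, pileup$positions)
  if (is.na(i)) return(setNames(rep(0L, 4), BASES))
  setNames(pileup$counts[i, ], BASES)
}

# mpileup base-string symbols that represent a read but not a usable base
.is_read_symbol <- function(ch) ch %in% c(".", ",", "*", "n", "N") | toupper(ch) %in% BASES

#' Read an mpileup-style text pileup
#'
#' Parses the samtools-mpileup text dialect restricted to one chromosome:
#' tab-separated `chrom pos ref depth bases [quals] [offsets]`. In the base
#' string, `.` and `,` denote the reference base, letters denote mismatches
#' (case = strand, folded on input), `*` a deletion and `N` an uncalled
#' base; `^x` (read start + mapping quality), `$` (read end) and `+n`/`-n`
#' indel sequences are consumed and ignored. Deletions and Ns are excluded
#' from base counts. An optional final column carries comma-separated
#' per-read distances from the nearer read end, aligned with the read
#' symbols of the base string.
#'
#' @param path Path to the pileup text file.
#' @param sample Optional sample id attached to the result.
#' @return An [nry_pileup].
#' @export
read_pileup <- function(path, sample = NULL) {
  if (!file.exists(path)) stop_nry("pileup file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$|^#", lines)]
  n <- length(lines)
  pos <- numeric(n)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  off_list <- vector("list", n)
  chrom <- "Y"
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      stop_nry(sprintf("pileup line %d: expected >= 5 tab-separated fields", i))
    }
    chrom <- f[1]
    pos[i] <- as.numeric(f[2])
    ref <- toupper(f[3])
    depth <- as.numeric(f[4])
    syms <- .parse_base_string(f[5], ref, i)
    if (length(syms) != depth) {
      stop_nry(sprintf(
        "pileup line %d: depth %d inconsistent with %d read symbols",
        i, depth, length(syms)))
    }
    usable <- syms %in% BASES
    tb <- table(factor(syms[usable], levels = BASES))
    counts[i, ] <- as.integer(tb)
    if (length(f) >= 7 && nzchar(f[7])) {
      offs <- as.numeric(strsplit(f[7], ",", fixed = TRUE)[[1]])
      if (length(offs) != depth) {
        stop_nry(sprintf("pileup line %d: %d offsets for depth %d",
                         i, length(offs), depth))
      }
      if (any(usable)) {
        off_list[[i]] <- data.frame(position = pos[i], base = syms[usable],
                                    offset = offs[usable])
      }
    }
  }
  offsets <- if (any(!vapply(off_list, is.null, TRUE))) {
    do.call(rbind, off_list[!vapply(off_list, is.null, TRUE)])
  }
  nry_pileup(pos, counts, offsets = offsets, chrom = chrom, sample = sample)
}

# Expand one mpileup base string into one uppercase symbol per read:
# A/C/G/T, "*" (deletion) or "N". `.`/`,` become the reference base when it
# is ACGT, otherwise "N".
.parse_base_string <- function(s, ref, lineno) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # skip mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch %in% c(".", ",")) {
      out <- c(out, if (ref %in% BASES) ref else "N")
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% c(BASES, "N", "*")) {
        out <- c(out, up)
      } else {
        stop_nry(sprintf("pileup line %d: unexpected base symbol '%s'",
                         lineno, ch))
      }
      i <- i + 1L
    }
  }
  out
}

#' Write a pileup in the mpileup-style text dialect
#'
#' Bases are written as explicit letters (reference is emitted as `N`), so a
#' written file read back with [read_pileup()] reproduces the counts (and
#' offsets, when present) exactly.
#'
#' @param pileup An [nry_pileup].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  stopifnot(inherits(pileup, "nry_pileup"))
  n <- length(pileup$positions)
  has_off <- !is.null(pileup$offsets)
  lines <- character(n)
  for (i in seq_len(n)) {
    cnt <- pileup$counts[i, ]
    bases <- rep(BASES, cnt)
    offs <- ""
    if (has_off) {
      od <- pileup$offsets[pileup$offsets$position == pileup$positions[i], ,
                           drop = FALSE]
      # order offsets to match the emitted base order
      od <- od[order(match(od$base, BASES)), , drop = FALSE]
      if (nrow(od) == length(bases)) {
        offs <- paste(od$offset, collapse = ",")
      }
    }
    depth <- sum(cnt)
    qual <- paste(rep("~", depth), collapse = "")
    lines[i] <- paste(pileup$chrom,
                      format(pileup$positions[i], scientific = FALSE),
                      "N", depth, paste(bases, collapse = ""), qual, offs,
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
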