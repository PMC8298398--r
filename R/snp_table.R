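#' Construct a haplogroup-SNP catalogue
#'
#' An ISOGG-style catalogue: one row per haplogroup-defining SNP with its
#' 1-based chrY position and ancestral/derived alleles. Rows are validated
#' (alleles in A/C/G/T, ancestral != derived, position >= 1).
#'
#' @param name SNP identifiers.
#' @param haplogroup Haplogroup labels (e.g. `"H2"`); trailing `~`
#'   (provisional) is kept verbatim.
#' @param position 1-based positions.
#' @param ancestral,derived Single-base alleles.
#' @return A data.frame of class `snp_table`.
#' @export
snp_table <- function(name, haplogroup, position, ancestral, derived) {
  df <- data.frame(name = as.character(name),
                   haplogroup = as.character(haplogroup),
                   position = as.numeric(position),
                   ancestral = toupper(as.character(ancestral)),
                   derived = toupper(as.character(derived)),
                   stringsAsFactors = FALSE)
  ok <- df$ancestral %in% BASES & df$derived %in% BASES &
    df$ancestral != df$derived & !is.na(df$position) & df$position >= 1
  if (any(!ok)) {
    stop_nry(sprintf("%d invalid SNP record(s); first at row %d",
                     sum(!ok), which(!ok)[1]))
  }
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Read a delimited haplogroup-SNP table
#'
#' Reads an ISOGG-style SNP list. Because published snapshots vary in their
#' column layout, the mapping from file columns to fields is configurable:
#' `columns` names the (1-based) indices of the required fields. Alleles may
#' be given either as two separate columns (`ancestral`, `derived`) or as a
#' single `mutation` column of the form `"C->T"`.
#'
#' Rows with non-ACGT alleles (e.g. indel or multistate entries), equal
#' alleles or non-numeric positions are skipped, not errors; the number of
#' skipped rows is recorded in `attr(, "skipped")`.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @param columns Named integer vector mapping fields to column indices.
#'   Required names: `name`, `haplogroup`, `position`, then either
#'   `ancestral` and `derived` or `mutation`.
#' @param header Does the file have a header line?
#' @return A `snp_table` with attribute `skipped` (count of dropped rows).
#' @export
read_snp_table <- function(path, sep = ",",
                           columns = c(name = 1, haplogroup = 2, position = 3,
                                       ancestral = 4, derived = 5),
                           header = TRUE) {
  if (!file.exists(path)) stop_nry("SNP table not found: ", path)
  need <- c("name", "haplogroup", "position")
  if (!all(need %in% names(columns))) {
    stop_nry("columns must map at least: ", paste(need, collapse = ", "))
  }
  two_col <- all(c("ancestral", "derived") %in% names(columns))
  if (!two_col && !("mutation" %in% names(columns))) {
    stop_nry("columns must map either ancestral+derived or mutation")
  }
  raw <- read.table(path, sep = sep, header = header, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE)
  if (ncol(raw) < max(columns)) {
    stop_nry(sprintf("file has %d column(s) but the column map needs %d",
                     ncol(raw), max(columns)))
  }
  name <- trimws(raw[[columns[["name"]]]])
  haplogroup <- trimws(raw[[columns[["haplogroup"]]]])
  position <- suppressWarnings(as.numeric(trimws(raw[[columns[["position"]]]])))
  if (two_col) {
    ancestral <- toupper(trimws(raw[[columns[["ancestral"]]]]))
    derived <- toupper(trimws(raw[[columns[["derived"]]]]))
  } else {
    mut <- toupper(gsub("\\s", "", raw[[columns[["mutation"]]]]))
    parts <- regmatches(mut, regexec("^([ACGT])->?([ACGT])$", mut))
    ancestral <- vapply(parts, function(x) if (length(x) == 3) x[2] else NA_character_, "")
    derived <- vapply(parts, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  }
  ok <- !is.na(position) & position >= 1 & position == floor(position) &
    ancestral %in% BASES & derived %in% BASES & ancestral != derived
  out <- snp_table(name[ok], haplogroup[ok], position[ok],
                   ancestral[ok], derived[ok])
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Write a SNP catalogue as delimited text
#'
#' @param snps A `snp_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path, sep = ",") {
  write.table(as.data.frame(snps), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
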