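# shared fixture builders; everything is generated in code

# pileup from a named list position -> named base-count vector
make_pileup <- function(sites, sample = "S1", offsets = NULL) {
  pos <- as.numeric(names(sites))
  counts <- matrix(0L, length(pos), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(sites)) {
    counts[i, names(sites[[i]])] <- sites[[i]]
  }
  nry_pileup(pos, counts, offsets = offsets, sample = sample)
}

# consensus_seq built directly from positions + bases
make_consensus <- function(positions, base, sample, mode = NA_character_) {
  structure(list(sample = sample, positions = positions, base = base,
                 mode = mode), class = "consensus_seq")
}

# brute-force union size of 0-based half-open intervals via boolean mask
mask_union_length <- function(start, end) {
  m <- logical(max(end))
  for (i in seq_along(start)) {
    if (end[i] > start[i]) m[(start[i] + 1):end[i]] <- TRUE
  }
  sum(m)
}

# random interval set on [0, span)
random_intervals <- function(n, span = 1000) {
  start <- sample.int(span - 1, n, replace = TRUE) - 1
  len <- sample.int(50, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + len, span))
}

# brute-force four-rule diagnostic scan used as the oracle
oracle_diagnostic <- function(gm, known = NULL) {
  keep <- logical(length(gm$positions))
  for (j in seq_along(gm$positions)) {
    ing <- gm$geno[gm$groups == "ingroup", j]
    out <- gm$geno[gm$groups == "outgroup", j]
    r1 <- sum(ing == "ancestral", na.rm = TRUE) == 0
    r2 <- sum(!is.na(ing)) > 1
    r3 <- sum(out == "derived", na.rm = TRUE) == 0
    r4 <- sum(!is.na(out)) > 1
    dmg <- (gm$ref[j] == "C" && gm$alt[j] == "T") ||
      (gm$ref[j] == "G" && gm$alt[j] == "A")
    known_hit <- !is.null(known) &&
      any(known$position == gm$positions[j] &
            known$ancestral == gm$ref[j] & known$derived == gm$alt[j])
    keep[j] <- r1 && r2 && r3 && r4 && (!dmg || known_hit)
  }
  gm$positions[keep]
}

# random genotype matrix for the diagnostic-SNP property tests
random_genotype_matrix <- function(n_samples = 20, n_positions = 200,
                                   p_missing = 0.4, p_derived = 0.3) {
  cells <- sample(c("ancestral", "derived", NA), n_samples * n_positions,
                  replace = TRUE,
                  prob = c(1 - p_missing - p_derived, p_derived, p_missing))
  geno <- matrix(cells, n_samples, n_positions,
                 dimnames = list(sprintf("G%02d", seq_len(n_samples)),
                                 seq_len(n_positions) * 10))
  groups <- sample(rep(c("ingroup", "outgroup"), length.out = n_samples))
  ref <- sample(c("A", "C", "G", "T"), n_positions, replace = TRUE)
  alt_shift <- sample(1:3, n_positions, replace = TRUE)
  alt <- c("A", "C", "G", "T")[(match(ref, c("A", "C", "G", "T")) - 1 +
                                  alt_shift) %% 4 + 1]
  genotype_matrix(geno, groups, ref, alt)
}

# independent root-path tracer over a lineage_tree (test-side oracle)
trace_root_path_labels <- function(tree, leaf_id) {
  i <- match(leaf_id, tree$leaf_id)
  labs <- character()
  while (!is.na(i)) {
    labs <- c(tree$label[i], labs)
    i <- tree$parent[i]
  }
  labs
}
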