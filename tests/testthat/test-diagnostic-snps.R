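make_gm <- function(ing, out, ref = "A", alt = "G", position = 1000) {
  geno <- rbind(matrix(ing, ncol = 1), matrix(out, ncol = 1))
  rownames(geno) <- sprintf("S%d", seq_len(nrow(geno)))
  colnames(geno) <- position
  genotype_matrix(geno, c(rep("ingroup", length(ing)),
                          rep("outgroup", length(out))),
                  ref, alt)
}

test_that("each of the four diagnostic rules filters as stated", {
  hit <- make_gm(c("derived", "derived", NA), c("ancestral", "ancestral"))
  res <- find_diagnostic_sites(hit)
  expect_equal(res$position, 1000)
  expect_equal(res$annotation, "novel")
  expect_equal(res$ingroup_derived, 2)

  # (1) an ancestral ingroup sample rejects the site
  r1 <- make_gm(c("derived", "ancestral", NA), c("ancestral", "ancestral"))
  expect_equal(nrow(find_diagnostic_sites(r1)), 0)
  # (2) a single covered ingroup sample is not enough
  r2 <- make_gm(c("derived", NA, NA), c("ancestral", "ancestral"))
  expect_equal(nrow(find_diagnostic_sites(r2)), 0)
  # (3) a derived outgroup sample rejects the site
  r3 <- make_gm(c("derived", "derived", NA), c("derived", "ancestral"))
  expect_equal(nrow(find_diagnostic_sites(r3)), 0)
  # (4) a single covered outgroup sample is not enough
  r4 <- make_gm(c("derived", "derived", "derived"), c("ancestral", NA))
  expect_equal(nrow(find_diagnostic_sites(r4)), 0)
})

test_that("C>T / G>A candidates survive only when previously known", {
  dmg <- make_gm(c("derived", "derived"), c("ancestral", "ancestral"),
                 ref = "C", alt = "T")
  expect_equal(nrow(find_diagnostic_sites(dmg)), 0)
  known <- snp_table("P96", "H2", 1000, "C", "T")
  res <- find_diagnostic_sites(dmg, known = known)
  expect_equal(res$position, 1000)
  expect_true(res$known)
  expect_equal(res$annotation, "H2")
  # same position, different allele pair: still excluded
  other <- snp_table("P96", "H2", 1000, "C", "A")
  expect_equal(nrow(find_diagnostic_sites(dmg, known = other)), 0)
})

test_that("too-small groups are rejected", {
  gm <- make_gm(c("derived"), c("ancestral", "ancestral"))
  expect_error(find_diagnostic_sites(gm), ">= 2")
})

test_that("the finder equals the brute-force four-rule oracle on random matrices", {
  set.seed(37)
  known <- snp_table(paste0("k", 1:40), rep(c("H2", "R1a"), 20),
                     sample(seq(10, 2000, by = 10), 40),
                     rep("C", 40), rep("T", 40))
  for (r in 1:200) {
    gm <- random_genotype_matrix(20, 200)
    res <- find_diagnostic_sites(gm, known = known)
    expect_setequal(res$position, oracle_diagnostic(gm, known))
  }
})

test_that("discovery is invariant to sample order and all-missing padding", {
  set.seed(41)
  gm <- random_genotype_matrix(16, 120)
  base <- find_diagnostic_sites(gm)$position
  perm <- sample(nrow(gm$geno))
  gm_perm <- genotype_matrix(gm$geno[perm, ], gm$groups[perm], gm$ref, gm$alt)
  expect_setequal(find_diagnostic_sites(gm_perm)$position, base)

  pad <- matrix(NA_character_, 2, ncol(gm$geno),
                dimnames = list(c("PAD1", "PAD2"), colnames(gm$geno)))
  gm_pad <- genotype_matrix(rbind(gm$geno, pad),
                            c(gm$groups, "ingroup", "outgroup"),
                            gm$ref, gm$alt)
  expect_setequal(find_diagnostic_sites(gm_pad)$position, base)
})

test_that("simulated clade discovery recovers the subtending branch mutations", {
  tr <- simulate_tree(10, 50000, seed = 371)
  truth <- place_mutations(tr, mu = 8e-9, L = 2e5, seed = 372)
  em <- emit_pileups(truth, mean_depth = 15, missing_frac = 0.1,
                     damage_rate = 0, sites = truth$mutations$position,
                     seed = 373)
  # candidate clade: leaves under one child of the root
  kids <- which(tr$parent == 1)
  under <- function(node) {
    ids <- node
    repeat {
      nxt <- which(tr$parent %in% ids)
      if (all(nxt %in% ids)) break
      ids <- union(ids, nxt)
    }
    ids
  }
  clade_nodes <- under(kids[1])
  ing_ids <- tr$leaf_id[intersect(clade_nodes, which(tr$leaf))]
  if (length(ing_ids) >= 2 && tr$n_leaves - length(ing_ids) >= 2) {
    cons <- lapply(em$pileups, consensus_sequence)
    pos <- truth$mutations$position
    geno <- t(vapply(cons, function(cs) {
      hit <- match(pos, cs$positions)
      der <- truth$mutations$derived
      out <- ifelse(is.na(hit), NA_character_,
                    ifelse(cs$base[hit] == der, "derived", "ancestral"))
      out
    }, character(length(pos))))
    rownames(geno) <- names(em$pileups)
    colnames(geno) <- pos
    gm <- genotype_matrix(geno,
                          ifelse(rownames(geno) %in% ing_ids,
                                 "ingroup", "outgroup"),
                          truth$mutations$ancestral, truth$mutations$derived)
    found <- find_diagnostic_sites(gm, known = emit_snp_table(truth))
    oracle <- oracle_diagnostic(gm, known = emit_snp_table(truth))
    expect_setequal(found$position, oracle)
    # mutations on the clade's subtending branch that pass coverage are found
    stem <- truth$mutations$position[truth$mutations$node == kids[1]]
    covered_stem <- intersect(stem, oracle)
    expect_true(all(covered_stem %in% found$position))
    expect_true(all(truth$tree$label[truth$mutations$node[
      match(setdiff(found$position, stem), truth$mutations$position)]] %in%
        truth$tree$label[clade_nodes]))
  }
})

test_that("annotation against catalogues yields in/out-of-clade and novel counts", {
  res <- data.frame(position = c(100, 200, 300),
                    ref = c("A", "C", "G"), alt = c("G", "A", "T"),
                    ingroup_derived = 2, ingroup_covered = 2,
                    outgroup_covered = 2, damage_pair = FALSE,
                    known = FALSE, annotation = "novel",
                    stringsAsFactors = FALSE)
  isogg <- snp_table("a", "H2a", 100, "A", "G")
  yfull <- snp_table("b", "R1a1", 200, "C", "A")
  ann <- annotate_known(res, list(isogg, yfull), clade_prefix = "H2")
  expect_equal(unname(ann$summary),
               c(1, 1, 1))
  expect_equal(ann$snps$annotation, c("H2a", "R1a1", "novel"))
  # empty catalogue: everything stays novel
  ann2 <- annotate_known(res, snp_table(character(), character(),
                                        numeric(), character(), character()))
  expect_equal(unname(ann2$summary), c(0, 0, 3))
})

test_that("missingness report follows the x/N convention and recounts cells", {
  geno <- matrix(NA_character_, 31, 1, dimnames = list(sprintf("S%d", 1:31), 8611196))
  geno[1:20, 1] <- "derived"
  gm <- genotype_matrix(geno, rep("ingroup", 31), "A", "G")
  rep1 <- missingness_report(gm, 8611196)
  expect_equal(rep1$label, "20/31")
  expect_equal(rep1$missing, 11)
  expect_equal(rep1$ancestral, 0)
  expect_equal(rep1$derived, sum(geno == "derived", na.rm = TRUE))
  expect_error(missingness_report(gm, 999), "not in matrix")
})
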