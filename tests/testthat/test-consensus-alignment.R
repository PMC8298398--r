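test_that("consensus calls obey the depth and minor-fraction filters", {
  expect_true(is.na(consensus_call(c(T = 1))))               # depth < 2
  expect_true(is.na(consensus_call(c(A = 9, G = 1))))        # minor = 0.10
  expect_equal(consensus_call(c(A = 19, G = 1)), "A")        # minor = 0.05
  expect_equal(consensus_call(c(C = 2)), "C")
  expect_true(is.na(consensus_call(c(A = 5, G = 5))))        # tie
  expect_true(is.na(consensus_call(c(A = 4, G = 1))))        # minor = 0.20
})

test_that("no consensus base is ever supported by fewer than two reads", {
  set.seed(23)
  for (r in 1:50) {
    cnt <- setNames(stats::rpois(4, 1), c("A", "C", "G", "T"))
    call <- consensus_call(cnt)
    if (!is.na(call)) expect_gte(cnt[call], 2)
  }
})

test_that("vectorized consensus matches the per-site rule", {
  tr <- simulate_tree(2, 50000, seed = 231)
  truth <- place_mutations(tr, mu = 2e-8, L = 1e4, seed = 232)
  em <- emit_pileups(truth, mean_depth = 3, missing_frac = 0.2,
                     damage_rate = 0.05, seed = 233)
  p <- em$pileups[[1]]
  cs <- consensus_sequence(p)
  per_site <- vapply(seq_along(p$positions), function(i)
    consensus_call(p$counts[i, ]), "")
  expect_equal(cs$positions, p$positions[!is.na(per_site)])
  expect_equal(cs$base, per_site[!is.na(per_site)])
})

test_that("build_alignment applies sample and site filters to a fixed point", {
  # three identical sequences: nothing segregates
  same <- lapply(c("S1", "S2", "S3"), function(s)
    make_consensus(c(1, 2, 3), c("A", "C", "G"), s))
  expect_error(build_alignment(same, min_seg_sites = 1), "segregating")

  a <- make_consensus(c(1, 2, 3), c("A", "C", "G"), "S1")
  b <- make_consensus(c(1, 2, 3), c("T", "G", "C"), "S2")
  m <- build_alignment(list(a, b), min_seg_sites = 2)
  expect_equal(dim(m$mat), c(2, 3))
  expect_equal(m$positions, c(1, 2, 3))

  # a sample below the segregating-site minimum is dropped, and sites
  # covered by < 2 of the survivors go with it
  c3 <- make_consensus(1, "T", "S3")
  expect_error(build_alignment(list(a, b, c3), min_seg_sites = 10),
               "minimum")
})

test_that("build_alignment is idempotent", {
  set.seed(29)
  cons <- lapply(sprintf("S%d", 1:6), function(s) {
    pos <- sort(sample.int(40, 25))
    make_consensus(pos, sample(c("A", "G"), 25, replace = TRUE), s)
  })
  m1 <- build_alignment(cons, min_seg_sites = 5)
  again <- lapply(seq_along(m1$samples), function(i) {
    called <- !is.na(m1$mat[i, ])
    make_consensus(m1$positions[called], m1$mat[i, called], m1$samples[i])
  })
  m2 <- build_alignment(again, min_seg_sites = 5)
  expect_equal(m2$mat, m1$mat)
  expect_equal(m2$positions, m1$positions)
})

test_that("alignment sites equal truth mutations covered in >= 2 samples", {
  tr <- simulate_tree(6, 40000, seed = 241)
  truth <- place_mutations(tr, mu = 1e-8, L = 1e5, seed = 242)
  em <- emit_pileups(truth, mean_depth = 8, missing_frac = 0.3,
                     damage_rate = 0, seed = 243)
  cons <- lapply(em$pileups, consensus_sequence)
  m <- build_alignment(cons, min_seg_sites = 1)
  # oracle: segregating implies mutated (no damage/noise), called in >= 2
  called <- vapply(truth$mutations$position, function(pos) {
    bases <- vapply(cons, function(cs) {
      i <- match(pos, cs$positions)
      if (is.na(i)) NA_character_ else cs$base[i]
    }, "")
    sum(!is.na(bases)) >= 2 && length(unique(bases[!is.na(bases)])) >= 2
  }, TRUE)
  expect_setequal(m$positions, truth$mutations$position[called])
})

test_that("neighbour joining recovers clean simulated topologies", {
  tr <- simulate_tree(6, 50000, seed = 251)
  truth <- place_mutations(tr, mu = 1e-8, L = 2e5, seed = 252)
  em <- emit_pileups(truth, mean_depth = 20, missing_frac = 0,
                     damage_rate = 0, seed = 253)
  cons <- lapply(em$pileups, consensus_sequence)
  m <- build_alignment(cons, min_seg_sites = 1)
  nwk <- pairwise_distance_tree(m)
  nj <- ape::read.tree(text = as.character(nwk))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj),
                                         ape::unroot(as_phylo_lineage(tr)))), 0)

  # permuting the sample order leaves the topology invariant
  m_perm <- m
  perm <- c(4, 1, 6, 3, 2, 5)
  m_perm$mat <- m$mat[perm, ]
  m_perm$samples <- m$samples[perm]
  m_perm$seg_covered <- m$seg_covered[perm]
  nj2 <- ape::read.tree(text = as.character(pairwise_distance_tree(m_perm)))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), ape::unroot(nj2))), 0)
})

test_that("three samples give the single unrooted topology", {
  cons <- list(make_consensus(1:5, c("A", "A", "G", "G", "T"), "S1"),
               make_consensus(1:5, c("A", "G", "G", "T", "T"), "S2"),
               make_consensus(1:5, c("C", "G", "A", "G", "T"), "S3"))
  m <- build_alignment(cons, min_seg_sites = 1)
  nwk <- pairwise_distance_tree(m)
  phy <- ape::read.tree(text = as.character(nwk))
  expect_equal(length(phy$tip.label), 3)
  expect_equal(phy$Nnode, 1)
})

test_that("pairs with no joint coverage stop the distance tree", {
  cons <- list(make_consensus(c(1, 2), c("A", "G"), "S1"),
               make_consensus(c(1, 2), c("G", "A"), "S2"),
               make_consensus(c(1, 2), c("G", "G"), "S3"))
  m <- build_alignment(cons, min_seg_sites = 1)
  m$mat[3, ] <- NA_character_
  m$mat[3, 1] <- "A"
  m$mat[1, 1] <- NA_character_
  expect_error(pairwise_distance_tree(m), "S1-S3")
})

test_that("the basal split of the NJ tree matches the truth tree's", {
  tr <- simulate_tree(8, 60000, seed = 261)
  truth <- place_mutations(tr, mu = 1e-8, L = 2e5, seed = 262)
  em <- emit_pileups(truth, mean_depth = 15, missing_frac = 0.1,
                     damage_rate = 0, seed = 263)
  cons <- lapply(em$pileups, consensus_sequence)
  m <- build_alignment(cons, min_seg_sites = 1)
  nwk <- pairwise_distance_tree(m)
  nj <- ape::read.tree(text = as.character(nwk))
  # truth basal clades: leaves under each child of the root
  kids <- which(tr$parent == 1)
  clade <- function(node) {
    ids <- node
    repeat {
      nxt <- which(tr$parent %in% ids)
      if (all(nxt %in% ids)) break
      ids <- union(ids, nxt)
    }
    sort(tr$leaf_id[intersect(ids, which(tr$leaf))])
  }
  truth_clades <- lapply(kids, clade)
  parts <- ape::prop.part(nj)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(idx) sort(labs[idx]))
  all_tips <- sort(nj$tip.label)
  has_split <- function(cl) {
    any(vapply(splits, identical, TRUE, cl)) ||
      any(vapply(splits, identical, TRUE, sort(setdiff(all_tips, cl))))
  }
  for (cl in truth_clades) {
    if (length(cl) >= 2) expect_true(has_split(sort(cl)))
  }
})
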