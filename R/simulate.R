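#' Simulate a Y-lineage tree
#'
#' Generates a random bifurcating genealogy for `n_leaves` male lineages
#' with the root placed exactly `depth_years` years before present and all
#' sampled leaves at the present (time 0). The topology is drawn by
#' recursive random splits of the leaf set; internal-node times are laid
#' out by tree level in disjoint jittered bands, which guarantees that
#' every branch has a duration of at least `0.5 * depth_years / levels`.
#' Named haplogroup branches in real Y phylogenies are typically defined by
#' several SNPs each; this layout reproduces that property at simulation
#' scale, whereas a plain coalescent would routinely produce near-zero
#' terminal branches that no SNP could tag.
#'
#' Node haplogroup labels are hierarchical (root `"Y"`, children appending
#' alternating letter/digit suffixes, ISOGG-style); each leaf's label is
#' its true haplogroup. Leaf sample ids are `S001`, `S002`, ...
#'
#' @param n_leaves Number of sampled lineages (>= 2).
#' @param depth_years Root age in years before present.
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @return An object of class `lineage_tree`: parallel vectors `parent`
#'   (NA at the root), `time` (years BP), `leaf`, `label` (haplogroup),
#'   `leaf_id` (sample id or NA).
#' @export
simulate_tree <- function(n_leaves, depth_years, seed = NULL) {
  if (n_leaves < 2) stop_nry("n_leaves must be >= 2")
  if (depth_years <= 0) stop_nry("depth_years must be positive")
  with_seed(seed, {
    parent <- NA_integer_
    level <- 0L
    nsub <- as.integer(n_leaves)   # leaves under each node
    label <- "Y"
    # breadth-first construction by random binomial splits
    queue <- 1L
    while (length(queue)) {
      id <- queue[1]
      queue <- queue[-1]
      n <- nsub[id]
      if (n == 1L) next
      k <- 0L
      while (k < 1L || k > n - 1L) k <- stats::rbinom(1, n, 0.5)
      lev <- level[id] + 1L
      suffixes <- if (lev %% 2L == 1L) letters[1:2] else as.character(1:2)
      for (j in 1:2) {
        parent <- c(parent, id)
        level <- c(level, lev)
        nsub <- c(nsub, if (j == 1) k else n - k)
        label <- c(label, paste0(label[id], suffixes[j]))
        queue <- c(queue, length(parent))
      }
    }
    leaf <- nsub == 1L
    internal <- !leaf
    m <- max(level[internal]) + 1L
    u <- runif(length(parent), 0, 0.5)
    time <- ifelse(leaf, 0, depth_years * (m - level + u) / m)
    time[1] <- depth_years  # root exactly at depth_years
    leaf_id <- rep(NA_character_, length(parent))
    leaf_id[leaf] <- sprintf("S%03d", seq_len(sum(leaf)))
    structure(list(parent = parent, time = time, leaf = leaf,
                   label = label, leaf_id = leaf_id,
                   n_leaves = sum(leaf), depth_years = depth_years),
              class = "lineage_tree")
  })
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d leaves, root %.0f years BP, %d nodes\n",
              x$n_leaves, x$time[1], length(x$parent)))
  invisible(x)
}

# node ids on the path root -> node (root first, node last)
root_path <- function(tree, node) {
  path <- node
  while (!is.na(tree$parent[path[1]])) path <- c(tree$parent[path[1]], path)
  path
}

#' True TMRCA of two leaves in a simulated tree
#'
#' @param tree A [simulate_tree()] result.
#' @param leaf_a,leaf_b Leaf sample ids (e.g. `"S001"`).
#' @return MRCA age in years before present.
#' @export
lineage_tmrca <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$leaf_id)
  ib <- match(leaf_b, tree$leaf_id)
  if (is.na(ia) || is.na(ib)) stop_nry("unknown leaf id")
  common <- intersect(root_path(tree, ia), root_path(tree, ib))
  tree$time[common[length(common)]]
}

#' Convert a lineage tree to an ape phylo object
#'
#' @param tree A `lineage_tree`.
#' @return An object of class `phylo` with branch lengths in years.
#' @export
as_phylo_lineage <- function(tree) {
  tips <- which(tree$leaf)
  internals <- c(1L, setdiff(which(!tree$leaf), 1L))  # root first
  idmap <- integer(length(tree$parent))
  idmap[tips] <- seq_along(tips)
  idmap[internals] <- length(tips) + seq_along(internals)
  nonroot <- which(!is.na(tree$parent))
  edge <- cbind(idmap[tree$parent[nonroot]], idmap[nonroot])
  phy <- structure(list(edge = edge,
                        tip.label = tree$leaf_id[tips],
                        edge.length = tree$time[tree$parent[nonroot]] -
                          tree$time[nonroot],
                        Nnode = length(internals)),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Place mutations on a simulated tree
#'
#' Under the infinite-sites model, each branch receives a Poisson number of
#' mutations with mean `mu * L * duration`; mutated positions are drawn
#' uniformly without replacement over `1..L`, so no position mutates twice.
#' Each mutation gets a random ancestral base and a random distinct derived
#' base.
#'
#' @param tree A [simulate_tree()] result.
#' @param mu Substitution rate in substitutions/site/year (NRY-scale
#'   default 8e-10).
#' @param L Sequence length in bp (the mappable NRY is ~10,445,000 bp;
#'   reduce for fast simulations).
#' @param seed Integer seed.
#' @return An object of class `simulation_truth`: the tree, a `mutations`
#'   data.frame (`position`, `node` = child end of the mutated branch,
#'   `ancestral`, `derived`), `mu` and `L`.
#' @export
place_mutations <- function(tree, mu = 8e-10, L = 10445000, seed = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (mu <= 0 || L <= 0) stop_nry("mu and L must be positive")
  nonroot <- which(!is.na(tree$parent))
  duration <- tree$time[tree$parent[nonroot]] - tree$time[nonroot]
  lambda <- mu * L * duration
  if (sum(lambda) > 0.5 * L) {
    stop_nry("expected mutation count exceeds half the sequence length; ",
             "reduce mu or increase L (infinite-sites assumption broken)")
  }
  with_seed(seed, {
    counts <- rpois(length(lambda), lambda)
    total <- sum(counts)
    # positions drawn without replacement are exchangeable, so assigning
    # them blockwise to branches keeps per-branch positions uniform
    positions <- if (total) sample.int(L, total) else integer()
    node <- rep(nonroot, counts)
    anc_i <- sample.int(4, max(total, 1), replace = TRUE)[seq_len(total)]
    der_i <- ((anc_i - 1 + sample.int(3, max(total, 1),
                                      replace = TRUE)[seq_len(total)]) %% 4) + 1
    structure(list(tree = tree,
                   mutations = data.frame(position = positions,
                                          node = node,
                                          ancestral = BASES[anc_i],
                                          derived = BASES[der_i],
                                          stringsAsFactors = FALSE),
                   mu = mu, L = L),
              class = "simulation_truth")
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d mutation(s), mu=%.3g, L=%s, %d leaves\n",
              nrow(x$mutations), x$mu, format(x$L, big.mark = ","),
              x$tree$n_leaves))
  invisible(x)
}

#' True haplotype of one simulated leaf
#'
#' @param truth A [place_mutations()] result.
#' @param leaf Leaf sample id.
#' @param sites Positions at which to report the haplotype; defaults to the
#'   mutated positions.
#' @param ref Reference (ancestral) base per site; defaults to the mutation
#'   ancestral alleles at mutated sites and `"A"` elsewhere.
#' @return Character vector of bases, named by position.
#' @export
leaf_haplotype <- function(truth, leaf, sites = NULL, ref = NULL) {
  tree <- truth$tree
  i <- match(leaf, tree$leaf_id)
  if (is.na(i)) stop_nry("unknown leaf id: ", leaf)
  sites <- sites %||% truth$mutations$position
  if (is.null(ref)) {
    ref <- rep("A", length(sites))
    hit <- match(sites, truth$mutations$position)
    ref[!is.na(hit)] <- truth$mutations$ancestral[hit[!is.na(hit)]]
  }
  hap <- ref
  path <- root_path(tree, i)
  onpath <- truth$mutations$node %in% path
  hit <- match(truth$mutations$position[onpath], sites)
  hap[hit[!is.na(hit)]] <- truth$mutations$derived[onpath][!is.na(hit)]
  setNames(hap, sites)
}

#' Synthetic haplogroup-SNP catalogue from simulation truth
#'
#' Every placed mutation becomes one catalogue SNP labelled with the
#' haplogroup of the clade below the mutated branch, exactly as ISOGG names
#' haplogroup-defining SNPs. A leaf is therefore derived for precisely the
#' SNPs on its root path.
#'
#' @param truth A [place_mutations()] result with >= 1 mutation.
#' @return A [snp_table()].
#' @export
emit_snp_table <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  m <- truth$mutations
  if (!nrow(m)) stop_nry("truth contains no mutations")
  snp_table(name = sprintf("sim%05d", seq_len(nrow(m))),
            haplogroup = truth$tree$label[m$node],
            position = m$position, ancestral = m$ancestral,
            derived = m$derived)
}

#' Emit per-sample pileups from simulation truth
#'
#' Generates, for each leaf, a read pileup with the statistical structure
#' the downstream analyses assume: per-site Poisson depth, whole-site
#' dropout, post-mortem deamination (each endogenous read of a C flips to
#' T, and of a G to A, independently with probability `damage_rate` —
#' orientation-symmetric because strand is folded downstream), and optional
#' contamination in which each read is drawn from another leaf's haplotype
#' with probability `contam_frac`. Contaminant reads are modelled as
#' present-day (undamaged) male DNA. Read-end offsets are drawn from a
#' uniform position within a read of `read_length` bp.
#'
#' @param truth A [place_mutations()] result.
#' @param mean_depth Mean reads per covered site (Poisson).
#' @param missing_frac Probability a site is dropped entirely.
#' @param damage_rate Per-read deamination probability at C/G sites.
#' @param contam_frac Probability a read comes from the contaminant.
#' @param contam_source Leaf sample id of the contaminant (required when
#'   `contam_frac > 0`).
#' @param read_length Read length in bp used to draw end offsets.
#' @param sites Positions to cover; defaults to all of `1..L` (reduce `L`
#'   or pass e.g. catalogue positions to keep simulations light).
#' @param with_offsets Track per-read end offsets? (Adds memory; needed
#'   only for damage review.)
#' @param seed Integer seed.
#' @return List with `pileups` (named list of [nry_pileup], one per leaf),
#'   `ref` (reference/ancestral base per site), `sites`, and `samples`
#'   (data.frame of sample id and true haplogroup).
#' @export
emit_pileups <- function(truth, mean_depth = 5, missing_frac = 0.1,
                         damage_rate = 0.02, contam_frac = 0,
                         contam_source = NULL, read_length = 60,
                         sites = NULL, with_offsets = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  for (p in c(missing_frac, damage_rate, contam_frac)) {
    if (p < 0 || p > 1) stop_nry("proportions must lie in [0, 1]")
  }
  if (contam_frac > 0 && is.null(contam_source)) {
    stop_nry("contam_frac > 0 requires a contam_source leaf id")
  }
  tree <- truth$tree
  sites <- sort(sites %||% seq_len(truth$L))
  with_seed(seed, {
    ref <- sample(BASES, length(sites), replace = TRUE)
    hit <- match(truth$mutations$position, sites)
    ref[hit[!is.na(hit)]] <- truth$mutations$ancestral[!is.na(hit)]
    contam_hap <- if (!is.null(contam_source)) {
      leaf_haplotype(truth, contam_source, sites, ref)
    }
    leaves <- which(tree$leaf)
    pileups <- vector("list", length(leaves))
    names(pileups) <- tree$leaf_id[leaves]
    for (k in seq_along(leaves)) {
      id <- tree$leaf_id[leaves[k]]
      hap <- leaf_haplotype(truth, id, sites, ref)
      keep <- runif(length(sites)) >= missing_frac
      pos <- sites[keep]
      own_base <- hap[keep]
      depth <- rpois(length(pos), mean_depth)
      nz <- depth > 0
      pos <- pos[nz]; own_base <- own_base[nz]; depth <- depth[nz]
      contam <- if (contam_frac > 0) rbinom(length(pos), depth, contam_frac)
                else integer(length(pos))
      endo <- depth - contam
      counts <- matrix(0L, length(pos), 4, dimnames = list(NULL, BASES))
      for (b in BASES) {
        idx <- which(own_base == b & endo > 0)
        if (!length(idx)) next
        if (b == "C" && damage_rate > 0) {
          flips <- rbinom(length(idx), endo[idx], damage_rate)
          counts[idx, "C"] <- counts[idx, "C"] + endo[idx] - flips
          counts[idx, "T"] <- counts[idx, "T"] + flips
        } else if (b == "G" && damage_rate > 0) {
          flips <- rbinom(length(idx), endo[idx], damage_rate)
          counts[idx, "G"] <- counts[idx, "G"] + endo[idx] - flips
          counts[idx, "A"] <- counts[idx, "A"] + flips
        } else {
          counts[idx, b] <- counts[idx, b] + endo[idx]
        }
      }
      if (contam_frac > 0) {
        cbase <- contam_hap[keep][nz]
        for (b in BASES) {
          idx <- which(cbase == b & contam > 0)
          if (length(idx)) counts[idx, b] <- counts[idx, b] + contam[idx]
        }
      }
      offsets <- NULL
      if (with_offsets) {
        per_base_pos <- lapply(BASES, function(b) rep(pos, counts[, b]))
        opos <- unlist(per_base_pos)
        obase <- rep(BASES, vapply(per_base_pos, length, 0L))
        inread <- sample.int(read_length, length(opos), replace = TRUE)
        offsets <- data.frame(position = opos, base = obase,
                              offset = pmin(inread - 1L, read_length - inread))
        offsets <- offsets[order(offsets$position), ]
      }
      pileups[[k]] <- nry_pileup(pos, counts, offsets = offsets,
                                 chrom = "Y", sample = id)
    }
    list(pileups = pileups, ref = setNames(ref, sites), sites = sites,
         samples = data.frame(sample = tree$leaf_id[leaves],
                              haplogroup = tree$label[leaves],
                              stringsAsFactors = FALSE))
  })
}
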