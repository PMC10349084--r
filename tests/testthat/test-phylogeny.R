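test_that("domain regions are extracted with 1-based inclusive coordinates", {
  r <- rec("x", paste(rep("ACDEFGHIKL", 30), collapse = ""))
  cut <- extract_domain_region(r, data.frame(start = 51, end = 250))
  expect_equal(nchar(cut$residues), 200)
  expect_equal(cut$id, "x_51-250")
  expect_equal(cut$residues, substring(r$residues, 51, 250))

  full <- extract_domain_region(r, data.frame(start = 1, end = 300))
  expect_equal(full$residues, r$residues)

  two <- lapply(list(c(1, 100), c(151, 300)), function(h)
    extract_domain_region(r, data.frame(start = h[1], end = h[2])))
  expect_false(two[[1]]$id == two[[2]]$id)

  expect_error(extract_domain_region(r, data.frame(start = 0, end = 10)),
               "coordinate")
  expect_error(extract_domain_region(r, data.frame(start = 200, end = 301)),
               "coordinate")
})

test_that("column filtering keeps exactly the sufficiently occupied columns", {
  # 20 rows; column 1 has 9 residues (removed), column 2 has 10 (retained)
  rows <- lapply(1:20, function(i) {
    c1 <- if (i <= 9) "A" else "-"
    c2 <- if (i <= 10) "C" else "-"
    protein_record(paste0("r", i), paste0(c1, c2, "DDDD"), aligned = TRUE)
  })
  aln <- aa_alignment(rows)
  filt <- filter_columns(aln, min_occupancy = 10)
  expect_equal(filt$length, 5)
  expect_equal(substr(filt$records[[1]]$residues, 1, 1), "C")

  # alignment with no gaps is unchanged; filtering is idempotent
  nogap <- generate_family_alignment(seed = 3, n_taxa = 12,
                                     seq_length = 50)$alignment
  expect_equal(filter_columns(nogap, 10), nogap)

  dlhscan:::with_seed(13, {
    for (i in 1:5) {
      m <- matrix(sample(c(dlhscan:::AA20, rep("-", 30)), 15 * 40,
                         replace = TRUE), nrow = 15)
      aln_r <- aa_alignment(lapply(1:15, function(j)
        protein_record(paste0("s", j), paste(m[j, ], collapse = ""),
                       aligned = TRUE)))
      keep <- colSums(m != "-") >= 10
      if (!any(keep)) next
      f1 <- filter_columns(aln_r, 10)
      expect_equal(f1$length, sum(keep))
      expect_equal(dlhscan:::alignment_matrix(f1), m[, keep, drop = FALSE],
                   ignore_attr = TRUE)
      expect_equal(filter_columns(f1, 10), f1)  # idempotent
    }
  })
  expect_error(filter_columns(aln, min_occupancy = 50), "empty-alignment")
})

test_that("protein distances follow the closed-form models", {
  aln <- aa_alignment(list(rec("a", "AAAA", aligned = TRUE),
                           rec("b", "AAAC", aligned = TRUE),
                           rec("c", "AAAA", aligned = TRUE)))
  p <- distance_matrix(aln, model = "p_distance")
  expect_equal(p["a", "b"], 0.25)
  expect_equal(p["a", "c"], 0)
  pois <- distance_matrix(aln, model = "poisson")
  expect_equal(pois["a", "b"], -log(0.75), tolerance = 1e-12)
  kim <- distance_matrix(aln, model = "kimura_protein")
  expect_equal(kim["a", "b"], -log(1 - 0.25 - 0.2 * 0.25^2),
               tolerance = 1e-12)

  # saturated pairs are capped
  sat <- aa_alignment(list(rec("a", "AAAA", aligned = TRUE),
                           rec("b", "CCCC", aligned = TRUE),
                           rec("c", "AAAA", aligned = TRUE)))
  expect_equal(distance_matrix(sat, "poisson")["a", "b"], 10)

  # pairwise gap exclusion; a pair sharing no scored columns is an error
  gap <- aa_alignment(list(rec("a", "AA--", aligned = TRUE),
                           rec("b", "--CC", aligned = TRUE),
                           rec("c", "AACC", aligned = TRUE)))
  expect_error(distance_matrix(gap), "undefined-distance.*a.*b")

  # model ordering p <= poisson <= kimura for p in (0, 0.8)
  dlhscan:::with_seed(17, {
    for (i in 1:5) {
      fam <- generate_family_alignment(seed = i, n_taxa = 6,
                                       seq_length = 120,
                                       branch_range = c(0.05, 0.4))$alignment
      dp <- distance_matrix(fam, "p_distance")
      dpo <- distance_matrix(fam, "poisson")
      dk <- distance_matrix(fam, "kimura_protein")
      sel <- dp > 0 & dp < 0.8
      expect_true(all(dp[sel] <= dpo[sel] + 1e-12))
      expect_true(all(dpo[sel] <= dk[sel] + 1e-12))
    }
  })
})

test_that("neighbor joining matches the three-taxon closed form and additivity", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 1, c = 3))

  # additive oracle: distances from random trees are recovered exactly
  dlhscan:::with_seed(23, {
    for (i in 1:50) {
      n <- sample(4:10, 1)
      t0 <- ape::rtree(n, rooted = FALSE,
                       br = function(k) stats::runif(k, 0.1, 1))
      dm0 <- stats::cophenetic(t0)[t0$tip.label, t0$tip.label]
      tr0 <- neighbor_joining(dm0)
      expect_equal(ape::dist.topo(t0, tr0), 0, ignore_attr = TRUE)
      patristic <- stats::cophenetic(tr0)[t0$tip.label, t0$tip.label]
      expect_lt(max(abs(patristic - dm0)), 1e-9)
    }
  })

  # equidistant joins resolve deterministically
  um <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_identical(to_newick(neighbor_joining(um)),
                   to_newick(neighbor_joining(um)))

  # independent cross-check: same topology as ape's NJ on noisy matrices
  dlhscan:::with_seed(29, {
    for (i in 1:5) {
      m <- matrix(stats::runif(49, 1, 5), 7)
      m <- (m + t(m)) / 2; diag(m) <- 0
      dimnames(m) <- list(letters[1:7], letters[1:7])
      expect_equal(ape::dist.topo(neighbor_joining(m), ape::nj(m)), 0,
                   ignore_attr = TRUE)
    }
  })

  bad <- dm; bad[1, 2] <- 3
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap support is reproducible and strong for clear clades", {
  fam <- generate_family_alignment(seed = 2, design = "two_clade",
                                   n_taxa = 4, n_fixed_diff = 100)
  tr <- bootstrap_support(fam$alignment, n_replicates = 200, seed = 3)
  sup <- suppressWarnings(as.integer(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_length(sup, 1)  # one internal edge on 4 unrooted taxa
  expect_gte(sup, 95)

  # identical seeds give identical supports; single replicate is 0/100
  tr2 <- bootstrap_support(fam$alignment, n_replicates = 200, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  one <- bootstrap_support(fam$alignment, n_replicates = 1, seed = 9)
  s1 <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0L, 100L)))

  # supports are invariant to the row order of the alignment
  fam10 <- generate_family_alignment(seed = 5, design = "two_clade",
                                     n_taxa = 10, n_fixed_diff = 100)
  key_support <- function(aln) {
    tr <- bootstrap_support(aln, n_replicates = 50, seed = 7)
    bip <- dlhscan:::tree_bipartitions(tr)
    sup <- tr$node.label[bip$nodes - length(tr$tip.label)]
    stats::setNames(sup, bip$keys)[order(bip$keys)]
  }
  shuffled <- aa_alignment(rev(fam10$alignment$records))
  expect_identical(key_support(fam10$alignment),
                   key_support(shuffled))
})

test_that("newick serialization round-trips topology, lengths and support", {
  tr3 <- neighbor_joining(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                                 dimnames = list(c("a", "b", "c"),
                                                 c("a", "b", "c"))))
  txt <- to_newick(tr3)
  expect_match(txt, "^\\(.*a.*b.*c.*\\);$")

  fam <- generate_family_alignment(seed = 8, n_taxa = 20, seq_length = 150)
  tr <- neighbor_joining(distance_matrix(fam$alignment))
  back <- from_newick(to_newick(tr))
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(stats::cophenetic(back)[tr$tip.label, tr$tip.label]),
               sort(stats::cophenetic(tr)), tolerance = 1e-12,
               ignore_attr = TRUE)

  sup_tree <- from_newick("(a:1,(b:1,c:1)95:0.5);")
  expect_true("95" %in% sup_tree$node.label)

  expect_error(from_newick("(a:1,(b:1,c:1):0.5;"), "parse error")
  expect_error(from_newick("(a:1))b;"), "position")
})
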