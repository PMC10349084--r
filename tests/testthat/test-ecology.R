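test_that("percent of mapped reads is exact, bounded and scale-invariant", {
  cnt <- matrix(c(5, 985, 10, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  pct <- percent_mapped_reads(cnt, c(1000, 10))
  expect_equal(pct["g1", "s1"], 0.5)
  expect_equal(pct["g2", "s2"], 0)
  expect_equal(percent_mapped_reads(matrix(50, 1, 1), 50)[1, 1], 100)

  # doubling all counts and totals leaves percentages unchanged
  expect_equal(percent_mapped_reads(2 * cnt, 2 * c(1000, 10)),
               percent_mapped_reads(cnt, c(1000, 10)))

  # an exhaustive table sums to at most 100 per sample
  expect_true(all(colSums(pct) <= 100 + 1e-12))

  expect_warning(p0 <- percent_mapped_reads(cnt, c(1000, 0)), "zero total")
  expect_true(all(is.na(p0[, 2])))
  expect_error(percent_mapped_reads(cnt, c(10, 10)), ">=")
})

test_that("spearman matches the exact rank formula on all permutations n <= 6", {
  # 1 - 6 sum(d^2) / (n (n^2 - 1)), valid without ties
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  for (n in 3:6) {
    x <- seq_len(n)
    for (y in perms(seq_len(n))) {
      d2 <- sum((x - y)^2)
      expect_equal(spearman_cor(x, y)$rho, 1 - 6 * d2 / (n * (n^2 - 1)),
                   tolerance = 1e-12)
    }
  }

  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)

  # cross-check rho and t-approximation p against cor.test
  dlhscan:::with_seed(5, {
    x <- stats::rnorm(30); y <- 0.5 * x + stats::rnorm(30)
    ours <- spearman_cor(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ct$estimate), tolerance = 1e-12)
    tstat <- ours$rho * sqrt((30 - 2) / (1 - ours$rho^2))
    expect_equal(ours$p, 2 * stats::pt(-abs(tstat), 28))
  })

  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))$rho))
  expect_match(spearman_cor(c(1, 1, 1), c(1, 2, 3))$reason, "constant")
  expect_true(is.na(spearman_cor(c(1, 2), c(1, 2))$rho))
  # pairwise deletion of missing values
  expect_equal(spearman_cor(c(1, 2, NA, 3, 4), c(1, 3, 5, NA, 9))$n, 3)
})

test_that("per-taxon per-region correlations use pairwise deletion and BH", {
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     station = paste0("st", 1:8), depth = 5,
                     region = rep(c("north", "south"), each = 4),
                     NO3 = c(1, 2, 3, 4, NA, NA, NA, NA),
                     Fe = c(8:5, 4:1), stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("d1", "d2", "h1"),
                      taxon = c("Dino", "Dino", "Hapto"),
                      stringsAsFactors = FALSE)
  values <- rbind(c(1, 2, 3, 4, 1, 1, 1, 1),
                  c(0, 0, 1, 2, 0, 0, 0, 0),
                  c(4, 3, 2, 1, 2, 2, 2, 2))
  tab <- abundance_table(values, genes, meta)
  corr <- taxon_region_correlations(tab, taxa = c("Dino", "Hapto"),
                                    variables = c("NO3", "Fe"))
  # planted monotone: Dino abundance rises with NO3 in the north
  cell <- corr[corr$taxon == "Dino" & corr$region == "north" &
                 corr$variable == "NO3", ]
  expect_equal(cell$rho, 1)
  # all-missing variable in a region is NA and counted
  na_cell <- corr[corr$taxon == "Dino" & corr$region == "south" &
                    corr$variable == "NO3", ]
  expect_true(is.na(na_cell$rho))
  expect_gte(attr(corr, "n_na_cells"), 1)
  # BH adjustment across the emitted grid
  expect_equal(corr$p_adj, stats::p.adjust(corr$p, "BH"))
  expect_error(taxon_region_correlations(tab, variables = "PO4"),
               "schema error.*PO4")
})

test_that("size factors implement median-of-ratios exactly", {
  # all samples identical -> all factors 1
  same <- matrix(rep(c(10, 20, 30, 40, 50), 3), ncol = 3)
  expect_equal(size_factors(same), rep(1, 3), ignore_attr = TRUE)

  # pure scaling: one sample 3x another
  dlhscan:::with_seed(7, {
    base <- stats::rpois(200, 100) + 1
    sc <- size_factors(cbind(a = base, b = 3 * base))
    expect_equal(sc["b"] / sc["a"], 3, ignore_attr = TRUE)
  })

  # 5-gene x 2-sample toy: hand-computed median of ratios
  toy <- matrix(c(10, 20, 30, 40, 50,
                  20, 10, 60, 120, 50), ncol = 2)
  ref <- exp(rowMeans(log(toy)))           # geometric mean per gene
  expected <- apply(toy / ref, 2, stats::median)
  expect_equal(size_factors(toy), expected, ignore_attr = TRUE)

  # gene order invariance; per-sample scaling multiplies its factor by k
  dlhscan:::with_seed(8, {
    cnt <- matrix(stats::rnbinom(300, mu = 80, size = 5) + 1, ncol = 3)
    expect_equal(sort(size_factors(cnt[sample(nrow(cnt)), ])),
                 sort(size_factors(cnt)))
    # scaling one sample by k multiplies its factor relative to any other
    # sample by exactly k (the geometric-mean reference shifts with it)
    k <- 2.5
    scaled <- cnt * 1.0; scaled[, 2] <- cnt[, 2] * k
    sf0 <- size_factors(cnt); sf1 <- size_factors(scaled)
    expect_equal(sf1[2] / sf1[1], k * sf0[2] / sf0[1],
                 ignore_attr = TRUE, tolerance = 1e-12)
  })

  # independent cross-check against the reference implementation
  dlhscan:::with_seed(9, {
    cnt <- matrix(stats::rnbinom(600, mu = 100, size = 5) + 1, ncol = 6)
    expect_equal(size_factors(cnt),
                 DESeq2::estimateSizeFactorsForMatrix(cnt),
                 ignore_attr = TRUE, tolerance = 1e-12)
  })

  allzero <- matrix(c(0, 5, 3, 0), 2)
  expect_error(size_factors(allzero), "poscounts")
  expect_true(all(size_factors(allzero, method = "poscounts") > 0))
})

test_that("fold changes recover planted contrasts with pseudocounts", {
  dlhscan:::with_seed(11, {
    mu <- exp(stats::rnorm(40, log(500), 0.3))
    fold <- rep(1, 40); fold[1:5] <- 1 / 8   # 8-fold reduction in group A
    cnt <- cbind(
      matrix(stats::rnbinom(40 * 3, mu = mu * fold, size = 50), ncol = 3),
      matrix(stats::rnbinom(40 * 3, mu = mu, size = 50), ncol = 3))
    colnames(cnt) <- paste0("s", 1:6)
    fc <- fold_change(cnt, group_a = 1:3, group_b = 4:6,
                      sf = rep(1, 6))
    # the planted contrast estimate lands in [6, 10] at n = 3 per group
    expect_true(stats::median(1 / fc[1:5]) >= 6 &&
                  stats::median(1 / fc[1:5]) <= 10)
    expect_true(all(1 / fc[1:5] >= 4 & 1 / fc[1:5] <= 16))
    expect_true(all(abs(log2(fc[6:40])) < 1))
  })

  same <- matrix(rep(c(30, 60, 90), 4), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  fc0 <- fold_change(same, 1:2, 3:4)
  expect_equal(unname(fc0), rep(1, 3), tolerance = 1e-12)

  zero <- rbind(same, 0)
  expect_equal(unname(fold_change(zero, 1:2, 3:4, sf = rep(1, 4))[4]), 1)
  expect_error(fold_change(same, 1:2, 2:3), "disjoint")
})

test_that("depth differential calls planted mesopelagic genes and controls type I", {
  depths <- c(20, 45, 80, 120, 150, 200, 250, 350, 450, 550, 650, 800)
  ds <- generate_abundance_dataset(seed = 7, stations = 1, depths = depths,
                                   n_regions = 1, taxa = "Dinophyceae",
                                   genes_per_taxon = 20, n_de_meso = 4,
                                   n_de_eu = 0)
  dd <- depth_differential(ds$table$values, ds$table$samples$depth,
                           n_permutations = 2000, seed = 5)
  called <- dd$gene[!is.na(dd$zone) & dd$zone == "mesopelagic"]
  expect_setequal(called, ds$manifest$de_genes$mesopelagic)

  # determinism under a fixed seed
  dd2 <- depth_differential(ds$table$values, ds$table$samples$depth,
                            n_permutations = 2000, seed = 5)
  expect_identical(dd$p, dd2$p)

  # type-I control on null data: raw permutation p-values are valid
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    null <- generate_abundance_dataset(seed = 300 + s, stations = 1,
                                       depths = depths, n_regions = 1,
                                       taxa = "Dinophyceae",
                                       genes_per_taxon = 20,
                                       n_de_meso = 0, n_de_eu = 0)
    ddn <- depth_differential(null$table$values, null$table$samples$depth,
                              n_permutations = 500, seed = s)
    hits <- hits + sum(ddn$p < 0.05)
    total <- total + nrow(ddn)
  }
  # binomial upper bound at nominal 0.05 over `total` tests
  expect_lte(hits / total, 0.05 + 2.58 * sqrt(0.05 * 0.95 / total))

  expect_error(depth_differential(ds$table$values,
                                  ds$table$samples$depth,
                                  boundary_m = 1000), "configuration")
})
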