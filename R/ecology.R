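#' Assemble an abundance table with sample metadata
#'
#' Container for a gene-by-sample matrix of percent-of-mapped-reads
#' abundances together with per-gene taxon labels and per-sample metadata
#' (station, depth in metres, oceanic region, size fraction, and
#' environmental variables such as temperature, NO3, PO4, Fe).
#'
#' @param values Non-negative gene x sample numeric matrix.
#' @param genes Data frame with columns `gene_id`, `taxon` (one row per
#'   matrix row).
#' @param samples Data frame with at least `sample_id`, `station`, `depth`,
#'   `region` (one row per matrix column); further numeric columns are
#'   treated as environmental variables.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, genes, samples) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("abundance values must be >= 0")
  req_g <- c("gene_id", "taxon")
  if (!all(req_g %in% names(genes)))
    stop("schema error: missing gene column(s): ",
         paste(setdiff(req_g, names(genes)), collapse = ", "))
  req_s <- c("sample_id", "station", "depth", "region")
  if (!all(req_s %in% names(samples)))
    stop("schema error: missing sample metadata column(s): ",
         paste(setdiff(req_s, names(samples)), collapse = ", "))
  if (nrow(genes) != nrow(values) || nrow(samples) != ncol(values))
    stop("dimension mismatch between values, genes and samples")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (!is.numeric(samples$depth)) stop("schema error: depth must be numeric")
  rownames(values) <- genes$gene_id
  colnames(values) <- samples$sample_id
  structure(list(values = values, genes = genes, samples = samples),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d genes x %d samples (%d regions, %d taxa)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$region)),
              length(unique(x$genes$taxon))))
  invisible(x)
}

#' Percent-of-mapped-reads abundance
#'
#' Converts raw per-gene read counts into the abundance unit used for
#' metatranscriptome biogeography: `100 * count / total mapped reads` of the
#' sample.
#'
#' @param counts Gene x sample matrix of non-negative integer counts.
#' @param total_mapped Per-sample totals of mapped reads; each must be at
#'   least the corresponding column sum.
#' @return Matrix of percentages; samples with a zero total yield an `NA`
#'   column with a warning.
#' @export
percent_mapped_reads <- function(counts, total_mapped) {
  counts <- as.matrix(counts)
  if (length(total_mapped) != ncol(counts))
    stop("one total per sample required")
  if (any(counts < 0)) stop("counts must be >= 0")
  zero <- total_mapped == 0
  if (any(total_mapped[!zero] < colSums(counts)[!zero]))
    stop("total_mapped must be >= the column sums")
  out <- sweep(counts, 2, 100 / total_mapped, `*`)
  if (any(zero)) {
    warning("zero total mapped reads in sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    out[, zero] <- NA_real_
  }
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks use average ties; `rho` is the Pearson correlation of the ranks and
#' the two-sided p-value comes from the t approximation with `n - 2` degrees
#' of freedom. Missing values are removed pairwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3 usable pairs).
#' @return List with `rho`, `p`, `n` and (when undefined) `reason`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "fewer than 3 complete pairs"))
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "constant vector"))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, reason = NULL)
}

#' Per-taxon, per-region correlations with environmental drivers
#'
#' For every (taxon, region, variable) cell, sums the taxon's gene abundances
#' per sample within the region and Spearman-correlates the sums with the
#' environmental variable over the samples where both are available
#' (pairwise deletion). P-values are Benjamini-Hochberg adjusted across the
#' whole emitted grid. Cells with fewer than 3 usable samples are reported
#' as `NA` and counted in the `n_na_cells` attribute.
#'
#' @param table An `abundance_table`.
#' @param taxa Taxon labels to analyse; default all in the table.
#' @param variables Environmental variable (metadata column) names.
#' @return Data frame with columns `taxon`, `region`, `variable`, `rho`,
#'   `n`, `p`, `p_adj`.
#' @export
taxon_region_correlations <- function(table,
                                      taxa = unique(table$genes$taxon),
                                      variables = c("temperature", "NO3",
                                                    "PO4", "Fe")) {
  stopifnot(inherits(table, "abundance_table"))
  missing_vars <- setdiff(variables, names(table$samples))
  if (length(missing_vars))
    stop("schema error: missing sample metadata column(s): ",
         paste(missing_vars, collapse = ", "))
  regions <- unique(table$samples$region)
  grid <- expand.grid(taxon = taxa, region = regions, variable = variables,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    gene_idx <- which(table$genes$taxon == g$taxon)
    samp_idx <- which(table$samples$region == g$region)
    ab <- colSums(table$values[gene_idx, samp_idx, drop = FALSE])
    env <- table$samples[[g$variable]][samp_idx]
    r <- spearman_cor(ab, env)
    data.frame(taxon = g$taxon, region = g$region, variable = g$variable,
               rho = r$rho, n = r$n, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_na_cells") <- sum(is.na(out$rho))
  out
}

#' Median-of-ratios size factors
#'
#' The count normalization estimator popularized for RNA-seq differential
#' expression: the reference for each gene is its geometric mean across
#' samples (genes with any zero excluded); a sample's size factor is the
#' median over reference genes of `count / reference`.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param method `"ratio"` (all-nonzero reference genes) or `"poscounts"`
#'   (geometric mean over positive counts only, usable when every gene has a
#'   zero somewhere).
#' @return Positive per-sample size factors.
#' @export
size_factors <- function(counts, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (method == "ratio") {
    usable <- rowSums(counts == 0) == 0
    if (!any(usable))
      stop("normalization error: no gene has nonzero counts in every ",
           "sample; consider method = \"poscounts\"")
    logref <- rowMeans(log(counts[usable, , drop = FALSE]))
    sf <- apply(counts[usable, , drop = FALSE], 2, function(cnt)
      exp(stats::median(log(cnt) - logref)))
  } else {
    logref <- apply(counts, 1, function(cnt) {
      pos <- cnt > 0
      if (!any(pos)) NA_real_ else mean(log(cnt[pos]))
    })
    usable <- is.finite(logref)
    sf <- apply(counts[usable, , drop = FALSE], 2, function(cnt) {
      ratio <- log(cnt) - logref[usable]
      exp(stats::median(ratio[is.finite(ratio)]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("normalization error: non-positive size factor")
  sf
}

#' Per-gene fold change between two sample groups
#'
#' Ratio of mean size-factor-normalized counts (group A over group B) with a
#' pseudocount of 0.5 added to both means.
#'
#' @param counts Gene x sample count matrix.
#' @param group_a,group_b Disjoint, non-empty sets of column names or
#'   indices.
#' @param sf Optional precomputed size factors; computed with
#'   [size_factors()] when `NULL`.
#' @return Named per-gene fold changes.
#' @export
fold_change <- function(counts, group_a, group_b, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  (rowMeans(norm[, group_a, drop = FALSE]) + 0.5) /
    (rowMeans(norm[, group_b, drop = FALSE]) + 0.5)
}

#' Euphotic versus mesopelagic differential expression
#'
#' Splits samples at a depth boundary (euphotic `<= boundary_m`, mesopelagic
#' `> boundary_m`; 200 m by default), computes per gene the difference of
#' mean `log2(value + pseudocount)` between zones, and assesses it with a
#' seeded permutation test of the zone labels followed by Benjamini-Hochberg
#' correction across genes. A gene is called enriched in the zone with the
#' higher mean when its adjusted p-value falls below `alpha`.
#'
#' @param values Gene x sample matrix: normalized abundances (or raw counts
#'   with `normalize = TRUE`, which applies median-of-ratios size factors).
#' @param depths Per-sample depths in metres.
#' @param boundary_m Euphotic/mesopelagic boundary depth.
#' @param n_permutations Number of label permutations.
#' @param alpha BH-adjusted significance level.
#' @param seed Integer seed for the permutations.
#' @param pseudocount Added inside the log.
#' @param normalize Treat `values` as raw counts and normalize first.
#' @return Data frame with one row per gene: `gene`, `mean_euphotic`,
#'   `mean_mesopelagic` (mean log2 levels), `statistic` (euphotic minus
#'   mesopelagic), `p`, `p_adj`, `zone` (`"euphotic"`, `"mesopelagic"` or
#'   `NA` when not significant).
#' @export
depth_differential <- function(values, depths, boundary_m = 200,
                               n_permutations = 1000L, alpha = 0.05,
                               seed = 1L, pseudocount = 0.5,
                               normalize = FALSE) {
  values <- as.matrix(values)
  if (length(depths) != ncol(values))
    stop("one depth per sample required")
  eu <- depths <= boundary_m
  if (!any(eu) || all(eu))
    stop("configuration error: all samples fall on one side of the ",
         boundary_m, " m boundary")
  if (normalize) values <- sweep(values, 2, size_factors(values), `/`)
  logm <- log2(values + pseudocount)
  n_eu <- sum(eu); n_me <- sum(!eu); ns <- ncol(logm)
  contrast <- ifelse(eu, 1 / n_eu, -1 / n_me)
  obs <- as.numeric(logm %*% contrast)
  perm_w <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) contrast[sample.int(ns)],
           numeric(ns))
  })
  perm_stats <- logm %*% perm_w  # genes x permutations
  exceed <- rowSums(abs(perm_stats) >= abs(obs) - 1e-12)
  p <- (1 + exceed) / (n_permutations + 1)
  p_adj <- stats::p.adjust(p, method = "BH")
  zone <- ifelse(p_adj < alpha,
                 ifelse(obs > 0, "euphotic", "mesopelagic"), NA_character_)
  data.frame(gene = rownames(values) %||% as.character(seq_len(nrow(values))),
             mean_euphotic = rowMeans(logm[, eu, drop = FALSE]),
             mean_mesopelagic = rowMeans(logm[, !eu, drop = FALSE]),
             statistic = obs, p = p, p_adj = p_adj, zone = zone,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
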