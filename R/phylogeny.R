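#' Extract a domain region from a protein record
#'
#' Cuts a sequence to a domain hit's coordinates (1-based inclusive) ahead of
#' alignment and tree building; the record id is suffixed with the
#' coordinates so that two domain copies on one protein stay distinct.
#'
#' @param rec An ungapped `protein_record`.
#' @param hit A one-row data frame (or list) with `start` and `end`.
#' @return A `protein_record` covering `[start, end]`.
#' @export
extract_domain_region <- function(rec, hit) {
  start <- as.integer(hit$start[1]); end <- as.integer(hit$end[1])
  L <- nchar(rec$residues)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("coordinate error: hit [", start, ", ", end,
         "] outside sequence of length ", L)
  protein_record(paste0(rec$id, "_", start, "-", end),
                 substring(rec$residues, start, end),
                 rec$description, rec$taxon)
}

#' Drop sparsely occupied alignment columns
#'
#' Retains exactly the columns carrying at least `min_occupancy` non-gap
#' residues, the column rule used to clean domain alignments of terminal and
#' lineage-specific extensions before tree building. Row order is unchanged;
#' the operation is idempotent.
#'
#' @param aln An `aa_alignment`.
#' @param min_occupancy Minimum number of sequences with a residue in a
#'   retained column.
#' @return A filtered `aa_alignment`.
#' @export
filter_columns <- function(aln, min_occupancy = 10L) {
  m <- alignment_matrix(aln)
  keep <- colSums(m != "-") >= min_occupancy
  if (!any(keep))
    stop("empty-alignment error: no column has >= ", min_occupancy,
         " residues")
  alignment_from_matrix(m[, keep, drop = FALSE], aln)
}

#' Pairwise protein distance matrix
#'
#' Pairwise proportion of differing residues `p` with pairwise gap exclusion
#' (columns where either sequence is gapped are not scored; `X` counts as a
#' mismatch), optionally corrected for multiple substitutions:
#' `poisson` uses `d = -ln(1 - p)` and `kimura_protein` the protein
#' correction `d = -ln(1 - p - 0.2 p^2)`. Saturated pairs (log argument
#' <= 0) are capped at `max_distance`.
#'
#' @param aln An `aa_alignment` with at least 3 rows.
#' @param model Distance model.
#' @param max_distance Cap for saturated distances.
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @export
distance_matrix <- function(aln,
                            model = c("kimura_protein", "p_distance",
                                      "poisson"),
                            max_distance = 10) {
  model <- match.arg(model)
  if (length(aln$records) < 3L) stop("need at least 3 sequences")
  m <- alignment_matrix(aln)
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      scored <- !gap[i, ] & !gap[j, ]
      ns <- sum(scored)
      if (ns == 0L)
        stop("undefined-distance error: no scored columns between '",
             rownames(m)[i], "' and '", rownames(m)[j], "'")
      mism <- m[i, scored] != m[j, scored] |
        m[i, scored] == "X" | m[j, scored] == "X"
      p <- sum(mism) / ns
      dist <- switch(model,
        p_distance = p,
        poisson = { arg <- 1 - p
          if (arg <= 0) max_distance else min(-log(arg), max_distance) },
        kimura_protein = { arg <- 1 - p - 0.2 * p^2
          if (arg <= 0) max_distance else min(-log(arg), max_distance) })
      d[i, j] <- d[j, i] <- dist
    }
  }
  d
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("matrix error: distance matrix must be square")
  if (is.null(rownames(dm))) stop("matrix error: missing labels")
  if (max(abs(dm - t(dm))) > 1e-12)
    stop("matrix error: distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("matrix error: non-zero diagonal")
  if (any(dm < 0)) stop("matrix error: negative distances")
  invisible(dm)
}

fmt_len <- function(x) sprintf("%.17g", x)

#' Neighbor-Joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` is joined, with branch lengths
#' from the standard formulas. Negative branch lengths are clamped to zero
#' with the deficit transferred to the sister branch (path lengths
#' preserved); ties in Q are broken deterministically by the smallest pair
#' of representative labels in lexicographic order (each subtree is
#' represented by its smallest tip label), so the result does not depend on
#' the row order of the input matrix.
#'
#' @param dm Symmetric labeled distance matrix, `n >= 3`.
#' @return An unrooted `phylo` tree (see \pkg{ape}) with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  check_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(dm)
  nodes <- labels  # newick fragment per active node
  reprs <- labels  # smallest tip label in each active subtree
  d <- dm

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- max(0, lj + li); li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }

  while (length(nodes) > 3L) {
    nn <- length(nodes)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    ## among ties, the pair with the smallest representative labels
    qmin <- min(q)
    cand <- which(q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(reprs[cand[, 1]], reprs[cand[, 2]])
    hi <- pmax(reprs[cand[, 1]], reprs[cand[, 2]])
    pick <- order(lo, hi, method = "radix")[1]  # locale-independent
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    ll <- clamp_pair(li, lj)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_len(ll[1]),
                      nodes[j], fmt_len(ll[2]))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], merged)
    reprs <- c(reprs[keep], min(reprs[c(i, j)]))
    d <- d2
  }

  ## final trifurcation
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l12 <- clamp_pair(l1, l2); l1 <- l12[1]; l2 <- l12[2]
  l3 <- max(0, l3)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_len(l1),
                    nodes[2], fmt_len(l2), nodes[3], fmt_len(l3))
  ape::read.tree(text = newick)
}

## Canonical bipartition keys for the internal edges of an unrooted phylo.
## Each internal edge is keyed by the sorted tip labels on the side that
## excludes the reference tip (the alphabetically first label), so keys are
## rooting- and orientation-invariant.
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  root <- ntip + 1L
  ## tips under each internal node
  desc <- vector("list", ntip + phy$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- phy$tip.label[t]
  for (e in ape::postorder(phy)) {  # children visited before parents
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    if (child <= ntip || child == root) next
    side <- desc[[child]]
    if (length(side) < 2 || length(side) > ntip - 2) next  # trivial split
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, child)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-Joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times (seeded), rebuilds the tree per
#' replicate, and annotates each internal edge of the full-data tree with the
#' percentage of replicates containing the same bipartition. Replicates whose
#' distance matrix is degenerate (a pair with no scored columns) are skipped
#' with a warning and excluded from the denominator.
#'
#' @param aln An `aa_alignment`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param model Distance model, see [distance_matrix()].
#' @param seed Integer seed.
#' @param max_distance Cap for saturated distances.
#' @return The full-data `phylo` tree with integer support values (0-100) as
#'   internal node labels; the number of skipped replicates is attached as
#'   attribute `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L,
                              model = c("kimura_protein", "p_distance",
                                        "poisson"),
                              seed = 1L, max_distance = 10) {
  model <- match.arg(model)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  full <- neighbor_joining(distance_matrix(aln, model, max_distance))
  bip <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, length(bip$keys)), bip$keys)
  m <- alignment_matrix(aln)
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      rep_aln <- alignment_from_matrix(m[, cols, drop = FALSE], aln)
      tr <- tryCatch(
        neighbor_joining(distance_matrix(rep_aln, model, max_distance)),
        error = function(e) NULL)
      if (is.null(tr)) { n_skipped <- n_skipped + 1L; next }
      rk <- tree_bipartitions(tr)$keys
      hit <- bip$keys %in% rk
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (n_skipped > 0L)
    warning(n_skipped, " of ", n_replicates,
            " bootstrap replicates skipped (degenerate distances)")
  n_ok <- n_replicates - n_skipped
  support <- if (n_ok > 0) as.integer(round(100 * counts / n_ok)) else
    rep(NA_integer_, length(counts))
  ntip <- length(full$tip.label)
  node_label <- rep("", full$Nnode)
  node_label[bip$nodes - ntip] <- as.character(support)
  full$node.label <- node_label
  attr(full, "n_skipped") <- n_skipped
  full
}

#' Serialize a tree to Newick / parse Newick text
#'
#' Standard Newick with branch lengths; integer bootstrap supports travel as
#' internal node labels (e.g. `"(a:1,b:1)95:0.1"`).
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when given the text is also written there.
#' @return `to_newick`: the Newick string. `from_newick`: a `phylo`.
#' @export
to_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 17)
  if (!is.null(file)) writeLines(txt, file)
  txt
}

#' @rdname to_newick
#' @param text Newick string (or path to a file containing one).
#' @export
from_newick <- function(text) {
  txt <- if (file.exists(text) && !grepl("\\(", text)) readLines(text) else text
  txt <- paste(txt, collapse = "")
  ## locate an unbalanced parenthesis for the error message
  depth <- 0L; bad <- NA_integer_
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) { bad <- i; break }
  }
  if (depth != 0L)
    stop("parse error: unbalanced parenthesis",
         if (!is.na(bad)) paste0(" at position ", bad) else
           paste0(" (", depth, " unclosed)"))
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e)
    stop("parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("parse error: not a valid newick string")
  tr
}
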