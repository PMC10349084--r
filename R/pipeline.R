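#' Read and write abundance tables as TSV
#'
#' The abundance TSV carries one row per gene: `gene_id`, `taxon`, then one
#' numeric column per sample. The metadata TSV carries one row per sample
#' with columns `sample_id`, `station`, `depth`, `region`, `size_fraction`
#' and any environmental variables.
#'
#' @param abundance_path,meta_path Paths to the two TSV files.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(abundance_path, meta_path) {
  ab <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "taxon") %in% names(ab)))
    stop("schema error: abundance TSV must start with columns ",
         "'gene_id' and 'taxon'")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "station", "depth", "region")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop("schema error: missing sample metadata column(s): ",
         paste(missing, collapse = ", "))
  sample_cols <- setdiff(names(ab), c("gene_id", "taxon"))
  if (!setequal(sample_cols, meta$sample_id))
    stop("schema error: abundance sample columns do not match metadata ",
         "sample_id values")
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  values <- as.matrix(ab[, sample_cols, drop = FALSE])
  abundance_table(values, ab[, c("gene_id", "taxon")], meta)
}

#' @rdname read_abundance_tsv
#' @param table An `abundance_table`.
#' @return `write_abundance_tsv`: the paths, invisibly.
#' @export
write_abundance_tsv <- function(table, abundance_path, meta_path) {
  ab <- cbind(table$genes[, c("gene_id", "taxon")],
              as.data.frame(table$values, check.names = FALSE))
  utils::write.table(ab, abundance_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance_path, meta_path))
}

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  utils::modifyList(defaults, config)
}

log_msg <- function(...) message("[dlhscan] ", sprintf(...))

#' Run the DLH identification pipeline
#'
#' Reads candidate proteins, a domain profile and a motif bank, classifies
#' every record and writes a results TSV plus a summary; the counts
#' surviving each evidence filter (candidates, domain, cysteine pair,
#' motifs) are logged to stderr.
#'
#' @param config A list or YAML file path with elements `fasta`, `profile`,
#'   `motifs`, `out` (results TSV path) and optionally `min_motifs` (5),
#'   `require_order` (TRUE).
#' @return Invisibly, a list with `batch` (the [classify_batch()] result)
#'   and `stage_counts`.
#' @export
run_identify <- function(config) {
  cfg <- resolve_config(config, list(min_motifs = 5L, require_order = TRUE))
  for (f in c("fasta", "profile", "motifs", "out"))
    if (is.null(cfg[[f]])) stop("config error: missing field '", f, "'")
  records <- read_fasta(cfg$fasta)
  profile <- read_domain_profile(cfg$profile)
  motifs <- read_motif_bank(cfg$motifs)
  batch <- classify_batch(records, profile, motifs,
                          min_motifs = cfg$min_motifs,
                          require_order = cfg$require_order)
  res <- batch$results
  domain_pass <- vapply(res, function(r) nrow(r$domain_hits) >= 1L, NA)
  cys_pass <- domain_pass & vapply(res, function(r)
    has_canonical_pair(r$cys_hits, cfg$require_order), NA)
  motif_pass <- cys_pass & vapply(res, function(r)
    r$n_motifs_matched >= cfg$min_motifs, NA)
  stage_counts <- c(candidates = length(res), domain = sum(domain_pass),
                    cysteine_pair = sum(cys_pass), motifs = sum(motif_pass))
  log_msg("identify: %d candidates -> %d domain -> %d cysteine pair -> %d DLH",
          stage_counts[1], stage_counts[2], stage_counts[3], stage_counts[4])
  utils::write.table(as.data.frame(batch), cfg$out, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(batch = batch, stage_counts = stage_counts))
}

#' Run the phylogeny pipeline
#'
#' Reads an aligned FASTA, removes sparse columns, computes protein
#' distances, builds the Neighbor-Joining tree with bootstrap support and
#' writes Newick plus a distance-matrix TSV.
#'
#' @param config A list or YAML file path with `aln` (aligned FASTA),
#'   `out_tree` (Newick path) and optionally `min_occupancy` (10), `model`
#'   (`"kimura_protein"`), `bootstrap` (1000), `seed` (1), `out_dist`
#'   (distance TSV path).
#' @return Invisibly, a list with `tree` and `distances`.
#' @export
run_phylogeny <- function(config) {
  cfg <- resolve_config(config, list(min_occupancy = 10L,
                                     model = "kimura_protein",
                                     bootstrap = 1000L, seed = 1L))
  for (f in c("aln", "out_tree"))
    if (is.null(cfg[[f]])) stop("config error: missing field '", f, "'")
  aln <- read_fasta(cfg$aln, aligned = TRUE)
  log_msg("phylogeny: %d sequences x %d columns", length(aln$records),
          aln$length)
  aln <- filter_columns(aln, cfg$min_occupancy)
  log_msg("phylogeny: %d columns retained (occupancy >= %d)", aln$length,
          cfg$min_occupancy)
  dm <- distance_matrix(aln, cfg$model)
  tree <- bootstrap_support(aln, n_replicates = cfg$bootstrap,
                            model = cfg$model, seed = cfg$seed)
  to_newick(tree, file = cfg$out_tree)
  if (!is.null(cfg$out_dist))
    utils::write.table(dm, cfg$out_dist, sep = "\t", quote = FALSE,
                       col.names = NA)
  log_msg("phylogeny: wrote %s (%d leaves, %d bootstrap replicates)",
          cfg$out_tree, length(tree$tip.label), cfg$bootstrap)
  invisible(list(tree = tree, distances = dm))
}

#' Run the ecology pipeline
#'
#' Reads an abundance TSV plus sample metadata and runs the requested
#' analyses: per-taxon/per-region Spearman correlations with environmental
#' drivers, and/or euphotic-versus-mesopelagic differential expression.
#'
#' @param config A list or YAML file path with `abundance`, `meta`, and for
#'   correlations `out_correlations` plus optionally `taxa`, `variables`;
#'   for the depth contrast `out_depthdiff` plus optionally `boundary_m`
#'   (200), `n_permutations` (1000), `alpha` (0.05), `seed` (1).
#' @return Invisibly, a list with `correlations` and/or `depth_differential`.
#' @export
run_ecology <- function(config) {
  cfg <- resolve_config(config, list(boundary_m = 200, n_permutations = 1000L,
                                     alpha = 0.05, seed = 1L,
                                     variables = c("temperature", "NO3",
                                                   "PO4", "Fe")))
  for (f in c("abundance", "meta"))
    if (is.null(cfg[[f]])) stop("config error: missing field '", f, "'")
  table <- read_abundance_tsv(cfg$abundance, cfg$meta)
  out <- list()
  if (!is.null(cfg$out_correlations)) {
    taxa <- cfg$taxa %||% unique(table$genes$taxon)
    corr <- taxon_region_correlations(table, taxa = taxa,
                                      variables = cfg$variables)
    utils::write.table(corr, cfg$out_correlations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg("ecology: %d correlation cells (%d NA) -> %s", nrow(corr),
            attr(corr, "n_na_cells"), cfg$out_correlations)
    out$correlations <- corr
  }
  if (!is.null(cfg$out_depthdiff)) {
    dd <- depth_differential(table$values, table$samples$depth,
                             boundary_m = cfg$boundary_m,
                             n_permutations = cfg$n_permutations,
                             alpha = cfg$alpha, seed = cfg$seed)
    utils::write.table(dd, cfg$out_depthdiff, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg("ecology: %d/%d genes zone-enriched at alpha = %g -> %s",
            sum(!is.na(dd$zone)), nrow(dd), cfg$alpha, cfg$out_depthdiff)
    out$depth_differential <- dd
  }
  if (!length(out))
    stop("config error: set 'out_correlations' and/or 'out_depthdiff'")
  invisible(out)
}
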