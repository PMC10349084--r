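#' Synthetic racemase-domain consensus (stand-in)
#'
#' A fixed 160-residue synthetic consensus used by the data generator and
#' example profiles. It is a stand-in for the Asp/Glu/Hydantoin racemase
#' conserved domain, which is not redistributable here; it shares no sequence
#' with the real domain and is guaranteed to contain neither canonical
#' cysteine context.
#'
#' @return A single 160-character string.
#' @export
synthetic_racemase_consensus <- function() {
  paste0("TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY",
         "KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC",
         "LNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATAC")
}

#' Default planted motif consensus set
#'
#' Ten fixed synthetic motif consensus strings (widths 6-10) planted by
#' [generate_protein_sets()], mirroring the ten discriminative motifs that
#' characterize eukaryotic DMSP-lyase homologs.
#'
#' @return Character vector of length 10.
#' @export
default_motif_set <- function() {
  c("WHCRIDI", "NWYIVRGS", "EMGCEGMI", "TQEDPKIPR", "CNILQI",
    "SVFGDKSI", "SVVIGLPHN", "STMPNVATA", "MSCKTIKKY", "YIVDVPVM")
}

#' Generate a seed alignment of noised domain copies
#'
#' Independent copies of the domain consensus with per-site substitution
#' noise, returned as an (ungapped, equal-length) alignment suitable for
#' [build_domain_profile()].
#'
#' @param seed Integer seed.
#' @param n_seqs Number of copies (>= 5).
#' @param noise Per-site substitution probability.
#' @param consensus Domain consensus string.
#' @return An `aa_alignment`.
#' @export
generate_seed_alignment <- function(seed = 1L, n_seqs = 20L, noise = 0.05,
                                    consensus = synthetic_racemase_consensus()) {
  with_seed(seed, {
    aa_alignment(lapply(seq_len(n_seqs), function(i)
      protein_record(sprintf("seed_%02d", i), mutate_seq(consensus, noise),
                     taxon = "synthetic", aligned = TRUE)))
  })
}

#' Generate positive and decoy protein sets with planted structure
#'
#' Positives carry a noised copy of the synthetic racemase-domain consensus
#' with an `[D/N]CGF` context and, downstream at a configurable spacing, an
#' `ECT[E/Q]` context planted inside it, plus each motif of `motif_set` with
#' the configured penetrance in the C-terminal flank. Decoys carry the noised
#' domain but are scrubbed of both canonical contexts and carry no motifs —
#' the bacterial-like homologs that the cysteine and motif criteria exclude.
#' A fraction of positives can carry a second (context-free) domain copy to
#' emulate racemase-domain duplication.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_pos,n_neg Number of positives / decoys.
#' @param motif_set Character vector of motif consensi (widths 4-15).
#' @param motif_penetrance Probability that each motif is planted in a
#'   positive.
#' @param domain_consensus Domain consensus string.
#' @param domain_noise Per-site substitution probability applied to each
#'   domain copy.
#' @param context_spacing Integer range (min, max) of residues between the
#'   N-site and C-site cysteines.
#' @param duplication_frac Fraction of positives receiving a second domain
#'   copy.
#' @param taxa Taxon labels sampled for the positives.
#' @return List with `positives`, `decoys` (lists of `protein_record`s) and
#'   `manifest`: a data frame of planted elements (record, element, start,
#'   end, detail).
#' @export
generate_protein_sets <- function(seed = 1L, n_pos = 100L, n_neg = 100L,
                                  motif_set = default_motif_set(),
                                  motif_penetrance = 1.0,
                                  domain_consensus = synthetic_racemase_consensus(),
                                  domain_noise = 0.05,
                                  context_spacing = c(80L, 130L),
                                  duplication_frac = 0,
                                  taxa = c("Dinophyceae", "Haptophyceae",
                                           "Diatoms", "Chlorophyta")) {
  if (any(nchar(motif_set) < 4L | nchar(motif_set) > 15L))
    stop("spec error: motif widths must lie in [4, 15]")
  dlen <- nchar(domain_consensus)
  if (max(context_spacing) + 25L > dlen)
    stop("spec error: context spacing does not fit in the domain")
  with_seed(seed, {
    manifest <- list()
    note <- function(rec, el, start, end, detail = "") {
      manifest[[length(manifest) + 1L]] <<-
        data.frame(record = rec, element = el, start = start, end = end,
                   detail = detail, stringsAsFactors = FALSE)
    }

    planted_domain <- function(rec_id, with_contexts) {
      dom <- mutate_seq(domain_consensus, domain_noise)
      if (!with_contexts) return(scrub_contexts(dom))
      chars <- strsplit(dom, "", fixed = TRUE)[[1]]
      p_n <- sample(5:15, 1)
      spacing <- sample(context_spacing[1]:context_spacing[2], 1)
      p_c <- p_n + spacing
      n_ctx <- sample(c("DCGF", "NCGF"), 1)
      c_ctx <- sample(c("ECTE", "ECTQ"), 1)
      chars[(p_n - 1L):(p_n + 2L)] <- strsplit(n_ctx, "")[[1]]
      chars[(p_c - 1L):(p_c + 2L)] <- strsplit(c_ctx, "")[[1]]
      attr_pos <- c(p_n, p_c)
      out <- paste(chars, collapse = "")
      attr(out, "cys") <- attr_pos
      out
    }

    ## duplication planted as an exact count, not per-record coin flips
    dup_set <- if (duplication_frac > 0)
      sample.int(n_pos, round(duplication_frac * n_pos)) else integer(0)

    build_positive <- function(i) {
      id <- sprintf("pos_%03d", i)
      taxon <- sample(taxa, 1)
      parts <- character(0); cursor <- 0L
      add <- function(piece, el = NULL, detail = "") {
        parts <<- c(parts, piece)
        if (!is.null(el))
          note(id, el, cursor + 1L, cursor + nchar(piece), detail)
        cursor <<- cursor + nchar(piece)
      }
      add(random_aa(sample(20:60, 1)))
      dom <- planted_domain(id, with_contexts = TRUE)
      cys <- attr(dom, "cys")
      dom_start <- cursor + 1L
      add(dom, "domain", "primary")
      note(id, "n_site", dom_start + cys[1] - 1L, dom_start + cys[1] - 1L)
      note(id, "c_site", dom_start + cys[2] - 1L, dom_start + cys[2] - 1L)
      if (i %in% dup_set) {
        add(random_aa(sample(10:30, 1)))
        add(planted_domain(id, with_contexts = FALSE), "domain", "duplicate")
      }
      add(random_aa(sample(10:25, 1)))
      for (k in seq_along(motif_set)) {
        if (stats::runif(1) < motif_penetrance) {
          add(random_aa(sample(2:8, 1)))
          add(motif_set[k], "motif", as.character(k))
        }
      }
      add(random_aa(sample(20:60, 1)))
      protein_record(id, paste(parts, collapse = ""),
                     description = paste0("synthetic positive taxon=", taxon),
                     taxon = taxon)
    }

    build_decoy <- function(i) {
      id <- sprintf("neg_%03d", i)
      s <- paste0(random_aa(sample(20:60, 1)),
                  planted_domain(id, with_contexts = FALSE),
                  random_aa(sample(120:200, 1)))
      protein_record(id, scrub_contexts(s),
                     description = "synthetic bacterial-like decoy taxon=Bacteria",
                     taxon = "Bacteria")
    }

    positives <- lapply(seq_len(n_pos), build_positive)
    decoys <- lapply(seq_len(n_neg), build_decoy)
    manifest <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(record = character(0), element = character(0),
                 start = integer(0), end = integer(0),
                 detail = character(0))
    list(positives = positives, decoys = decoys, manifest = manifest)
  })
}

#' Generate a motif-discovery benchmark set
#'
#' Positives are random sequences with a single motif consensus planted at a
#' random interior position with probability `penetrance`; controls are pure
#' random sequences of the same length distribution.
#'
#' @param seed Integer seed.
#' @param n_pos,n_ctl Set sizes.
#' @param length Sequence length.
#' @param motif Planted consensus (width 4-15).
#' @param penetrance Fraction of positives carrying the motif.
#' @return List with `positives`, `controls` and `manifest` (record,
#'   start, end of each planted occurrence).
#' @export
generate_motif_sets <- function(seed = 1L, n_pos = 100L, n_ctl = 100L,
                                length = 120L, motif = "WDCGFHKY",
                                penetrance = 1.0) {
  w <- nchar(motif)
  if (w < 4L || w > 15L) stop("spec error: motif width must lie in [4, 15]")
  if (w >= length) stop("spec error: motif longer than sequence")
  with_seed(seed, {
    manifest <- list()
    positives <- lapply(seq_len(n_pos), function(i) {
      id <- sprintf("pos_%03d", i)
      s <- random_aa(length)
      if (stats::runif(1) < penetrance) {
        start <- sample(seq_len(length - w + 1L), 1)
        substr(s, start, start + w - 1L) <- motif
        manifest[[length(manifest) + 1L]] <<-
          data.frame(record = id, start = start, end = start + w - 1L,
                     stringsAsFactors = FALSE)
      }
      protein_record(id, s, taxon = "synthetic")
    })
    controls <- lapply(seq_len(n_ctl), function(i)
      protein_record(sprintf("ctl_%03d", i), random_aa(length),
                     taxon = "synthetic"))
    manifest <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(record = character(0), start = integer(0), end = integer(0))
    list(positives = positives, controls = controls, manifest = manifest)
  })
}

## Evolve a sequence down a phylo tree: per branch, each site substitutes
## with probability min(branch length, 0.95).
evolve_along_tree <- function(tree, root_seq) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root_seq
  for (e in rev(ape::postorder(tree))) {  # parents before children
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    rate <- min(tree$edge.length[e], 0.95)
    seqs[[child]] <- mutate_seq(seqs[[parent]], rate)
  }
  out <- seqs[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}

#' Generate a protein family alignment along a known tree
#'
#' `design = "random"` evolves a random root sequence along a random
#' unrooted binary tree with uniform branch lengths (per-branch, per-site
#' substitution probability equal to the branch length). `design =
#' "two_clade"` builds two clades separated by a fixed number of diagnostic
#' substitutions, giving a single strongly supported internal structure for
#' bootstrap checks.
#'
#' @param seed Integer seed.
#' @param n_taxa Number of leaves.
#' @param seq_length Alignment length (no gaps are introduced).
#' @param branch_range Range of branch lengths for the random design.
#' @param design `"random"` or `"two_clade"`.
#' @param n_fixed_diff Diagnostic differences between clades (two-clade
#'   design).
#' @param within_noise Per-site substitution probability within clades
#'   (two-clade design).
#' @return List with `alignment` (an `aa_alignment`) and `tree` (the
#'   generating `phylo`, unrooted).
#' @export
generate_family_alignment <- function(seed = 1L, n_taxa = 12L,
                                      seq_length = 200L,
                                      branch_range = c(0.02, 0.15),
                                      design = c("random", "two_clade"),
                                      n_fixed_diff = 100L,
                                      within_noise = 0.01) {
  design <- match.arg(design)
  with_seed(seed, {
    if (design == "random") {
      tree <- ape::rtree(n_taxa, rooted = FALSE,
                         br = function(n) stats::runif(n, branch_range[1],
                                                       branch_range[2]))
      tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
      root_seq <- random_aa(seq_length)
      seqs <- evolve_along_tree(tree, root_seq)
      recs <- lapply(names(seqs), function(nm)
        protein_record(nm, seqs[[nm]], taxon = "synthetic"))
      list(alignment = aa_alignment(recs), tree = tree)
    } else {
      if (n_fixed_diff >= seq_length)
        stop("n_fixed_diff must be smaller than seq_length")
      half <- n_taxa %/% 2
      base_a <- random_aa(seq_length)
      chars <- strsplit(base_a, "", fixed = TRUE)[[1]]
      diff_sites <- sample(seq_length, n_fixed_diff)
      for (i in diff_sites) chars[i] <- sample(setdiff(AA20, chars[i]), 1)
      base_b <- paste(chars, collapse = "")
      recs <- c(
        lapply(seq_len(half), function(i)
          protein_record(sprintf("a%02d", i), mutate_seq(base_a, within_noise),
                         taxon = "cladeA")),
        lapply(seq_len(n_taxa - half), function(i)
          protein_record(sprintf("b%02d", i), mutate_seq(base_b, within_noise),
                         taxon = "cladeB")))
      newick <- sprintf("(%s,(%s):0.2);",
                        paste(sprintf("a%02d:0.01", seq_len(half)),
                              collapse = ","),
                        paste(sprintf("b%02d:0.01", seq_len(n_taxa - half)),
                              collapse = ","))
      list(alignment = aa_alignment(recs),
           tree = ape::read.tree(text = newick))
    }
  })
}

#' Generate an abundance/expression dataset with known structure
#'
#' Emulates a station-by-depth metatranscriptome survey. Per region, each
#' taxon's per-sample total abundance is linked to one environmental
#' variable through a Gaussian copula at a target Spearman correlation
#' (latent Pearson correlation `2 sin(pi rho / 6)`), then split across the
#' taxon's genes. Raw counts are drawn negative-binomially around
#' zone-specific means implementing a per-gene euphotic/mesopelagic fold
#' -change map, so that depth-differential expression and correlation
#' analyses can be scored against known truth.
#'
#' @param seed Integer seed.
#' @param stations Number of stations.
#' @param depths Depth levels (m) sampled at every station.
#' @param n_regions Number of oceanic regions (stations split evenly).
#' @param taxa Taxon labels.
#' @param genes_per_taxon Genes per taxon.
#' @param target_rho Data frame with columns `taxon`, `region`, `variable`,
#'   `rho`, or `NULL` for no planted correlation.
#' @param variables Environmental variable names generated for every sample.
#' @param n_de_meso,n_de_eu Number of genes planted as mesopelagic- /
#'   euphotic-enriched (taken from the start of the gene list).
#' @param de_fold Planted fold change between zones.
#' @param boundary_m Zone boundary (m).
#' @param base_mean Mean count scale.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @return List with `table` (an [abundance_table()] of percent-of-mapped
#'   -reads values), `counts` (gene x sample integer matrix), `meta`
#'   (sample metadata), and `manifest` (planted truths: `de_genes`,
#'   `target_rho`).
#' @export
generate_abundance_dataset <- function(seed = 1L, stations = 10L,
                                       depths = c(20, 60, 100, 150, 250, 400),
                                       n_regions = 2L,
                                       taxa = c("Dinophyceae", "Haptophyceae",
                                                "Diatoms"),
                                       genes_per_taxon = 8L,
                                       target_rho = NULL,
                                       variables = c("temperature", "NO3",
                                                     "PO4", "Fe"),
                                       n_de_meso = 4L, n_de_eu = 16L,
                                       de_fold = 8, boundary_m = 200,
                                       base_mean = 200, dispersion = 0.2) {
  if (!is.null(target_rho) && any(abs(target_rho$rho) > 1))
    stop("spec error: |target rho| must be <= 1")
  with_seed(seed, {
    n_samples <- stations * length(depths)
    meta <- data.frame(
      sample_id = sprintf("S%02d_D%04d", rep(seq_len(stations),
                                             each = length(depths)),
                          rep(round(depths), stations)),
      station = sprintf("st%02d", rep(seq_len(stations),
                                      each = length(depths))),
      depth = rep(depths, stations),
      region = sprintf("region%d",
                       rep(ceiling(seq_len(stations) / (stations / n_regions)),
                           each = length(depths))),
      size_fraction = "0.8-2000",
      stringsAsFactors = FALSE)
    ## latent standard normals per variable, shared across taxa
    latent <- matrix(stats::rnorm(n_samples * length(variables)),
                     ncol = length(variables),
                     dimnames = list(NULL, variables))
    env_scale <- list(temperature = function(z) 15 + 6 * z,
                      NO3 = function(z) exp(1 + 0.8 * z),
                      PO4 = function(z) exp(-1 + 0.5 * z),
                      Fe = function(z) exp(-3 + 0.6 * z))
    for (v in variables) {
      f <- env_scale[[v]] %||% function(z) z
      meta[[v]] <- f(latent[, v])
    }

    genes <- data.frame(
      gene_id = sprintf("%s_g%02d", rep(taxa, each = genes_per_taxon),
                        rep(seq_len(genes_per_taxon), length(taxa))),
      taxon = rep(taxa, each = genes_per_taxon),
      stringsAsFactors = FALSE)
    n_genes <- nrow(genes)

    ## per-taxon latent abundance, copula-linked to its target variable
    taxon_latent <- matrix(stats::rnorm(n_samples * length(taxa)),
                           ncol = length(taxa), dimnames = list(NULL, taxa))
    if (!is.null(target_rho)) {
      for (k in seq_len(nrow(target_rho))) {
        tr <- target_rho[k, ]
        idx <- which(meta$region == tr$region)
        r_p <- 2 * sin(pi * tr$rho / 6)
        z_env <- latent[idx, tr$variable]
        taxon_latent[idx, tr$taxon] <-
          r_p * z_env + sqrt(1 - r_p^2) * stats::rnorm(length(idx))
      }
    }

    ## zone-specific gene means implementing the fold-change map
    de_genes <- list(
      mesopelagic = genes$gene_id[seq_len(n_de_meso)],
      euphotic = if (n_de_eu > 0)
        genes$gene_id[(n_de_meso + 1L):(n_de_meso + n_de_eu)] else character(0))
    eu <- meta$depth <= boundary_m
    base_mu <- exp(stats::rnorm(n_genes, log(base_mean), 0.4))
    mu <- matrix(base_mu, nrow = n_genes, ncol = n_samples)
    mu[genes$gene_id %in% de_genes$mesopelagic, eu] <-
      mu[genes$gene_id %in% de_genes$mesopelagic, eu] / de_fold
    mu[genes$gene_id %in% de_genes$euphotic, !eu] <-
      mu[genes$gene_id %in% de_genes$euphotic, !eu] / de_fold
    ## taxon abundance modulation implementing the copula link; only taxa
    ## with a correlation target are modulated (the latent field exists to
    ## carry that link, not to add unrelated noise)
    for (t in intersect(taxa, target_rho$taxon)) {
      g_idx <- genes$taxon == t
      mu[g_idx, ] <- mu[g_idx, , drop = FALSE] *
        rep(exp(taxon_latent[, t]), each = sum(g_idx))
    }
    counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                    mu = as.vector(mu),
                                    size = 1 / dispersion),
                     nrow = n_genes,
                     dimnames = list(genes$gene_id, meta$sample_id))
    ## library size independent of the planted signal (mild per-sample noise)
    total_mapped <- pmax(colSums(counts),
                         round(stats::rlnorm(n_samples, log(2e6), 0.1)))
    values <- percent_mapped_reads(counts, total_mapped)
    list(table = abundance_table(values, genes, meta),
         counts = counts, meta = meta,
         manifest = list(de_genes = de_genes, de_fold = de_fold,
                         boundary_m = boundary_m, target_rho = target_rho,
                         total_mapped = total_mapped))
  })
}
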