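#' Build a position-specific racemase-domain profile
#'
#' Constructs an ungapped position-specific scoring profile from a seed
#' alignment of domain sequences, as an offline stand-in for a conserved
#' domain database search against the Asp/Glu/Hydantoin racemase superfamily
#' (cl00518). Profile columns are the alignment columns with at least 50%
#' residue occupancy; per-column log-odds use gap-excluded residue
#' frequencies with pseudocount 0.1 over a uniform background. The match
#' threshold is calibrated on a decoy set: the `1 - fpr` quantile of the
#' decoys' best-hit scores, tie-aware (the smallest score matched by at most
#' a fraction `fpr` of decoys).
#'
#' @param seed_alignment An [aa_alignment()] of at least 5 domain sequences.
#' @param decoy_set Non-empty list of `protein_record`s without the domain.
#' @param fpr Target false-positive rate for the decoy calibration.
#' @param gap_penalty Bit penalty per profile column left uncovered when a
#'   query is shorter than the profile.
#' @param name Profile name.
#' @return An object of class `domain_profile` with `length`, `log_odds`
#'   (length x 20), `threshold`, `gap_penalty` and `consensus`.
#' @export
build_domain_profile <- function(seed_alignment, decoy_set, fpr = 0.01,
                                 gap_penalty = 2,
                                 name = "Asp/Glu/Hydantoin racemase (synthetic profile)") {
  if (!inherits(seed_alignment, "aa_alignment"))
    stop("seed_alignment must be an aa_alignment")
  if (length(seed_alignment$records) < 5L)
    stop("insufficient-seed error: need at least 5 seed sequences")
  if (!length(decoy_set)) stop("decoy_set must be non-empty")

  m <- alignment_matrix(seed_alignment)
  occupancy <- colSums(m != "-")
  keep <- which(occupancy >= 0.5 * nrow(m))
  if (length(keep) < 50L)
    stop("profile too short: ", length(keep),
         " columns with >=50% occupancy (need >= 50)")
  counts <- t(apply(m[, keep, drop = FALSE], 2, function(col)
    table(factor(col[col %in% AA20], levels = AA20))))
  freqs <- (counts + 0.1) / (rowSums(counts) + 0.1 * 20)
  log_odds <- log2(freqs / (1 / 20))
  colnames(log_odds) <- AA20
  consensus <- paste(AA20[apply(counts, 1, which.max)], collapse = "")

  profile <- structure(list(name = name, length = length(keep),
                            log_odds = log_odds, gap_penalty = gap_penalty,
                            threshold = Inf, consensus = consensus,
                            fpr = fpr),
                       class = "domain_profile")
  best <- vapply(decoy_set, function(r) best_domain_score(r, profile),
                 numeric(1))
  profile$threshold <- calibrate_threshold(best, fpr)
  profile
}

## Smallest observed score v with #(scores >= v) <= fpr * n (hits are
## score >= threshold, so ties at the quantile must fall below it); when
## even the maximum is too common, just above the maximum.
calibrate_threshold <- function(scores, fpr) {
  vals <- sort(unique(scores))
  n_ge <- length(scores) - findInterval(vals - 1e-12, sort(scores))
  ok <- vals[n_ge <= fpr * length(scores)]
  if (length(ok)) min(ok) else max(scores) + 1e-6
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %s: %d columns, threshold %.2f bits (fpr %.3g)\n",
              x$name, x$length, x$threshold, x$fpr))
  invisible(x)
}

## All window scores of a profile along an ungapped sequence. For sequences
## shorter than the profile, the sequence is slid along the profile instead
## and uncovered profile columns are charged gap_penalty bits each.
profile_window_scores <- function(enc, profile) {
  plen <- profile$length
  L <- length(enc)
  if (L >= plen) {
    score_windows(window_matrix(enc, plen), profile$log_odds)
  } else {
    n_off <- plen - L + 1L
    vapply(seq_len(n_off), function(off) {
      mat <- profile$log_odds[off:(off + L - 1L), , drop = FALSE]
      vals <- mat[cbind(seq_len(L), enc)]
      vals[is.na(vals)] <- 0
      sum(vals) - profile$gap_penalty * (plen - L)
    }, numeric(1))
  }
}

best_domain_score <- function(rec, profile) {
  enc <- encode_seq(gsub("-", "", residues_of(rec), fixed = TRUE))
  max(profile_window_scores(enc, profile))
}

#' Scan a sequence for racemase-domain hits
#'
#' Slides the ungapped profile along the sequence, reports windows scoring at
#' or above the calibrated threshold, and merges overlapping candidates
#' keeping the higher-scoring one.
#'
#' @param rec A `protein_record` or string; gaps are removed.
#' @param profile A `domain_profile`.
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `score` (bits), ordered by `start`; zero rows when nothing passes.
#' @export
scan_domain <- function(rec, profile) {
  s <- gsub("-", "", residues_of(rec), fixed = TRUE)
  enc <- encode_seq(s)
  L <- length(enc)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0))
  if (L < profile$length) {
    sc <- max(profile_window_scores(enc, profile))
    if (sc < profile$threshold) return(empty)
    return(data.frame(start = 1L, end = L, score = sc))
  }
  sc <- profile_window_scores(enc, profile)
  cand <- which(sc >= profile$threshold)
  if (!length(cand)) return(empty)
  ## greedy selection by score keeps the higher of any overlapping pair
  ord <- cand[order(-sc[cand], cand)]
  taken <- logical(L)
  hits <- list()
  for (st in ord) {
    en <- st + profile$length - 1L
    if (any(taken[st:en])) next
    taken[st:en] <- TRUE
    hits[[length(hits) + 1L]] <- data.frame(start = st, end = en,
                                            score = sc[st])
  }
  out <- do.call(rbind, hits)
  out[order(out$start), , drop = FALSE]
}

#' Classify a protein as a putative DMSP-lyase homolog
#'
#' A sequence is called a DLH when all three evidence classes are present:
#' at least one racemase-domain profile hit, the canonical cysteine pair
#' (`[D/N]CGF` upstream of `ECT[E/Q]`), and at least `min_motifs` distinct
#' motifs from the bank. All evidence is retained in the result regardless of
#' the verdict; two or more non-overlapping domain hits raise the domain
#' duplication flag.
#'
#' @param rec A `protein_record`.
#' @param profile A `domain_profile`.
#' @param motifs List of `motif_model`s.
#' @param min_motifs Minimum number of distinct matched motifs.
#' @param require_order Passed to [has_canonical_pair()].
#' @return An object of class `dlh_classification` with fields `record_id`,
#'   `taxon`, `is_dlh`, `domain_hits`, `cys_hits`, `motif_ids_matched`,
#'   `n_motifs_matched`, `duplication`.
#' @export
classify_dlh <- function(rec, profile, motifs, min_motifs = 5L,
                         require_order = TRUE) {
  ungapped <- degap(rec)
  domain_hits <- scan_domain(ungapped, profile)
  cys_hits <- find_cysteine_contexts(ungapped)
  motif_hits <- scan_motifs(ungapped, motifs)
  ids <- sort(unique(motif_hits$motif_id))
  res <- list(record_id = rec$id, taxon = rec$taxon,
              is_dlh = nrow(domain_hits) >= 1L &&
                has_canonical_pair(cys_hits, require_order) &&
                length(ids) >= min_motifs,
              domain_hits = domain_hits, cys_hits = cys_hits,
              motif_ids_matched = ids, n_motifs_matched = length(ids),
              duplication = nrow(domain_hits) >= 2L)
  class(res) <- "dlh_classification"
  res
}

#' @export
print.dlh_classification <- function(x, ...) {
  cat(sprintf("<dlh_classification> %s: %s (domain hits %d, cys pair %s, motifs %d)%s\n",
              x$record_id, if (x$is_dlh) "DLH" else "not a DLH",
              nrow(x$domain_hits),
              if (has_canonical_pair(x$cys_hits)) "yes" else "no",
              x$n_motifs_matched,
              if (x$duplication) " [domain duplication]" else ""))
  invisible(x)
}

#' Classify a batch of proteins and summarize
#'
#' @param records List of `protein_record`s with unique ids.
#' @inheritParams classify_dlh
#' @return A list of class `dlh_batch`: `results` (one `dlh_classification`
#'   per record) and `summary` with `n_input`, `n_dlh`, `per_taxon` (DLH
#'   counts per taxon label) and `duplication_fraction` among DLHs (`NA`
#'   when no DLH was found).
#' @export
classify_batch <- function(records, profile, motifs, min_motifs = 5L,
                           require_order = TRUE) {
  if (!length(records)) stop("empty-input error: no records")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("input error: duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  results <- lapply(records, classify_dlh, profile = profile, motifs = motifs,
                    min_motifs = min_motifs, require_order = require_order)
  is_dlh <- vapply(results, `[[`, NA, "is_dlh")
  dup <- vapply(results, `[[`, NA, "duplication")
  taxa <- vapply(results, `[[`, "", "taxon")
  per_taxon <- if (any(is_dlh)) table(taxa[is_dlh]) else
    table(factor(character(0)))
  summary <- list(
    n_input = length(records),
    n_dlh = sum(is_dlh),
    per_taxon = per_taxon,
    duplication_fraction = if (any(is_dlh)) mean(dup[is_dlh]) else NA_real_)
  structure(list(results = results, summary = summary), class = "dlh_batch")
}

#' @export
print.dlh_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dlh_batch> %d records, %d DLHs", s$n_input, s$n_dlh))
  if (!is.na(s$duplication_fraction))
    cat(sprintf(", domain duplication in %.1f%% of DLHs",
                100 * s$duplication_fraction))
  cat("\n")
  if (length(s$per_taxon)) {
    cat("DLHs per taxon:\n")
    print(s$per_taxon)
  }
  invisible(x)
}

#' Batch results as a data frame
#'
#' @param x A `dlh_batch`.
#' @param ... Unused.
#' @return One row per record: id, taxon, verdict, best domain score, number
#'   of domain hits, cysteine positions, matched motif ids, duplication flag.
#' @export
as.data.frame.dlh_batch <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    n_pos <- r$cys_hits$c_position[r$cys_hits$site == "N_SITE"]
    c_pos <- r$cys_hits$c_position[r$cys_hits$site == "C_SITE"]
    data.frame(
      record_id = r$record_id, taxon = r$taxon, is_dlh = r$is_dlh,
      n_domain_hits = nrow(r$domain_hits),
      best_domain_score = if (nrow(r$domain_hits)) max(r$domain_hits$score)
                          else NA_real_,
      n_site_positions = paste(n_pos, collapse = ","),
      c_site_positions = paste(c_pos, collapse = ","),
      motif_ids = paste(r$motif_ids_matched, collapse = ","),
      n_motifs_matched = r$n_motifs_matched,
      duplication = r$duplication,
      stringsAsFactors = FALSE)
  }))
}

#' Write / read a domain profile as TSV
#'
#' Header comment lines carry the name, threshold, gap penalty and target
#' false-positive rate; the body is one row per profile column with 20
#' log-odds values.
#'
#' @param profile A `domain_profile`.
#' @param path File path.
#' @return `path` invisibly / a `domain_profile`.
#' @export
write_domain_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dlhscan domain profile"),
               sprintf("# name\t%s", profile$name),
               sprintf("# threshold\t%.10g", profile$threshold),
               sprintf("# gap_penalty\t%.10g", profile$gap_penalty),
               sprintf("# fpr\t%.10g", profile$fpr),
               paste(c("position", AA20), collapse = "\t")), con)
  for (i in seq_len(profile$length))
    writeLines(paste(c(i, sprintf("%.10g", profile$log_odds[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_domain_profile
#' @export
read_domain_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  get_meta <- function(key) {
    l <- meta[grepl(paste0("^# ", key, "\t"), meta)]
    if (!length(l)) return(NA)
    strsplit(l, "\t")[[1]][2]
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1]  # drop header row
  log_odds <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, "\t")[[1]][-1])))
  colnames(log_odds) <- AA20
  consensus <- paste(AA20[apply(log_odds, 1, which.max)], collapse = "")
  structure(list(name = get_meta("name"), length = nrow(log_odds),
                 log_odds = log_odds,
                 gap_penalty = as.numeric(get_meta("gap_penalty")),
                 threshold = as.numeric(get_meta("threshold")),
                 consensus = consensus,
                 fpr = as.numeric(get_meta("fpr"))),
            class = "domain_profile")
}
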