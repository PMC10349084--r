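#' Hold-out Fisher significance for a discriminative motif
#'
#' One-sided Fisher exact p-value (hypergeometric tail) for enrichment of
#' motif-carrying sequences among positives versus controls, Bonferroni-scaled
#' by the number of candidate seeds tested to give an E-value-like score.
#'
#' @param k_pos,n_pos Matched / total positive sequences.
#' @param k_neg,n_neg Matched / total control sequences.
#' @param n_tested Number of candidate seeds tested (>= 1).
#' @return `p * n_tested`, bounded below by the smallest positive double.
#' @export
motif_significance <- function(k_pos, n_pos, k_neg, n_neg, n_tested = 1L) {
  vals <- c(k_pos, n_pos, k_neg, n_neg, n_tested)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("parameter error: counts must be non-negative integers")
  if (k_pos > n_pos || k_neg > n_neg)
    stop("parameter error: k cannot exceed n")
  if (n_tested < 1) stop("parameter error: n_tested must be >= 1")
  ## P(X >= k_pos), X ~ Hypergeom(matched, unmatched, drawn = n_pos)
  p <- stats::phyper(k_pos - 1, k_pos + k_neg,
                     n_pos + n_neg - k_pos - k_neg, n_pos,
                     lower.tail = FALSE)
  max(p, .Machine$double.xmin) * n_tested
}

new_motif_model <- function(id, counts, background, threshold, significance,
                            nsites) {
  colnames(counts) <- AA20
  freqs <- (counts + 0.1) / (rowSums(counts) + 0.1 * 20)
  log_odds <- log2(sweep(freqs, 2, background, `/`))
  consensus <- paste(AA20[apply(counts, 1, which.max)], collapse = "")
  structure(list(id = id, width = nrow(counts), counts = counts,
                 log_odds = log_odds, background = background,
                 threshold = threshold, significance = significance,
                 nsites = nsites, consensus = consensus),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> #%d width %d consensus %s  E = %.3g  (%d sites)\n",
              x$id, x$width, x$consensus, x$significance, x$nsites))
  invisible(x)
}

## Count matrix under the zero-or-one occurrence model: each sequence
## contributes its best match to the seed k-mer only when that match is an
## exact occurrence; sequences without the seed contribute zero occurrences.
## Returns the counts plus the number of contributing sequences.
seed_counts <- function(winmats, seed_enc) {
  w <- length(seed_enc)
  counts <- matrix(0, nrow = w, ncol = 20)
  nsites <- 0L
  for (wm in winmats) {
    if (is.null(wm)) next
    hits <- colSums(wm == seed_enc, na.rm = TRUE)
    best <- which.max(hits)
    if (hits[best] < w) next  # no exact occurrence in this sequence
    col <- wm[, best]
    counts[cbind(seq_len(w), col)] <- counts[cbind(seq_len(w), col)] + 1
    nsites <- nsites + 1L
  }
  list(counts = counts, nsites = nsites)
}

## Best-window PWM score per sequence (-Inf for sequences shorter than w).
best_scores <- function(winmats, mat) {
  vapply(winmats, function(wm) {
    if (is.null(wm)) return(-Inf)
    max(score_windows(wm, mat))
  }, numeric(1))
}

## Match threshold maximizing training-set discrimination: the score of the
## motif's own training occurrences when that clears every training-control
## best score (maximum sensitivity at zero training false-positive rate),
## else just above the best control score. Thresholds below the control
## maximum are dominated: they admit training false positives for no gain
## in occurrence sensitivity under the zero-or-one model.
discriminative_threshold <- function(occ_score, scores_neg) {
  floor_v <- suppressWarnings(max(scores_neg[is.finite(scores_neg)]))
  if (!is.finite(floor_v)) return(occ_score - 1e-9)
  if (occ_score > floor_v) occ_score - 1e-9 else floor_v + 1e-6
}

#' Discover discriminative sequence motifs
#'
#' Finds ungapped amino-acid motifs (widths 4-15) that separate a positive
#' sequence set from a control set, in the spirit of discriminative motif
#' discovery tools. The algorithm is deterministic given `seed`:
#'
#' 1. positives and controls are each split into training and hold-out halves
#'    by a seeded shuffle;
#' 2. for every width, each w-mer occurring in at least 20% of training
#'    positives becomes a candidate seed;
#' 3. a position weight matrix is built from each seed's best match per
#'    training positive under the zero-or-one occurrence model (a sequence
#'    contributes its best-matching window when that window is an exact
#'    seed occurrence, else nothing), with pseudocount 0.1 and background
#'    residue frequencies pooled over the controls;
#' 4. the match threshold is the PWM score maximizing training-set
#'    discrimination: the smallest training-positive score exceeding every
#'    training-control score (maximum sensitivity at zero training
#'    false-positive rate);
#' 5. significance is a one-sided Fisher exact test on hold-out match counts,
#'    Bonferroni-scaled by the number of seeds tested (an E-value);
#' 6. the best motif with E below `alpha` is accepted, its matches in the
#'    positives are masked with `X`, and discovery repeats.
#'
#' @param positives,controls Lists of `protein_record`s (>= 5 each); gaps are
#'   removed.
#' @param width_min,width_max Motif width bounds, within `[4, 15]`.
#' @param n_motifs Maximum number of motifs to report.
#' @param alpha E-value acceptance cutoff.
#' @param seed Integer seed for the train/hold-out split.
#' @param min_seed_frac Fraction of training positives a w-mer must occur in
#'   to seed a motif.
#' @return A list of `motif_model`s ordered by significance; ids record
#'   discovery order.
#' @export
discover_motifs <- function(positives, controls, width_min = 4L,
                            width_max = 15L, n_motifs = 10L, alpha = 0.05,
                            seed = 1L, min_seed_frac = 0.2) {
  if (length(positives) == 0L || length(controls) == 0L)
    stop("empty-input error: positives and controls must be non-empty")
  if (length(positives) < 5L || length(controls) < 5L)
    stop("need at least 5 positives and 5 controls")
  if (width_min > width_max) stop("parameter error: width_min > width_max")
  if (width_min < 4L || width_max > 15L)
    stop("parameter error: widths must lie within [4, 15]")

  pos_seqs <- vapply(positives, function(r)
    gsub("-", "", residues_of(r), fixed = TRUE), "")
  ctl_seqs <- vapply(controls, function(r)
    gsub("-", "", residues_of(r), fixed = TRUE), "")

  split_half <- function(n) {
    idx <- sample.int(n)
    list(train = sort(idx[seq_len(ceiling(n / 2))]),
         hold = sort(idx[-seq_len(ceiling(n / 2))]))
  }
  sp <- with_seed(seed, list(pos = split_half(length(pos_seqs)),
                             neg = split_half(length(ctl_seqs))))

  ## Background: residue frequencies pooled over all controls (X excluded).
  bg_counts <- table(factor(unlist(strsplit(ctl_seqs, "", fixed = TRUE)),
                            levels = AA20))
  background <- as.numeric(bg_counts + 1) / (sum(bg_counts) + 20)
  names(background) <- AA20

  widths <- seq.int(width_min, width_max)
  motifs <- list()

  for (round in seq_len(n_motifs)) {
    enc_pos <- lapply(pos_seqs, encode_seq)
    enc_ctl <- lapply(ctl_seqs, encode_seq)
    tp <- sp$pos$train; hp <- sp$pos$hold
    tn <- sp$neg$train; hn <- sp$neg$hold

    ## Candidate seeds per width from training positives.
    cand <- list()
    for (w in widths) {
      per_seq <- lapply(pos_seqs[tp], function(s) {
        L <- nchar(s)
        if (L < w) return(character(0))
        unique(substring(s, seq_len(L - w + 1L), seq.int(w, L)))
      })
      tab <- table(unlist(per_seq))
      kmers <- names(tab)[tab >= min_seed_frac * length(tp)]
      kmers <- kmers[!grepl("X", kmers, fixed = TRUE)]
      if (length(kmers)) cand[[as.character(w)]] <- sort(kmers)
    }
    n_seeds <- sum(lengths(cand))
    if (n_seeds == 0L) break

    best <- NULL
    for (w_chr in names(cand)) {
      w <- as.integer(w_chr)
      wm_tp <- lapply(enc_pos[tp], window_matrix, w = w)
      wm_tn <- lapply(enc_ctl[tn], window_matrix, w = w)
      wm_hp <- lapply(enc_pos[hp], window_matrix, w = w)
      wm_hn <- lapply(enc_ctl[hn], window_matrix, w = w)
      for (kmer in cand[[w_chr]]) {
        seed_enc <- encode_seq(kmer)
        sc <- seed_counts(wm_tp, seed_enc)
        if (sc$nsites == 0L) next
        m <- new_motif_model(0L, sc$counts, background, NA_real_, NA_real_,
                             nsites = sc$nsites)
        occ_score <- sum(m$log_odds[cbind(seq_len(w), seed_enc)])
        thr <- discriminative_threshold(occ_score,
                                        best_scores(wm_tn, m$log_odds))
        k_pos <- sum(best_scores(wm_hp, m$log_odds) >= thr)
        k_neg <- sum(best_scores(wm_hn, m$log_odds) >= thr)
        e <- motif_significance(k_pos, length(hp), k_neg, length(hn), n_seeds)
        ## ties: more hold-out positives, then wider (a fragment never beats
        ## the full-width motif it came from), then lexicographic consensus
        better <- is.null(best) || e < best$e ||
          (e == best$e && k_pos > best$k_pos) ||
          (e == best$e && k_pos == best$k_pos && w > best$w) ||
          (e == best$e && k_pos == best$k_pos && w == best$w &&
             m$consensus < best$model$consensus)
        if (better)
          best <- list(model = m, thr = thr, e = e, k_pos = k_pos, w = w)
      }
    }
    if (is.null(best) || best$e >= alpha) break

    m <- best$model
    m$id <- length(motifs) + 1L
    m$threshold <- best$thr
    m$significance <- best$e
    motifs[[m$id]] <- m

    ## Mask accepted occurrences in all positives with X.
    for (i in seq_along(pos_seqs)) {
      wm <- window_matrix(encode_seq(pos_seqs[i]), best$w)
      if (is.null(wm)) next
      starts <- which(score_windows(wm, m$log_odds) >= best$thr)
      if (!length(starts)) next
      chars <- strsplit(pos_seqs[i], "", fixed = TRUE)[[1]]
      for (s0 in starts) chars[s0:(s0 + best$w - 1L)] <- "X"
      pos_seqs[i] <- paste(chars, collapse = "")
    }
  }

  motifs[order(vapply(motifs, `[[`, 0, "significance"))]
}

#' Build a motif bank from known consensus strings
#'
#' Constructs exact-match `motif_model`s from consensus strings, e.g. when
#' the discriminative motifs characterizing a protein family are already
#' known. Each motif's threshold is set at its consensus occurrence score,
#' so scanning reports exact consensus occurrences.
#'
#' @param consensi Character vector of consensus strings (widths 4-15).
#' @param background Background residue frequencies (length 20); uniform by
#'   default.
#' @param nsites Nominal site count recorded in the models.
#' @return A list of `motif_model`s, ids in input order.
#' @export
motif_bank_from_consensus <- function(consensi,
                                      background = stats::setNames(
                                        rep(1 / 20, 20), AA20),
                                      nsites = 30L) {
  if (any(nchar(consensi) < 4L | nchar(consensi) > 15L))
    stop("parameter error: motif widths must lie in [4, 15]")
  lapply(seq_along(consensi), function(k) {
    enc <- encode_seq(consensi[k])
    if (anyNA(enc)) stop("invalid residue in consensus: ", consensi[k])
    counts <- matrix(0, nchar(consensi[k]), 20)
    counts[cbind(seq_along(enc), enc)] <- nsites
    m <- new_motif_model(k, counts, background, NA_real_, 1e-10, nsites)
    m$threshold <- sum(m$log_odds[cbind(seq_along(enc), enc)]) - 1e-9
    m
  })
}

#' Scan a sequence with a motif bank
#'
#' Reports every window whose summed log-odds score meets the motif's match
#' threshold. `X` residues contribute the background log-odds (score 0).
#'
#' @param rec A `protein_record` or string (ungapped; gaps are removed).
#' @param motifs A list of `motif_model`s.
#' @return Data frame with columns `motif_id`, `position` (1-based start) and
#'   `score`; zero rows when nothing matches.
#' @export
scan_motifs <- function(rec, motifs) {
  s <- gsub("-", "", residues_of(rec), fixed = TRUE)
  enc <- encode_seq(s)
  out <- lapply(motifs, function(m) {
    wm <- window_matrix(enc, m$width)
    if (is.null(wm)) return(NULL)
    sc <- score_windows(wm, m$log_odds)
    keep <- which(sc >= m$threshold)
    if (!length(keep)) return(NULL)
    data.frame(motif_id = m$id, position = keep, score = sc[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(motif_id = integer(0), position = integer(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sequence-logo letter heights for a motif
#'
#' Per-column information content `IC = log2(20) - H` (Shannon entropy of the
#' column's residue frequencies, no small-sample correction); each residue's
#' letter height is its frequency times the column IC, in bits.
#'
#' @param motif A `motif_model` with non-zero count rows.
#' @return A `width x 20` matrix of letter heights (bits); column sums equal
#'   the per-position IC, at most `log2(20)`.
#' @export
logo_matrix <- function(motif) {
  counts <- motif$counts
  rs <- rowSums(counts)
  if (any(rs <= 0)) stop("parameter error: zero count row in motif")
  freq <- counts / rs
  h <- apply(freq, 1, function(f) -sum(f[f > 0] * log2(f[f > 0])))
  ic <- log2(20) - h
  heights <- freq * ic
  dimnames(heights) <- list(NULL, AA20)
  heights
}

#' Write a motif bank to a minimal MEME-like text file
#'
#' Plain-text format: an alphabet line, background frequencies, then per
#' motif a header with width, number of sites, threshold and E-value followed
#' by the probability matrix (one row per position, 20 columns).
#'
#' @param motifs List of `motif_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_bank <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DLHSCAN motif bank 1.0", "",
               paste("ALPHABET=", paste(AA20, collapse = ""), sep = " "), "",
               "Background letter frequencies:",
               paste(sprintf("%s %.12g", AA20, motifs[[1]]$background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    freqs <- (m$counts + 0.1) / (rowSums(m$counts) + 2)
    writeLines(sprintf("MOTIF %d %s", m$id, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d threshold= %.17g E= %.6g",
      m$width, m$nsites, m$threshold, m$significance), con)
    writeLines(apply(freqs, 1, function(r)
      paste(sprintf("%.12g", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a motif bank written by [write_motif_bank()]
#'
#' @param path Path to a motif bank file.
#' @return A list of `motif_model`s.
#' @export
read_motif_bank <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  if (!length(bg_i)) stop("parse error: no background line in ", path)
  bg_tok <- strsplit(trimws(lines[bg_i + 1L]), "\\s+")[[1]]
  background <- as.numeric(bg_tok[seq(2, length(bg_tok), by = 2)])
  names(background) <- bg_tok[seq(1, length(bg_tok), by = 2)]
  background <- background[AA20]

  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(i) {
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    id <- as.integer(hdr[2])
    meta <- lines[i + 1L]
    get_num <- function(key) as.numeric(sub(paste0(".*", key, " *([^ ]+).*"),
                                            "\\1", meta))
    w <- as.integer(get_num("w="))
    nsites <- as.integer(get_num("nsites="))
    threshold <- get_num("threshold=")
    e <- get_num("E=")
    freq <- do.call(rbind, lapply(lines[(i + 2L):(i + 1L + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    ## recover approximate counts from frequencies for logo rendering
    counts <- freq * nsites
    m <- new_motif_model(id, counts, background, threshold, e, nsites)
    ## preserve frequencies exactly for scoring
    m$log_odds <- log2(sweep(freq, 2, background, `/`))
    dimnames(m$log_odds) <- list(NULL, AA20)
    m
  })
}
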