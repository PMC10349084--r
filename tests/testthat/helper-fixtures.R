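## Shared test helpers; fixtures are generated in code, never stored.

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rec <- function(id, residues, taxon = "unknown", aligned = FALSE)
  protein_record(id, residues, taxon = taxon, aligned = aligned)

random_records <- function(n, len, prefix = "r", seed = NULL) {
  gen <- function() lapply(seq_len(n), function(i)
    rec(paste0(prefix, i), paste(sample(dlhscan:::AA20, len, replace = TRUE),
                                 collapse = "")))
  if (is.null(seed)) gen() else dlhscan:::with_seed(seed, gen())
}

## Default classifier ingredients shared across tests: a decoy-calibrated
## domain profile and an exact-match bank of the generator's motif set.
default_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      seed_aln <- generate_seed_alignment(seed = 101)
      calib <- random_records(500, 300, prefix = "calib", seed = 102)
      cache <<- build_domain_profile(seed_aln, decoy_set = calib, fpr = 0.01)
    }
    cache
  }
})

default_bank <- function() motif_bank_from_consensus(default_motif_set())

## Independent brute-force one-sided Fisher p (hypergeometric tail sum).
brute_fisher_p <- function(k_pos, n_pos, k_neg, n_neg) {
  m <- k_pos + k_neg
  total <- n_pos + n_neg
  xs <- max(0, m - n_neg):min(m, n_pos)
  xs <- xs[xs >= k_pos]
  sum(stats::dhyper(xs, m, total - m, n_pos))
}
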