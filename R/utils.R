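## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## Random amino-acid string(s) over the 20-letter alphabet.
random_aa <- function(n_chars) {
  paste(sample(AA20, n_chars, replace = TRUE), collapse = "")
}

## Replace canonical cysteine contexts in a sequence so that neither
## [D/N]CGF nor ECT[E/Q] occurs; the critical residue is mutated to A.
scrub_contexts <- function(s) {
  while (grepl("[DN]CGF", s)) s <- sub("([DN])CGF", "\\1AGF", s)
  while (grepl("ECT[EQ]", s)) s <- sub("ECT([EQ])", "EAT\\1", s)
  s
}

## Apply per-site substitution noise to a sequence (prob per residue), each
## substituted site drawing a uniformly random different amino acid.
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}
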