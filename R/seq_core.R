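#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, in alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a protein record
#'
#' A `protein_record` holds an identified amino-acid sequence together with a
#' free-text description and a taxonomic group label (e.g. `"Dinophyceae"`).
#' Residues are upper-case one-letter amino-acid codes; `X` marks an unknown
#' residue and `-` a gap (aligned records only).
#'
#' @param id Non-empty record identifier, unique within a collection.
#' @param residues Amino-acid sequence as a single string.
#' @param description Free text carried on the FASTA header.
#' @param taxon Taxonomic group label; `"unknown"` when absent.
#' @param aligned Logical; if `FALSE` (the default) gap characters are
#'   rejected.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, residues, description = "", taxon = "unknown",
                           aligned = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("record '", id, "': residues must be a non-empty string")
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1]]),
                 c(AA20, "X", "-"))
  if (length(bad))
    stop("record '", id, "': invalid residue character(s): ",
         paste(bad, collapse = ", "))
  if (!aligned && grepl("-", residues, fixed = TRUE))
    stop("record '", id, "': gap characters in an unaligned record")
  structure(list(id = id, description = description, taxon = taxon,
                 residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s [%s] %d residues\n",
              x$id, x$taxon, nchar(x$residues)))
  invisible(x)
}

residues_of <- function(x) {
  if (inherits(x, "protein_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a protein_record or a single string")
}

#' Remove gap characters from a record
#'
#' @param rec A `protein_record` (possibly aligned) or a string.
#' @return An ungapped `protein_record`.
#' @export
degap <- function(rec) {
  if (is.character(rec)) rec <- protein_record("seq", rec, aligned = TRUE)
  protein_record(rec$id, gsub("-", "", rec$residues, fixed = TRUE),
                 rec$description, rec$taxon)
}

#' Create an alignment of protein records
#'
#' @param records List of `protein_record`s of equal (aligned) length;
#'   at least two.
#' @return An object of class `aa_alignment` with elements `records` and
#'   `length` (number of columns).
#' @export
aa_alignment <- function(records) {
  if (!is.list(records) || length(records) < 2L)
    stop("an alignment needs at least 2 records")
  records <- lapply(records, function(r)
    if (inherits(r, "protein_record")) r else stop("records must be protein_record"))
  lens <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(lens)) != 1L)
    stop("alignment-shape error: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = records, length = lens[[1]]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              length(x$records), x$length))
  invisible(x)
}

## Alignment as a character matrix (rows = sequences, one residue per cell).
alignment_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$records, function(r)
    strsplit(r$residues, "", fixed = TRUE)[[1]]))
  rownames(m) <- vapply(aln$records, `[[`, "", "id")
  m
}

## Rebuild an alignment from a character matrix, keeping record metadata.
alignment_from_matrix <- function(m, template) {
  recs <- lapply(seq_len(nrow(m)), function(i) {
    tr <- template$records[[i]]
    protein_record(tr$id, paste(m[i, ], collapse = ""), tr$description,
                   tr$taxon, aligned = TRUE)
  })
  aa_alignment(recs)
}

parse_header <- function(header) {
  header <- sub("^>", "", header)
  id <- sub("\\s.*$", "", header)
  description <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
  taxon <- if (grepl("taxon=", description, fixed = TRUE))
    sub(".*taxon=(\\S+).*", "\\1", description) else "unknown"
  list(id = id, description = description, taxon = taxon)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are `">id description"`; a `taxon=<label>` token in the description
#' sets the record's taxon (else `"unknown"`). With `aligned = TRUE` all
#' sequences must have equal length and an [aa_alignment()] is returned.
#'
#' @param path Path to a FASTA (or aligned FASTA, gap `-`) file.
#' @param aligned Logical; read as an alignment.
#' @return A list of `protein_record`s, or an `aa_alignment`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty-input error: no sequences in ", path)
  recs <- lapply(seq_along(set), function(i) {
    h <- parse_header(names(set)[i])
    protein_record(h$id, as.character(set[[i]]), h$description, h$taxon,
                   aligned = aligned)
  })
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (aligned) aa_alignment(recs) else recs
}

#' Write protein records to a FASTA file
#'
#' Sequences are written unwrapped (one line per record) so that a write/read
#' cycle preserves ids, descriptions and residues exactly.
#'
#' @param records A list of `protein_record`s or an `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "aa_alignment")) records <- records$records
  if (inherits(records, "protein_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) paste(">", r$id, " ", r$description, sep = "")
              else paste(">", r$id, sep = "")
    c(header, r$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Percent identity between two aligned sequences
#'
#' Counts columns where both sequences carry the identical non-gap residue.
#' With `scope = "aligned_columns"` the denominator is the number of columns
#' in which at least one of the pair has a residue (columns gapped in both are
#' ignored); with `scope = "shorter_sequence"` it is the shorter ungapped
#' length. `X` never counts as a match.
#'
#' @param a,b Aligned `protein_record`s (or strings) of equal length.
#' @param scope Denominator convention.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b,
                              scope = c("aligned_columns", "shorter_sequence")) {
  scope <- match.arg(scope)
  ca <- strsplit(residues_of(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(residues_of(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb))
    stop("alignment-shape error: sequences have unequal aligned lengths")
  both_gap <- ca == "-" & cb == "-"
  match_col <- ca == cb & ca != "-" & ca != "X"
  denom <- switch(scope,
    aligned_columns = sum(!both_gap),
    shorter_sequence = min(sum(ca != "-"), sum(cb != "-")))
  if (denom == 0) stop("no scored columns between the pair")
  100 * sum(match_col) / denom
}

#' Find canonical active-site cysteine contexts
#'
#' Scans an ungapped sequence for the two 4-residue contexts that surround the
#' catalytic cysteines of the eukaryotic DMSP lyase: `[D/N]CGF` (N-terminal
#' site, C108 in the Emiliania huxleyi enzyme) and `ECT[E/Q]` (C-terminal
#' site, C265). The cysteine sits at the second position of each context, so
#' its 1-based position is the match start + 1. Overlapping occurrences are
#' all reported.
#'
#' @param rec A `protein_record` or string; gaps are removed first.
#' @return A data frame with columns `site` (`"N_SITE"`/`"C_SITE"`),
#'   `c_position` (1-based cysteine position in the ungapped sequence) and
#'   `context` (the matched 4-mer), sorted by position. Zero rows when there
#'   is no match.
#' @export
find_cysteine_contexts <- function(rec) {
  s <- gsub("-", "", residues_of(rec), fixed = TRUE)
  find_all <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts[starts > 0]
  }
  n_starts <- find_all("[DN]CGF")
  c_starts <- find_all("ECT[EQ]")
  ctx <- function(starts) if (length(starts))
    substring(s, starts, starts + 3L) else character(0)
  hits <- data.frame(
    site = c(rep("N_SITE", length(n_starts)), rep("C_SITE", length(c_starts))),
    c_position = c(n_starts + 1L, c_starts + 1L),
    context = c(ctx(n_starts), ctx(c_starts)),
    stringsAsFactors = FALSE)
  hits[order(hits$c_position), , drop = FALSE]
}

#' Does a set of context hits form the canonical cysteine pair?
#'
#' A sequence qualifies when it carries at least one N-site context and at
#' least one C-site context. By default the C site must lie downstream of an
#' N site, mirroring the C108 < C265 arrangement of the characterized enzyme;
#' set `require_order = FALSE` to accept any arrangement.
#'
#' @param hits Data frame from [find_cysteine_contexts()] for one sequence.
#' @param require_order Logical; require an N site upstream of a C site.
#' @return `TRUE` or `FALSE`.
#' @export
has_canonical_pair <- function(hits, require_order = TRUE) {
  if (is.null(hits) || nrow(hits) == 0L) return(FALSE)
  n_pos <- hits$c_position[hits$site == "N_SITE"]
  c_pos <- hits$c_position[hits$site == "C_SITE"]
  if (!length(n_pos) || !length(c_pos)) return(FALSE)
  if (!require_order) return(TRUE)
  any(outer(n_pos, c_pos, `<`))
}

## Integer encoding over AA20; X, gaps and anything else become NA.
encode_seq <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], AA20)
}

## All windows of width w of an encoded sequence, as a w x n_windows matrix.
## Returns NULL when the sequence is shorter than w.
window_matrix <- function(enc, w) {
  L <- length(enc)
  if (L < w) return(NULL)
  n <- L - w + 1L
  matrix(enc[outer(seq_len(w) - 1L, seq_len(n), `+`)], nrow = w)
}

## Score every window against a w x 20 score matrix; NA residues (X) score 0.
score_windows <- function(winmat, mat) {
  w <- nrow(mat)
  vals <- mat[cbind(rep(seq_len(w), ncol(winmat)), as.vector(winmat))]
  vals[is.na(vals)] <- 0
  colSums(matrix(vals, nrow = w))
}
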