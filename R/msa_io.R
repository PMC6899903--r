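## MSA reading, validation and integer encoding.
##
## Three flat alignment dialects are supported:
##   * fasta  — standard headers + aligned sequences
##   * a3m    — fasta-like; lowercase letters are insert states relative to
##              the query and are deleted so all rows share the query frame
##   * psicov — one aligned sequence per line, no headers

#' An integer-encoded multiple sequence alignment
#'
#' Constructs an `msa` object from aligned sequence strings. Rows are
#' upper-cased and encoded over the fixed 21-state alphabet
#' ([aa_alphabet()] plus gap); any letter outside the 20 standard amino
#' acids (B, Z, X, U, O, J, '.', '-') becomes the gap state 21. The first
#' row is the query/target sequence by convention.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param ids Optional sequence identifiers; defaults to `seq_1 ...`.
#' @return An object of class `msa` with elements `ids`, `codes`
#'   (N x L integer matrix in 1..21), `N` and `L`.
#' @export
msa <- function(seqs, ids = NULL) {
  if (length(seqs) == 0L) stop("empty alignment: no sequences")
  seqs <- unname(toupper(seqs))
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty alignment row")
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  L <- lens[1L]
  lut <- rep(GAP_STATE, 256L)
  lut[utf8ToInt(paste(AA_ALPHABET, collapse = "")) + 1L] <- seq_len(20L)
  codes <- matrix(0L, nrow = length(seqs), ncol = L)
  for (s in seq_along(seqs)) {
    codes[s, ] <- lut[utf8ToInt(seqs[s]) + 1L]
  }
  structure(list(ids = as.character(ids), codes = codes,
                 N = length(seqs), L = L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query: %s)\n",
              x$N, x$L, x$ids[1L]))
  invisible(x)
}

#' Decode an msa back to character sequences
#'
#' @param m An [msa] object.
#' @return Character vector of aligned sequences ('-' for gaps).
#' @export
msa_sequences <- function(m) {
  letters21 <- c(AA_ALPHABET, "-")
  apply(m$codes, 1L, function(row) paste(letters21[row], collapse = ""))
}

#' Read a multiple sequence alignment
#'
#' Reads an alignment from one of three flat-text dialects and encodes it
#' over the fixed 21-state alphabet. For `a3m`, lowercase letters denote
#' insertions relative to the query and are removed before encoding, so
#' every row shares the query's column frame.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"a3m"`, `"psicov"`.
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("fasta", "a3m", "psicov")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "psicov") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty alignment file: ", path)
    return(msa(trimws(lines)))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  seqs <- as.character(set)
  ids <- names(set)
  if (format == "a3m") {
    # delete insert-state (lowercase) columns; '.' is an a3m insert gap
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ch[!(ch %in% letters) & ch != "."], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  msa(seqs, ids)
}

#' Write an alignment to fasta or psicov format
#'
#' @param m An [msa] object.
#' @param path Output path.
#' @param format `"fasta"` or `"psicov"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(m, path, format = c("fasta", "psicov")) {
  format <- match.arg(format)
  seqs <- msa_sequences(m)
  if (format == "psicov") {
    writeLines(seqs, path)
  } else {
    writeLines(as.vector(rbind(paste0(">", m$ids), seqs)), path)
  }
  invisible(path)
}

#' One-hot encoding of an alignment
#'
#' @param m An [msa] object.
#' @return An N x L x 21 0/1 array; exactly one 1 per (sequence, column),
#'   at the index of that residue's code.
#' @export
one_hot <- function(m) {
  out <- array(0, dim = c(m$N, m$L, N_STATES))
  idx <- cbind(rep(seq_len(m$N), m$L),
               rep(seq_len(m$L), each = m$N),
               as.vector(m$codes))
  out[idx] <- 1
  out
}

## Sparse-ish one-hot as an N x (L*21) matrix, column index (i-1)*21 + a.
## Used by the frequency machinery; dense is fine at desk scale.
one_hot_flat <- function(m) {
  out <- matrix(0, nrow = m$N, ncol = m$L * N_STATES)
  cols <- sweep(m$codes, 2L, (seq_len(m$L) - 1L) * N_STATES, "+")
  out[cbind(rep(seq_len(m$N), m$L), as.vector(cols))] <- 1
  out
}
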