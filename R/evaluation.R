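## CASP-style contact assessment.
##
## Range conventions (CASP): long-range = sequence separation |i-j| >= 24,
## medium-range = 12..23, medium+long = >= 12. Top-L/k precision takes
## the floor(L/k) highest-scoring eligible pairs (at least 1), with
## deterministic tie-breaks: descending score, then ascending (i, j).

range_limits <- function(range = c("long", "medium", "medium+long")) {
  switch(match.arg(range),
         "long" = c(24L, Inf),
         "medium" = c(12L, 23L),
         "medium+long" = c(12L, Inf))
}

#' Top-L/k precision of a contact score map
#'
#' @param scores L x L score matrix (higher = more confident).
#' @param truth L x L binary contact map.
#' @param k_divisor One of 1, 2, 5, 10: evaluate the top floor(L/k) pairs.
#' @param range `"long"`, `"medium"` or `"medium+long"`.
#' @return Precision as a percentage in \[0, 100\].
#' @export
topk_precision <- function(scores, truth, k_divisor = 5,
                           range = c("long", "medium", "medium+long")) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth))) stop("shape mismatch")
  if (any(truth != 0 & truth != 1)) stop("truth map must be binary")
  if (!k_divisor %in% c(1, 2, 5, 10)) stop("k_divisor must be 1, 2, 5 or 10")
  lim <- range_limits(range)
  L <- nrow(scores)
  ij <- which(upper.tri(scores), arr.ind = TRUE)
  sep <- ij[, 2L] - ij[, 1L]
  elig <- sep >= lim[1L] & sep <= lim[2L]
  if (!any(elig)) stop("no eligible residue pairs for range '", range[1L], "'")
  ij <- ij[elig, , drop = FALSE]
  sc <- scores[ij]
  ord <- order(-sc, ij[, 1L], ij[, 2L])
  n_sel <- max(1L, floor(L / k_divisor))
  n_sel <- min(n_sel, length(sc))
  sel <- ord[seq_len(n_sel)]
  100 * sum(truth[ij[sel, , drop = FALSE]] == 1) / n_sel
}

#' Load the packaged CASP13 FM / FM-TBM domain table
#'
#' Per-domain records (id, classification, length, top-L/5 long-range
#' precision in percent, Meff of the full-length target alignment)
#' transcribed from the published assessment of the method.
#'
#' @return data frame with 43 rows.
#' @export
casp13_domain_table <- function() {
  path <- system.file("extdata", "casp13_fm_domains.csv",
                      package = "contactnet", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate a domain precision table
#'
#' Optionally filters rows by maximum Meff and/or minimum precision, then
#' reports the mean precision (rounded to 2 decimals) and the row count.
#'
#' @param table Data frame with columns `precision_topL5_long` and `meff`
#'   (e.g. [casp13_domain_table()]).
#' @param meff_max Keep rows with `meff <= meff_max` (optional).
#' @param precision_min Keep rows with precision `>= precision_min`
#'   (optional).
#' @return List with `mean_precision`, `n` and the filtered `rows`;
#'   `mean_precision` is `NA` when no rows survive.
#' @export
aggregate_table <- function(table, meff_max = NULL, precision_min = NULL) {
  stopifnot(nrow(table) > 0L)
  rows <- table
  if (!is.null(meff_max)) rows <- rows[rows$meff <= meff_max, , drop = FALSE]
  if (!is.null(precision_min)) {
    rows <- rows[rows$precision_topL5_long >= precision_min, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    return(list(mean_precision = NA_real_, n = 0L, rows = rows))
  }
  list(mean_precision = round(mean(rows$precision_topL5_long), 2L),
       n = nrow(rows), rows = rows)
}

#' Splice domain-level scores back into a full-length score map
#'
#' Overwrites `full[i, j]` with the domain prediction wherever both i and
#' j fall inside the domain segment(s); all other entries are untouched.
#' Used when a sub-sequence (putative domain) has been re-predicted on
#' its own alignment.
#'
#' @param full L x L full-length score map.
#' @param domain l x l domain score map, l = total segment length.
#' @param segments Either `c(start, end)` (1-based, inclusive) or a list
#'   of such vectors for a discontinuous domain; non-overlapping and in
#'   order.
#' @return The updated L x L map.
#' @export
splice_domain_scores <- function(full, domain, segments) {
  full <- as.matrix(full); domain <- as.matrix(domain)
  if (!is.list(segments)) segments <- list(segments)
  L <- nrow(full)
  idx <- unlist(lapply(segments, function(s) {
    if (length(s) != 2L || s[1L] > s[2L] || s[1L] < 1L || s[2L] > L) {
      stop("segment out of bounds: [", s[1L], ", ", s[2L], "] for L = ", L)
    }
    seq.int(s[1L], s[2L])
  }))
  if (anyDuplicated(idx)) stop("overlapping domain segments")
  if (length(idx) != nrow(domain)) {
    stop("domain map size (", nrow(domain),
         ") does not match total segment length (", length(idx), ")")
  }
  full[idx, idx] <- domain
  full
}

#' Contact map from residue coordinates
#'
#' `truth[i, j] = 1` iff the Euclidean distance between the (C-beta)
#' coordinates of residues i and j is at most `cutoff` and i != j.
#'
#' @param coords L x 3 coordinate matrix (angstroms).
#' @param cutoff Contact distance cutoff (default 8.0 A).
#' @return L x L symmetric 0/1 matrix with zero diagonal.
#' @export
contacts_from_coords <- function(coords, cutoff = 8.0) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  cm <- (d <= cutoff) * 1
  diag(cm) <- 0
  cm
}

## ---- CASP RR format --------------------------------------------------------

#' Write / read CASP RR contact files
#'
#' The RR dialect: `PFRMAT RR`, optional `TARGET`/`MODEL` headers,
#' optional sequence lines, then records `i j 0 8 p` with 1-based residue
#' indices sorted by descending probability, terminated by `END`.
#'
#' @param scores Symmetric L x L probability matrix.
#' @param path Output path.
#' @param target Target identifier for the header.
#' @param sequence Optional sequence string, wrapped at 50 columns.
#' @param min_prob Records below this probability are omitted.
#' @return `path` (write); for the reader, a list with `scores` (L x L
#'   matrix, unrecorded pairs 0), `target` and `L`.
#' @export
write_rr <- function(scores, path, target = "T0000", sequence = NULL,
                     min_prob = 0) {
  scores <- as.matrix(scores)
  L <- nrow(scores)
  ij <- which(upper.tri(scores), arr.ind = TRUE)
  p <- scores[ij]
  keep <- p >= min_prob
  ij <- ij[keep, , drop = FALSE]; p <- p[keep]
  ord <- order(-p, ij[, 1L], ij[, 2L])
  lines <- c("PFRMAT RR", paste("TARGET", target), "MODEL 1")
  if (!is.null(sequence)) {
    lines <- c(lines, substring(sequence, seq(1L, nchar(sequence), 50L),
                                pmin(seq(1L, nchar(sequence), 50L) + 49L,
                                     nchar(sequence))))
  }
  lines <- c(lines,
             sprintf("%d %d 0 8 %.6f", ij[ord, 1L], ij[ord, 2L], p[ord]),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rr
#' @param L Sequence length for the reader; inferred from the largest
#'   residue index (or sequence line) when omitted.
#' @export
read_rr <- function(path, L = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  target <- NA_character_
  seq_chars <- character(0)
  rec <- list()
  for (ln in lines) {
    if (grepl("^(PFRMAT|MODEL|END|REMARK|AUTHOR|METHOD)", ln)) next
    if (startsWith(ln, "TARGET")) {
      target <- trimws(sub("^TARGET", "", ln))
    } else if (grepl("^[A-Za-z]+$", ln)) {
      seq_chars <- c(seq_chars, ln)
    } else {
      f <- strsplit(ln, "\\s+")[[1L]]
      if (length(f) >= 5L) rec[[length(rec) + 1L]] <- as.numeric(f[c(1, 2, 5)])
    }
  }
  rec <- do.call(rbind, rec)
  if (is.null(L)) {
    L <- if (length(seq_chars) > 0L) sum(nchar(seq_chars))
         else if (!is.null(rec)) max(rec[, 1:2])
         else stop("cannot infer L from RR file: ", path)
  }
  scores <- matrix(0, L, L)
  if (!is.null(rec)) {
    scores[rec[, 1:2, drop = FALSE]] <- rec[, 3L]
    scores[rec[, 2:1, drop = FALSE]] <- rec[, 3L]
  }
  list(scores = scores, target = target,
       sequence = if (length(seq_chars)) paste(seq_chars, collapse = "") else NULL,
       L = L)
}
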