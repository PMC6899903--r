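## Assembly of the 501-channel network input tensor.
##
## Layout (names in channel_manifest()):
##   58 "alignment-statistic" channels:
##     - striped sequence profile           2 x 21 = 42
##     - striped 3-state secondary structure 2 x 3 =  6
##     - striped solvent accessibility       2 x 1 =  2
##     - pair channels (8): mutual information, APC-corrected MI,
##       joint entropy, mean contact potential, three external coupling
##       maps (psicov / ccmpred / freecontact; zero-filled when absent),
##       and the mean per-column gap fraction of the pair
##   441 raw covariance channels (21 x 21 residue-type pairs)
##   1 sequence-separation channel + 1 all-ones bounds channel
## Total: 501. Internally tensors are L x L x C arrays (channels last).

SS_STATES <- c("H", "E", "C")

#' Channel name manifest for the assembled feature tensor
#'
#' Single source of truth for the 501-channel layout; consumers index by
#' name, so the order can change here without touching them.
#'
#' @return Character vector of 501 unique channel names.
#' @export
channel_manifest <- function() {
  st <- c(AA_ALPHABET, "gap")
  prof <- as.vector(rbind(paste0("prof_", st, "_i"), paste0("prof_", st, "_j")))
  ss <- as.vector(rbind(paste0("ss_", SS_STATES, "_i"),
                        paste0("ss_", SS_STATES, "_j")))
  solv <- c("solv_i", "solv_j")
  pair <- c("mi", "mi_apc", "joint_entropy", "contact_potential",
            "psicov", "ccmpred", "freecontact", "gap_fraction")
  st2 <- c(AA_ALPHABET, "-")
  cov <- paste0("cov_", rep(st2, each = N_STATES), "_", st2)
  c(prof, ss, solv, pair, cov, "separation", "bounds")
}

#' Stripe per-residue features into 2D maps
#'
#' Each per-residue feature column c becomes two L x L channels: a
#' horizontal stripe `out[i, j] = values[i, c]` (constant along rows) and
#' a vertical stripe `out[i, j] = values[j, c]`; channel order is
#' (c horizontal, c vertical) for c = 1..k.
#'
#' @param values L x k matrix (or length-L vector) of per-residue features.
#' @return L x L x 2k array.
#' @export
stripe_1d <- function(values) {
  values <- as.matrix(values)
  L <- nrow(values)
  k <- ncol(values)
  out <- array(0, dim = c(L, L, 2L * k))
  for (c in seq_len(k)) {
    out[, , 2L * c - 1L] <- matrix(values[, c], L, L)         # out[i,j]=v[i]
    out[, , 2L * c] <- matrix(values[, c], L, L, byrow = TRUE) # out[i,j]=v[j]
  }
  out
}

#' Sequence-separation channel
#'
#' `out[i, j] = min(|i - j|, cap) / cap`; symmetric with zero diagonal.
#' The cap (default 100 residues) bounds the encoding so that very long
#' separations saturate at 1.
#'
#' @param L Sequence length.
#' @param cap Saturation separation in residues.
#' @return L x L matrix.
#' @export
separation_channel <- function(L, cap = 100) {
  d <- abs(outer(seq_len(L), seq_len(L), "-"))
  pmin(d, cap) / cap
}

#' All-ones sequence-bounds channel
#'
#' Lets the first convolution distinguish true zeros in the data from
#' zeros introduced by padding outside the L x L frame.
#'
#' @param L Sequence length.
#' @return L x L matrix of ones.
#' @export
bounds_channel <- function(L) matrix(1, L, L)

## ---- contact potential ----------------------------------------------------

the_pkg_cache <- new.env(parent = emptyenv())

#' The packaged synthetic residue contact-potential table
#'
#' A 20 x 20 symmetric pair-potential table shipped with the package.
#' It is a synthetic stand-in (not a published statistical potential),
#' constructed deterministically from the Kyte-Doolittle hydropathy
#' scale as `p[a, b] = -h_a * h_b / 25`, so hydrophobic-hydrophobic
#' pairs score favourably (negative). Stored as plain text in
#' `extdata/contact_potential_synthetic.tsv`.
#'
#' @return 20 x 20 numeric matrix with residue dimnames.
#' @export
contact_potential_table <- function() {
  if (is.null(the_pkg_cache$cpot)) {
    path <- system.file("extdata", "contact_potential_synthetic.tsv",
                        package = "contactnet", mustWork = TRUE)
    tab <- as.matrix(read.table(path, header = TRUE, row.names = 1L,
                                check.names = FALSE))
    the_pkg_cache$cpot <- tab[AA_ALPHABET, AA_ALPHABET]
  }
  the_pkg_cache$cpot
}

#' Profile-weighted mean contact-potential map
#'
#' `out[i, j]` is the expectation of the 20 x 20 contact-potential table
#' under the product of the (gap-excluded, renormalized) profile columns
#' at i and j. All-gap columns fall back to a uniform residue profile.
#'
#' @param m An [msa] object.
#' @param weights Optional per-sequence weights for the profile.
#' @return L x L matrix.
#' @export
contact_potential_map <- function(m, weights = NULL) {
  stats <- column_stats(m, weights)
  profile_potential_map(stats$f1)
}

## Same computation from an L x 21 profile directly.
profile_potential_map <- function(profile) {
  p20 <- profile[, seq_len(20L), drop = FALSE]
  rs <- rowSums(p20)
  p20[rs == 0, ] <- 1 / 20
  rs[rs == 0] <- 1
  p20 <- p20 / rs
  p20 %*% contact_potential_table() %*% t(p20)
}

## ---- residue features ------------------------------------------------------

#' Per-residue feature bundle
#'
#' Validates and packages the 1D features that are striped into the
#' tensor: the L x 21 sequence profile (rows sum to 1), predicted 3-state
#' secondary structure probabilities (columns H, E, C; rows sum to 1),
#' predicted relative solvent accessibility in \[0, 1\], and the boolean
#' loop mask used by loop-sampling augmentation.
#'
#' @param profile L x 21 matrix.
#' @param ss3 L x 3 matrix.
#' @param solv Length-L vector in \[0, 1\].
#' @param loop_mask Length-L logical vector.
#' @return A `residue_features` list.
#' @export
residue_features <- function(profile, ss3, solv, loop_mask) {
  profile <- as.matrix(profile); ss3 <- as.matrix(ss3)
  L <- nrow(profile)
  stopifnot(ncol(profile) == N_STATES, nrow(ss3) == L, ncol(ss3) == 3L,
            length(solv) == L, length(loop_mask) == L)
  if (max(abs(rowSums(profile) - 1)) > 1e-6) stop("profile rows must sum to 1")
  if (max(abs(rowSums(ss3) - 1)) > 1e-6) stop("ss3 rows must sum to 1")
  if (any(solv < -1e-9 | solv > 1 + 1e-9)) stop("solv must lie in [0, 1]")
  colnames(ss3) <- SS_STATES
  structure(list(profile = profile, ss3 = ss3, solv = as.numeric(solv),
                 loop_mask = as.logical(loop_mask), L = L),
            class = "residue_features")
}

#' Pairwise statistic bundle for tensor assembly
#'
#' Computes the covariance channels, mutual information, APC-corrected MI
#' and joint entropy from one set of column statistics.
#'
#' @param stats A [column_stats()] result.
#' @return A `pair_matrices` list with `cov` (L x L x 441), `mi`,
#'   `mi_apc`, `joint_entropy` (L x L each).
#' @export
pair_matrices <- function(stats) {
  mi <- mutual_information(stats)
  structure(list(cov = covariance_features(stats), mi = mi$mi,
                 mi_apc = mi$mi_apc, joint_entropy = mi$joint_entropy,
                 L = stats$L),
            class = "pair_matrices")
}

## ---- assembly --------------------------------------------------------------

#' Assemble the full 501-channel network input
#'
#' Combines striped per-residue features, internal pair statistics,
#' optional external coupling maps and the separation and bounds
#' channels, in the order of [channel_manifest()]. Missing external maps
#' are zero-filled (with a warning) and recorded in
#' `meta$missing_external`.
#'
#' @param m An [msa] object (used for the contact-potential and
#'   gap-fraction channels).
#' @param res A [residue_features()] bundle.
#' @param pm A [pair_matrices()] bundle.
#' @param external Optional named list with any of `psicov`, `ccmpred`,
#'   `freecontact`, each an L x L matrix.
#' @param sep_cap Saturation constant for the separation channel.
#' @return A `feature_tensor`: list with `data` (L x L x 501 array,
#'   channel dimnames), `channel_map`, `L`, `meta`.
#' @export
assemble_features <- function(m, res, pm, external = NULL, sep_cap = 100) {
  L <- m$L
  if (res$L != L || pm$L != L) stop("msa, residue features and pair matrices disagree on L")
  ext_names <- c("psicov", "ccmpred", "freecontact")
  external <- if (is.null(external)) list() else external
  missing_ext <- setdiff(ext_names, names(external))
  if (length(missing_ext) > 0L) {
    warning("external coupling maps absent, zero-filled: ",
            paste(missing_ext, collapse = ", "))
  }
  get_ext <- function(nm) {
    if (nm %in% names(external)) {
      mat <- as.matrix(external[[nm]])
      if (!all(dim(mat) == c(L, L))) stop("external map ", nm, " has wrong size")
      mat
    } else matrix(0, L, L)
  }
  cmap <- channel_manifest()
  data <- array(0, dim = c(L, L, length(cmap)), dimnames = list(NULL, NULL, cmap))
  data[, , 1:42] <- stripe_1d(res$profile)
  data[, , 43:48] <- stripe_1d(res$ss3)
  data[, , 49:50] <- stripe_1d(res$solv)
  data[, , "mi"] <- pm$mi
  data[, , "mi_apc"] <- pm$mi_apc
  data[, , "joint_entropy"] <- pm$joint_entropy
  data[, , "contact_potential"] <- contact_potential_map(m)
  for (nm in ext_names) data[, , nm] <- get_ext(nm)
  gapfreq <- colMeans(m$codes == GAP_STATE)
  data[, , "gap_fraction"] <- outer(gapfreq, gapfreq, function(a, b) (a + b) / 2)
  data[, , 59:499] <- pm$cov
  data[, , "separation"] <- separation_channel(L, cap = sep_cap)
  data[, , "bounds"] <- bounds_channel(L)
  if (!all(is.finite(data))) stop("non-finite values in assembled tensor")
  feature_tensor(data, cmap, meta = list(missing_external = missing_ext,
                                         sep_cap = sep_cap))
}

#' Feature tensor container
#'
#' @param data L x L x C numeric array.
#' @param channel_map Character vector of C unique channel names.
#' @param meta Optional metadata list.
#' @return A `feature_tensor` object.
#' @export
feature_tensor <- function(data, channel_map = dimnames(data)[[3]],
                           meta = list()) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == dim(data)[2])
  if (is.null(channel_map) || anyDuplicated(channel_map) ||
      length(channel_map) != dim(data)[3]) {
    stop("channel_map must uniquely name every channel")
  }
  dimnames(data) <- list(NULL, NULL, channel_map)
  structure(list(data = data, channel_map = channel_map,
                 L = dim(data)[1], meta = meta),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("feature_tensor: %d channels x %d x %d\n",
              length(x$channel_map), x$L, x$L))
  invisible(x)
}

#' Save / load a feature tensor
#'
#' The tensor (array + channel map + metadata) is stored in R's portable
#' native serialization.
#'
#' @param ft A `feature_tensor`.
#' @param path File path.
#' @return `path` (write) or the tensor (read).
#' @export
write_feature_tensor <- function(ft, path) {
  saveRDS(ft, path)
  invisible(path)
}

#' @rdname write_feature_tensor
#' @export
read_feature_tensor <- function(path) {
  ft <- readRDS(path)
  if (!inherits(ft, "feature_tensor")) stop("not a feature tensor: ", path)
  ft
}

## ---- PSIPRED-style ss2 I/O -------------------------------------------------

#' Read / write PSIPRED-style ss2 secondary-structure files
#'
#' The ss2 dialect has a comment header and one line per residue:
#' index, residue letter, state letter, then the coil, helix and strand
#' probabilities. Probabilities are returned in column order H, E, C and
#' renormalized to sum to 1.
#'
#' @param path File path.
#' @return List with `aa` (residue letters), `ss` (state letters) and
#'   `ss3` (L x 3 matrix, columns H/E/C).
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  aa <- vapply(parts, `[`, character(1), 2L)
  ss <- vapply(parts, `[`, character(1), 3L)
  probs <- t(vapply(parts, function(p) as.numeric(p[4:6]), numeric(3)))
  ss3 <- cbind(H = probs[, 2L], E = probs[, 3L], C = probs[, 1L])
  ss3 <- ss3 / rowSums(ss3)
  list(aa = aa, ss = ss, ss3 = ss3)
}

#' @rdname read_ss2
#' @param aa Residue letters.
#' @param ss3 L x 3 matrix of H/E/C probabilities.
#' @export
write_ss2 <- function(aa, ss3, path) {
  ss <- c("H", "E", "C")[max.col(ss3, ties.method = "first")]
  lines <- c("# PSIPRED VFORMAT (contactnet synthetic)", "",
             sprintf("%4d %s %s  %6.3f %6.3f %6.3f", seq_along(aa), aa, ss,
                     ss3[, 3L], ss3[, 1L], ss3[, 2L]))
  writeLines(lines, path)
  invisible(path)
}
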