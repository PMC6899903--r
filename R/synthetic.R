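## Synthetic desk-scale fixtures with the statistical structure the
## predictor assumes: idealized helix-bundle "proteins" with contact maps
## and loop annotations, alignments sampled from a pairwise-coupled
## sequence model so that column covariation is elevated at contact
## positions, and paired deep/shallow alignments of the same protein for
## the mixup augmentation.
##
## All sampling uses the current R RNG; seed before calling for
## reproducibility.

#' Generate an idealized helix-bundle toy structure
#'
#' Builds a bundle of ideal alpha-helices (rise 1.5 A/residue, 100
#' degrees/residue, C-beta radius 2.3 A) whose axes sit on a circle with
#' alternating up/down directions, connected by jittered loops. The
#' result is self-avoiding (minimum 3.5 A between residues with
#' |i - j| >= 3) and has at least one long-range (|i - j| >= 24)
#' contact; generation retries with fresh jitter until both hold.
#'
#' @param L Protein length (>= 20).
#' @param n_helices Number of helices; default scales with L.
#' @param max_retries Packing attempts before giving up.
#' @return A `toy_protein`: list with `length`, `cb_coords` (L x 3),
#'   `contact_map` (from [contacts_from_coords()] at 8 A), `ss_labels`
#'   (per-residue "H" or "C"), `loop_mask`.
#' @export
generate_toy_structure <- function(L, n_helices = max(3L, round(L / 15)),
                                   max_retries = 25L) {
  if (L < 20L) stop("L must be at least 20")
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  for (attempt in seq_len(max_retries)) {
    seed_state <- get(".Random.seed", envir = globalenv())
    ## segment layout: H1 loop H2 loop ... Hn, helices >= 4 residues
    n_loops <- n_helices - 1L
    loop_lens <- sample(3:6, n_loops, replace = TRUE)
    rem <- L - sum(loop_lens)
    base <- rem %/% n_helices
    helix_lens <- rep(base, n_helices)
    extra <- rem - base * n_helices
    if (extra > 0L) helix_lens[seq_len(extra)] <- helix_lens[seq_len(extra)] + 1L
    if (any(helix_lens < 4L)) {
      loop_lens <- rep(3L, n_loops)
      rem <- L - sum(loop_lens)
      base <- rem %/% n_helices
      helix_lens <- rep(base, n_helices)
      helix_lens[1L] <- helix_lens[1L] + rem - base * n_helices
    }
    R_axis <- 9.5 / (2 * sin(pi / max(n_helices, 2L))) * (1 + 0.04 * (attempt - 1L))
    coords <- matrix(NA_real_, L, 3L)
    labels <- character(L)
    pos <- 1L
    z_cur <- 0
    for (hk in seq_len(n_helices)) {
      theta <- 2 * pi * (hk - 1L) / n_helices
      ax <- R_axis * c(cos(theta), sin(theta))
      dirz <- if (hk %% 2L == 1L) 1 else -1
      phase <- runif(1, 0, 2 * pi)
      hl <- helix_lens[hk]
      for (t in seq_len(hl)) {
        ang <- phase + (t - 1L) * 100 * pi / 180
        coords[pos, ] <- c(ax[1L] + 2.3 * cos(ang), ax[2L] + 2.3 * sin(ang),
                           z_cur + dirz * (t - 1L) * 1.5)
        labels[pos] <- "H"
        pos <- pos + 1L
      }
      z_cur <- z_cur + dirz * (hl - 1L) * 1.5
      if (hk < n_helices) {
        ## loop: outward arc (quadratic Bezier through a control point
        ## outside the bundle) so loops avoid the packed core
        theta2 <- 2 * pi * hk / n_helices
        ax2 <- R_axis * c(cos(theta2), sin(theta2))
        p_from <- coords[pos - 1L, ]
        ll <- loop_lens[hk]
        p_to <- c(ax2[1L] + 2.3, ax2[2L], z_cur)
        mid <- (p_from + p_to) / 2
        rad <- sqrt(sum(mid[1:2]^2))
        ctrl <- c(mid[1:2] * (R_axis + 8) / max(rad, 1e-6),
                  mid[3L] + dirz * 5)
        for (t in seq_len(ll)) {
          frac <- t / (ll + 1L)
          coords[pos, ] <- (1 - frac)^2 * p_from +
            2 * frac * (1 - frac) * ctrl + frac^2 * p_to + rnorm(3L, 0, 0.3)
          labels[pos] <- "C"
          pos <- pos + 1L
        }
      }
    }
    d <- as.matrix(stats::dist(coords))
    far_enough <- TRUE
    sep <- abs(outer(seq_len(L), seq_len(L), "-"))
    if (min(d[sep >= 3]) < 3.5) far_enough <- FALSE
    cm <- contacts_from_coords(coords, 8.0)
    has_long <- any(cm[sep >= 24] == 1)
    if (far_enough && has_long) {
      return(structure(list(length = L, cb_coords = coords, contact_map = cm,
                            ss_labels = labels, loop_mask = labels == "C"),
                       class = "toy_protein"))
    }
  }
  stop("failed to pack a self-avoiding bundle with long-range contacts ",
       "after ", max_retries, " retries (L = ", L, "); RNG state exhausted: ",
       paste(utils::head(seed_state, 3L), collapse = ","))
}

#' Sample an alignment from a contact-coupled sequence model
#'
#' Sequences are drawn from a pairwise (Potts-like) model: independent
#' per-column fields plus, for every contact with |i - j| >= 5, a
#' coupling of size `coupling_strength` favouring one compatible residue
#' pair (in both orientations). Sampling is by Gibbs sweeps, vectorized
#' over sequences (sequences are i.i.d. draws; no phylogeny). Gaps are
#' injected at rate `gap_rate` into loop columns of all rows except the
#' query (row 1).
#'
#' @param protein A [generate_toy_structure()] result.
#' @param n_seqs Number of sequences.
#' @param coupling_strength Coupling energy; 0 gives independent columns.
#' @param n_sweeps Gibbs sweeps per sequence.
#' @param gap_rate Gap injection rate in loop columns.
#' @return An [msa] object (first row = query).
#' @export
sample_coupled_msa <- function(protein, n_seqs, coupling_strength = 1,
                               n_sweeps = 25L, gap_rate = 0.05) {
  stopifnot(n_seqs >= 1L)
  L <- protein$length
  h <- matrix(rnorm(L * 20L, 0, 1), L, 20L)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  pairs <- which(protein$contact_map == 1 & sep >= 5 & upper.tri(sep),
                 arr.ind = TRUE)
  np <- nrow(pairs)
  fav_a <- sample.int(20L, np, replace = TRUE)
  fav_b <- sample.int(20L, np, replace = TRUE)
  partners <- vector("list", L)   # per position: matrix (j, my_state, other_state)
  for (pidx in seq_len(np)) {
    i <- pairs[pidx, 1L]; j <- pairs[pidx, 2L]
    a <- fav_a[pidx]; b <- fav_b[pidx]
    partners[[i]] <- rbind(partners[[i]], c(j, a, b), c(j, b, a))
    partners[[j]] <- rbind(partners[[j]], c(i, b, a), c(i, a, b))
  }

  gumbel <- function(n) -log(-log(runif(n)))
  ## init from fields only
  S <- matrix(0L, n_seqs, L)
  for (i in seq_len(L)) {
    g <- matrix(rep(h[i, ], each = n_seqs), n_seqs, 20L) +
      matrix(gumbel(n_seqs * 20L), n_seqs, 20L)
    S[, i] <- max.col(g, ties.method = "first")
  }
  if (coupling_strength != 0 && np > 0L) {
    for (sweep in seq_len(n_sweeps)) {
      for (i in seq_len(L)) {
        logits <- matrix(rep(h[i, ], each = n_seqs), n_seqs, 20L)
        pt <- partners[[i]]
        if (!is.null(pt)) {
          for (r in seq_len(nrow(pt))) {
            hit <- S[, pt[r, 1L]] == pt[r, 3L]
            logits[hit, pt[r, 2L]] <- logits[hit, pt[r, 2L]] + coupling_strength
          }
        }
        g <- logits + matrix(gumbel(n_seqs * 20L), n_seqs, 20L)
        S[, i] <- max.col(g, ties.method = "first")
      }
    }
  }
  if (gap_rate > 0 && n_seqs > 1L && any(protein$loop_mask)) {
    loop_cols <- which(protein$loop_mask)
    for (i in loop_cols) {
      gap_rows <- which(runif(n_seqs) < gap_rate)
      gap_rows <- gap_rows[gap_rows != 1L]
      S[gap_rows, i] <- GAP_STATE
    }
  }
  structure(list(ids = paste0("synth_", seq_len(n_seqs)), codes = S,
                 N = n_seqs, L = L),
            class = "msa")
}

#' Generate a synthetic protein family with paired deep/shallow MSAs
#'
#' The shallow alignment is a random row subsample of the deep one
#' (query always retained), standing in for a lower-quality alignment of
#' the same protein as the mixup partner.
#'
#' @param L Protein length.
#' @param n_deep,n_shallow Sequence counts (`n_shallow <= n_deep`).
#' @param coupling_strength Contact coupling energy for the sampler.
#' @return A `synthetic_family`: `protein`, `msa_deep`, `msa_shallow`,
#'   `coupling_strength`.
#' @export
make_family <- function(L = 60L, n_deep = 300L, n_shallow = 30L,
                        coupling_strength = 2) {
  stopifnot(n_shallow <= n_deep, n_shallow >= 1L)
  protein <- generate_toy_structure(L)
  deep <- sample_coupled_msa(protein, n_deep, coupling_strength)
  keep <- sort(unique(c(1L, sample(2:n_deep, n_shallow - 1L))))
  shallow <- structure(list(ids = deep$ids[keep],
                            codes = deep$codes[keep, , drop = FALSE],
                            N = length(keep), L = L),
                       class = "msa")
  structure(list(protein = protein, msa_deep = deep, msa_shallow = shallow,
                 coupling_strength = coupling_strength),
            class = "synthetic_family")
}

#' Ground-truth residue features for a synthetic family
#'
#' Profile = weighted empirical column frequencies of the given MSA;
#' ss3 = one-hot true labels smoothed 0.9/0.05/0.05; solvent
#' accessibility = a burial proxy from coordinate centrality (distance
#' from the centroid, min-max scaled to \[0, 1\], buried = 0).
#'
#' @param family A [make_family()] result.
#' @param which_msa `"deep"` or `"shallow"`.
#' @return A [residue_features()] bundle.
#' @export
family_residue_features <- function(family, which_msa = c("deep", "shallow")) {
  which_msa <- match.arg(which_msa)
  m <- if (which_msa == "deep") family$msa_deep else family$msa_shallow
  prot <- family$protein
  stats <- column_stats(m, sequence_weights(m))
  ss3 <- matrix(0.05, prot$length, 3L, dimnames = list(NULL, SS_STATES))
  lab_col <- match(ifelse(prot$ss_labels == "C", "C", prot$ss_labels), SS_STATES)
  ss3[cbind(seq_len(prot$length), lab_col)] <- 0.9
  cen <- colMeans(prot$cb_coords)
  dc <- sqrt(rowSums(sweep(prot$cb_coords, 2L, cen, "-")^2))
  solv <- (dc - min(dc)) / max(max(dc) - min(dc), 1e-9)
  residue_features(stats$f1, ss3, solv, prot$loop_mask)
}

#' Build a training example from a synthetic family
#'
#' Assembles the full 501-channel tensor from the deep alignment (and,
#' optionally, the shallow-alignment tensor as the mixup partner).
#' External coupling maps are zero-filled, as usual for purely synthetic
#' fixtures (no warning here; that choice is deliberate).
#'
#' @param family A [make_family()] result.
#' @param with_alt Attach the shallow-alignment tensor as `x_alt`.
#' @return A [training_example()].
#' @export
family_training_example <- function(family, with_alt = TRUE) {
  build <- function(m, res) {
    stats <- column_stats(m, sequence_weights(m))
    suppressWarnings(assemble_features(m, res, pair_matrices(stats)))
  }
  x <- build(family$msa_deep, family_residue_features(family, "deep"))
  x_alt <- if (with_alt) {
    build(family$msa_shallow, family_residue_features(family, "shallow"))
  } else NULL
  training_example(x, family$protein$contact_map, family$protein$loop_mask,
                   x_alt = x_alt)
}

#' Write a synthetic family to a directory
#'
#' Emits deep and shallow alignments (psicov and fasta dialects), an ss2
#' file, the contact map and coordinates as flat text, and a JSON
#' manifest recording the generation parameters and seed.
#'
#' @param family A [make_family()] result.
#' @param dir Output directory (created if needed).
#' @param seed The seed used to generate the family (recorded only).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_msa(family$msa_deep, file.path(dir, "deep.aln"), "psicov")
  write_msa(family$msa_deep, file.path(dir, "deep.fasta"), "fasta")
  write_msa(family$msa_shallow, file.path(dir, "shallow.aln"), "psicov")
  res <- family_residue_features(family)
  query <- c(AA_ALPHABET, "-")[family$msa_deep$codes[1L, ]]
  write_ss2(query, res$ss3, file.path(dir, "query.ss2"))
  write_matrix_flat(family$protein$contact_map, file.path(dir, "contacts.mat"))
  write.csv(data.frame(family$protein$cb_coords), file.path(dir, "cb_coords.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(L = family$protein$length,
                            n_deep = family$msa_deep$N,
                            n_shallow = family$msa_shallow$N,
                            coupling_strength = family$coupling_strength,
                            seed = seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
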