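# Rigid superposition and the two structural aligners: a TM-score protein
# aligner and an RNA backbone aligner with unit-vector seeding and
# self-normalized scoring, plus the complex structural score and the
# interaction RMSD (IRMSD).

#' Distance scale d0 of the TM-style score
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 angstroms. Requires
#' `L >= 5`.
#'
#' @param l_norm normalization length (number of target residues).
#' @return d0 in angstroms.
#' @export
tm_d0 <- function(l_norm) {
  if (l_norm < 5) stop("normalization length must be >= 5")
  max(0.5, 1.24 * (max(l_norm, 15.5) - 15)^(1/3) - 1.8)
}

# RNA backbone distance scale: C3' spacing (~6 A) is far coarser than
# Calpha spacing, so the RNA aligner uses the RNA-structure-alignment
# convention with a higher floor
rna_d0 <- function(l_norm) {
  if (l_norm < 5) stop("normalization length must be >= 5")
  max(1.25, 0.6 * sqrt(max(l_norm, 1.5) - 0.5) - 2.5)
}

new_rigid_transform <- function(R, t) {
  R <- matrix(as.numeric(R), 3, 3)
  stopifnot(max(abs(R %*% t(R) - diag(3))) < 1e-6, abs(det(R) - 1) < 1e-6)
  structure(list(rotation = R, translation = as.numeric(t)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform a `rigid_transform` (`rotation`, `translation`).
#' @return Transformed n x 3 matrix (`y = R x + t` per row).
#' @export
apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' SVD-based, reflection-corrected rigid transform mapping `coords_a` onto
#' `coords_b`, minimizing the RMSD over matched rows.
#'
#' @param coords_a,coords_b n x 3 matrices of matched points, n >= 3.
#' @return List with `transform` (a `rigid_transform`) and `rmsd`
#'   (angstroms). Degenerate (collinear) inputs are solved but flagged
#'   with attribute `"degenerate"`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  stopifnot(is.matrix(coords_a), is.matrix(coords_b),
            ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  if (nrow(coords_a) < 3) stop("need at least 3 matched points")
  r <- cpp_kabsch(coords_a, coords_b)
  out <- list(transform = new_rigid_transform(r$R, r$t), rmsd = r$rmsd)
  sv <- svd(sweep(coords_a, 2, colMeans(coords_a)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) attr(out, "degenerate") <- TRUE
  out
}

#' Recover the rigid transform relating two copies of the same points
#'
#' Convenience wrapper: `recover_transform(x_out, x_in)` returns the
#' transform mapping `x_in` onto `x_out` (useful to back out the transform
#' an aligner applied to its input).
#'
#' @param coords_out,coords_in matched n x 3 matrices.
#' @return A `rigid_transform`.
#' @export
recover_transform <- function(coords_out, coords_in) {
  kabsch_superpose(coords_in, coords_out)$transform
}

#' TM-score of a fixed residue correspondence
#'
#' `TM = max over superpositions of (1/L) sum_i 1 / (1 + (d_i/d0)^2)`,
#' normalized by the target length `N` and with [tm_d0()] as the distance
#' scale. The maximization uses the standard iterative scheme: sliding
#' fragment seeds followed by re-superposition on the close-pair subset.
#'
#' @param coords_target N x 3 target coordinates (Calpha or C3').
#' @param coords_template M x 3 template coordinates.
#' @param aligned_pairs k x 2 matrix of 1-based (target, template) indices.
#' @param l_norm normalization length; defaults to `N`.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(coords_target, coords_template, aligned_pairs,
                     l_norm = nrow(coords_target)) {
  if (l_norm < 5) stop("normalization length must be >= 5")
  stopifnot(nrow(aligned_pairs) >= 3,
            all(aligned_pairs[, 1] >= 1), all(aligned_pairs[, 1] <= nrow(coords_target)),
            all(aligned_pairs[, 2] >= 1), all(aligned_pairs[, 2] <= nrow(coords_template)))
  a <- coords_target[aligned_pairs[, 1], , drop = FALSE]
  b <- coords_template[aligned_pairs[, 2], , drop = FALSE]
  cpp_tmscore(a, b, l_norm, tm_d0(l_norm))$score
}

new_struct_align <- function(res, l_norm, raw_from_norm = TRUE) {
  pairs <- res$pairs
  colnames(pairs) <- c("target", "template")
  structure(list(
    aligned_pairs = pairs,
    transform = new_rigid_transform(res$R, res$t),
    raw_score = res$score * l_norm,
    normalized_score = res$score,
    rmsd_aligned = res$rmsd_aligned
  ), class = "struct_align")
}

#' @export
print.struct_align <- function(x, ...) {
  cat(sprintf("<struct_align> %d pairs, score %.3f, rmsd(aligned) %.2f A\n",
              nrow(x$aligned_pairs), x$normalized_score, x$rmsd_aligned))
  invisible(x)
}

#' Structural alignment of two protein chains
#'
#' TM-align-style heuristic: gapless threading seeds, then iterative
#' dynamic programming over a TM-score-derived similarity matrix with gap
#' penalty -0.6, re-superposing at each round; the best alignment is
#' re-scored with the full TM-score rotation search. The score is
#' normalized by the target length.
#'
#' @param target,template protein [molecular_chain]s with >= 5 Calpha.
#' @return `struct_align`: `aligned_pairs` (indices into the Calpha
#'   arrays), `transform` mapping target onto the template frame,
#'   `raw_score`, `normalized_score` (= TM-score), `rmsd_aligned`.
#' @export
align_protein <- function(target, template) {
  if (target$kind != "protein" || template$kind != "protein")
    stop("align_protein needs two protein chains")
  a <- rep_coords(target); b <- rep_coords(template)
  if (nrow(a) < 5 || nrow(b) < 5) stop("protein chains must have >= 5 CA atoms")
  l_norm <- nrow(a)
  res <- cpp_struct_align(a, b, l_norm, tm_d0(l_norm), list())
  new_struct_align(res, l_norm)
}

# unit-vector descriptor seed: DP over dot products of consecutive-C3'
# unit vectors in a +-2 window (SARA-style shape fingerprint)
rna_descriptor_seed <- function(a, b) {
  uv <- function(x) {
    d <- diff(x)
    d / sqrt(rowSums(d^2))
  }
  va <- uv(a); vb <- uv(b)
  n <- nrow(va); m <- nrow(vb)
  S <- matrix(0, n, m)
  for (w in -2:2) {
    ia <- seq_len(n) + w; ib <- seq_len(m) + w
    oka <- ia >= 1 & ia <= n; okb <- ib >= 1 & ib <= m
    S[oka, okb] <- S[oka, okb] + tcrossprod(va[ia[oka], , drop = FALSE],
                                            vb[ib[okb], , drop = FALSE])
  }
  cpp_nwdp(S, -1)
}

#' Structural alignment of two RNA chains
#'
#' Backbone (C3') aligner: per-residue unit-vector descriptors from
#' consecutive C3' atoms seed a dynamic-programming alignment, refined by
#' the same iterative superposition scheme as the protein aligner and
#' scored with the TM functional form on C3' atoms. The score is
#' normalized by the raw score of the target aligned to itself (which is
#' the target length), so a self-alignment scores exactly 1. The rigid
#' transform is emitted directly.
#'
#' @param target,template RNA [molecular_chain]s with >= 10 C3' atoms.
#' @return See [align_protein()].
#' @export
align_rna <- function(target, template) {
  if (target$kind != "rna" || template$kind != "rna")
    stop("align_rna needs two RNA chains")
  a <- rep_coords(target); b <- rep_coords(template)
  if (nrow(a) < 10 || nrow(b) < 10) stop("RNA chains must have >= 10 C3' atoms")
  l_norm <- nrow(a)   # raw self-alignment score = target length
  res <- cpp_struct_align(a, b, l_norm, rna_d0(l_norm),
                          list(rna_descriptor_seed(a, b)))
  new_struct_align(res, l_norm)
}

#' Complex structural score
#'
#' The minimum of the protein TM-score and the normalized RNA score - the
#' template ranking criterion.
#'
#' @param tm protein TM-score in `[0,1]`.
#' @param rna_norm normalized RNA score in `[0,1]`.
#' @return List of class `complex_struct_similarity` with `tm_score`,
#'   `rna_score_normalized` and `complex_score = min(tm, rna_norm)`.
#' @export
complex_structural_score <- function(tm, rna_norm) {
  if (!is.finite(tm) || tm < 0 || tm > 1) stop("tm score out of [0,1]")
  if (!is.finite(rna_norm) || rna_norm < 0 || rna_norm > 1)
    stop("rna score out of [0,1]")
  structure(list(tm_score = tm, rna_score_normalized = rna_norm,
                 complex_score = min(tm, rna_norm)),
            class = "complex_struct_similarity")
}

# map alignment indices (into rep-atom arrays) to residue ordinals
align_idx_to_residue <- function(chain, idx) chain$rep_residues[idx]

#' Interaction RMSD between two binary complexes
#'
#' Pools the structurally aligned residue pairs (protein Calpha and RNA
#' C3') whose residue is interfacial in complex `a` or whose partner is
#' interfacial in complex `b`, superposes the pooled set with one joint
#' Kabsch fit, and reports the minimized RMSD. This measures binding-mode
#' similarity between complexes of possibly different monomers. With
#' `pool = FALSE` the superposition is fitted on the protein interface
#' pairs only (the alternative convention) and the RMSD is still measured
#' over all pooled pairs.
#'
#' @param complex_a,complex_b [binary_complex] objects.
#' @param prot_align,rna_align `struct_align` results of aligning the
#'   monomers of `a` (target) onto those of `b` (template).
#' @param pool fit the superposition on the pooled protein+RNA interface
#'   atoms (default) or on the protein side only.
#' @return IRMSD in angstroms, or `NA` (with attribute `"reason"`) when
#'   fewer than 3 pooled interface pairs exist.
#' @export
irmsd <- function(complex_a, complex_b, prot_align, rna_align, pool = TRUE) {
  if (nrow(prot_align$aligned_pairs) == 0 || nrow(rna_align$aligned_pairs) == 0)
    stop("alignments must be non-empty")
  pick <- function(pairs, chain_a, chain_b, int_a, int_b) {
    res_a <- align_idx_to_residue(chain_a, pairs[, 1])
    res_b <- align_idx_to_residue(chain_b, pairs[, 2])
    pairs[res_a %in% int_a | res_b %in% int_b, , drop = FALSE]
  }
  pp <- pick(prot_align$aligned_pairs, complex_a$protein, complex_b$protein,
             complex_a$protein_interface, complex_b$protein_interface)
  rp <- pick(rna_align$aligned_pairs, complex_a$rna, complex_b$rna,
             complex_a$rna_interface, complex_b$rna_interface)
  n_pool <- nrow(pp) + nrow(rp)
  if (n_pool < 3) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 3 pooled interface pairs"
    return(out)
  }
  pa <- rep_coords(complex_a$protein); pb <- rep_coords(complex_b$protein)
  ra <- rep_coords(complex_a$rna); rb <- rep_coords(complex_b$rna)
  xa <- rbind(pa[pp[, 1], , drop = FALSE], ra[rp[, 1], , drop = FALSE])
  xb <- rbind(pb[pp[, 2], , drop = FALSE], rb[rp[, 2], , drop = FALSE])
  if (pool || nrow(pp) < 3) {
    kabsch_superpose(xa, xb)$rmsd
  } else {
    tr <- kabsch_superpose(pa[pp[, 1], , drop = FALSE],
                           pb[pp[, 2], , drop = FALSE])$transform
    d <- apply_transform(xa, tr) - xb
    sqrt(mean(rowSums(d^2)))
  }
}
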