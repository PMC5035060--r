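# Deterministic synthetic structures: toy alpha-helical proteins, ideal
# A-form-like RNA backbones, complexes with planted binding modes, and
# whole libraries with planted redundancy and homolog/decoy structure.
#
# The generator states a small world the pipeline can be tested in
# end-to-end without downloads: rigid helical monomers, a fixed library
# of six well-separated binding modes (three azimuths x two axial slots,
# pairwise ligand-centroid separation >= 30 angstroms), and dummy heavy
# atoms at fixed offsets so interface and clash logic is exercisable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# drift_deg2 adds a quadratic phase drift (degrees per residue^2): a
# seeded per-chain fingerprint that breaks the perfect helix's screw
# symmetry so distinct chains are structurally distinguishable, while
# leaving local geometry (consecutive spacing) essentially unchanged
helix_trace <- function(n, rise, twist_deg, radius, drift_deg2 = 0) {
  k <- seq_len(n) - 1
  th <- (k * twist_deg + drift_deg2 * k^2) * pi / 180
  cbind(radius * cos(th), radius * sin(th), k * rise)
}

# Gentle per-chain bend: progressive hinge rotations about a seeded
# transverse axis. Each hinge rotates the rest of the chain rigidly about
# the hinge point, so all consecutive distances are preserved exactly,
# while the global shape (end-to-end deflection of a few angstroms)
# becomes a chain-specific fingerprint. Without it every synthetic helix
# of a given length is the same rigid body and template ranking is
# degenerate.
bend_trace <- function(trace, seed) {
  par <- with_seed(seed + 29L, list(
    azim = runif(1, 0, 2 * pi),
    kappa = runif(1, 0.02, 0.05) * sample(c(-1, 1), 1),  # deg per residue
    wfreq = runif(1, 0.04, 0.10), wphase = runif(1, 0, 2 * pi)))
  u <- c(cos(par$azim), sin(par$azim), 0)
  rodrigues <- function(ang) {
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  }
  n <- nrow(trace)
  for (i in 2:(n - 1)) {
    ang <- (par$kappa * (1 + 0.3 * sin(par$wfreq * i + par$wphase))) * pi / 180
    R <- rodrigues(ang)
    idx <- (i + 1):n
    trace[idx, ] <- sweep(sweep(trace[idx, , drop = FALSE], 2, trace[i, ]) %*% t(R),
                          2, trace[i, ], "+")
  }
  trace
}

# radial (outward) and tangential unit vectors of a canonical z-axis helix
helix_frames <- function(xyz) {
  u <- cbind(xyz[, 1], xyz[, 2], 0)
  u <- u / sqrt(rowSums(u^2))
  tang <- cbind(-u[, 2], u[, 1], 0)
  list(u = u, t = tang)
}

build_chain_atoms <- function(trace, offsets, rep_name, atom_names,
                              chain_id, kind, resnames, auth_start = 1L) {
  fr <- helix_frames(trace)
  n <- nrow(trace)
  per <- length(atom_names)
  xyz <- matrix(0, n * per, 3)
  for (k in seq_len(per)) {
    o <- offsets[[k]]
    xyz[seq(k, by = per, length.out = n), ] <-
      trace + o[1] * fr$u + o[2] * fr$t + matrix(c(0, 0, o[3]), n, 3, byrow = TRUE)
  }
  molecular_chain(chain_id, kind, resnames,
                  auth_ids = as.character(seq_len(n) + auth_start - 1L),
                  atom_xyz = xyz,
                  atom_names = rep(atom_names, n),
                  atom_res = rep(seq_len(n), each = per))
}

#' Synthetic protein chain
#'
#' Ideal alpha-helical Calpha trace (rise 1.5 angstroms, 100 degrees and
#' radius 2.3 angstroms per residue; consecutive Calpha ~3.8 apart) with
#' three dummy heavy atoms per residue at fixed offsets. The `"hairpin"`
#' fold folds the chain back on itself halfway. Sequence is random but
#' fully determined by `seed`.
#'
#' @param length number of residues (>= 5).
#' @param fold `"helix"` or `"hairpin"`.
#' @param seed integer seed.
#' @param chain_id chain identifier.
#' @return A protein [molecular_chain].
#' @export
make_protein <- function(length, fold = c("helix", "hairpin"), seed = 1,
                         chain_id = "A") {
  fold <- match.arg(fold)
  if (length < 5) stop("protein length must be >= 5")
  drift <- with_seed(seed + 17L, runif(1, 0.002, 0.008) * sample(c(-1, 1), 1))
  trace <- helix_trace(length, 1.5, 100, 2.3, drift)
  if (fold == "hairpin") {
    half <- ceiling(length / 2)
    down <- seq_len(length) > half
    trace[down, 1] <- trace[down, 1] + 5.5
    trace[down, 3] <- trace[half, 3] - (seq_len(sum(down))) * 1.5
  }
  trace <- bend_trace(trace, seed)
  resnames <- with_seed(seed, sample(names(AA3), length, replace = TRUE))
  build_chain_atoms(trace,
                    offsets = list(CA = c(0, 0, 0), CB = c(1.5, 0, 0),
                                   C = c(0.6, 1.2, 0), O = c(1.0, -1.0, 0.3)),
                    rep_name = "CA", atom_names = c("CA", "CB", "C", "O"),
                    chain_id = chain_id, kind = "protein", resnames = resnames)
}

#' Synthetic RNA chain
#'
#' Ideal A-form-like C3' helix (rise 2.8 angstroms, 32.7 degrees per
#' residue, radius 9.4 angstroms; consecutive C3' ~6 apart) with dummy
#' phosphate/sugar/base atoms at fixed radial offsets.
#'
#' @param length number of nucleotides (>= 10).
#' @param seed integer seed.
#' @param chain_id chain identifier.
#' @return An RNA [molecular_chain].
#' @export
make_rna <- function(length, seed = 1, chain_id = "B") {
  if (length < 10) stop("RNA length must be >= 10")
  drift <- with_seed(seed + 23L, runif(1, 0.01, 0.03) * sample(c(-1, 1), 1))
  trace <- helix_trace(length, 2.8, 32.7, 9.4, drift)
  resnames <- with_seed(seed + 104729L, sample(c("A", "C", "G", "U"), length,
                                               replace = TRUE))
  build_chain_atoms(trace,
                    offsets = list(`C3'` = c(0, 0, 0), P = c(1.2, 0.8, 1.0),
                                   `C1'` = c(-2.3, 0.5, 0), N1 = c(-4.5, 0, 0.5)),
                    rep_name = "C3'", atom_names = c("C3'", "P", "C1'", "N1"),
                    chain_id = chain_id, kind = "rna", resnames = resnames)
}

transform_chain <- function(chain, transform) {
  chain$atom_xyz <- apply_transform(chain$atom_xyz, transform)
  chain
}

jitter_chain <- function(chain, sigma, seed) {
  if (sigma <= 0) return(chain)
  chain$atom_xyz <- chain$atom_xyz +
    with_seed(seed, matrix(stats::rnorm(length(chain$atom_xyz), 0, sigma),
                           ncol = 3))
  chain
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# The fixed binding-mode library: azimuth (deg), axial offset (angstroms)
# and a spin of the RNA about its own axis. Modes 1-3 differ pairwise by
# 30 A in axial offset: a rotation about the protein helix axis cannot
# compensate an axial shift, so their mutual IRMSD is far above the
# 5 A binding-mode-similarity threshold by construction. Modes 4-6 share
# the axial slots but flip the azimuth by 180 deg; they are used as
# binding modes that the template library does not contain.
BINDING_MODES <- data.frame(
  mode = 1:6,
  azimuth = c(0, 120, 240, 180, 300, 60),
  z_slot = rep(c(-30, 0, 30), 2),
  spin = (0:5) * 60
)

# rigid transform placing a canonical RNA helix into a binding mode next to
# a canonical z-axis protein helix; the axis separation is found
# deterministically: the smallest clash-free distance that still leaves
# enough interface residues (interfaces shrink as the axes separate, so
# the closest clash-free geometry has the largest interface)
place_rna_mode <- function(protein, rna, mode, min_iface = 5) {
  m <- BINDING_MODES[BINDING_MODES$mode == mode, ]
  if (nrow(m) != 1) stop("unknown binding mode ", mode)
  z0 <- (max(protein$atom_xyz[, 3]) + min(protein$atom_xyz[, 3])) / 2 -
    (max(rna$atom_xyz[, 3]) + min(rna$atom_xyz[, 3])) / 2 + m$z_slot
  spin <- rot_z(m$spin)
  # the canonical azimuth and axial offset may be nudged slightly when
  # the discrete side-chain pattern starves the contact; the nudges are
  # small against the >= 30 A axial separation between modes
  az_offsets <- c(0, as.vector(rbind(seq(5, 45, 5), -seq(5, 45, 5))))
  for (z_off in c(0, 3, -3, 6, -6)) {
    for (az_off in az_offsets) {
      az <- (m$azimuth + az_off) * pi / 180
      dir <- c(cos(az), sin(az), 0)
      for (clash in seq(2.5, 1.0, by = -0.5)) {
        for (d_axis in seq(12, 24, by = 0.25)) {
          tr <- new_rigid_transform(spin, d_axis * dir + c(0, 0, z0 + z_off))
          cand <- transform_chain(rna, tr)
          if (cpp_count_close(protein$atom_xyz, cand$atom_xyz, clash) > 0) next
          iface <- detect_interface(protein, cand)
          if (length(iface$protein_interface) >= min_iface &&
              length(iface$rna_interface) >= min_iface)
            return(list(transform = tr, d_axis = d_axis))
        }
      }
    }
  }
  stop("no clash-free contact geometry found for mode ", mode)
}

#' Fixture specification for a synthetic complex pair
#'
#' @param seed integer seed driving every random choice.
#' @param protein_length,rna_length monomer sizes.
#' @param binding_mode_id binding mode of complex A (1..6).
#' @param binding_mode_b binding mode of complex B; defaults to the same
#'   mode.
#' @param noise_sigma per-coordinate Gaussian noise (angstroms) applied to
#'   complex B.
#' @param perturbation_rmsd rigid displacement (angstroms) of B's RNA
#'   within its binding mode; the expected ligand RMSD of template-based
#'   recovery.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, protein_length = 100, rna_length = 30,
                         binding_mode_id = 1, binding_mode_b = binding_mode_id,
                         noise_sigma = 0, perturbation_rmsd = 0) {
  stopifnot(perturbation_rmsd >= 0, noise_sigma >= 0,
            binding_mode_id %in% 1:6, binding_mode_b %in% 1:6)
  structure(list(seed = seed, protein_length = protein_length,
                 rna_length = rna_length, binding_mode_id = binding_mode_id,
                 binding_mode_b = binding_mode_b, noise_sigma = noise_sigma,
                 perturbation_rmsd = perturbation_rmsd),
            class = "fixture_spec")
}

make_one_complex <- function(pdb_id, protein, rna, mode, resolution,
                             deposit_date, sigma = 0, perturbation = 0,
                             seed = 1, min_iface = 5) {
  pl <- place_rna_mode(protein, rna, mode, min_iface)
  rna_placed <- transform_chain(rna, pl$transform)
  if (perturbation > 0) {
    dir <- with_seed(seed + 7L, stats::rnorm(3))
    dir <- dir / sqrt(sum(dir^2))
    rna_placed$atom_xyz <- sweep(rna_placed$atom_xyz, 2, perturbation * dir, "+")
  }
  protein <- jitter_chain(protein, sigma, seed + 11L)
  rna_placed <- jitter_chain(rna_placed, sigma, seed + 13L)
  bc <- binary_complex(pdb_id, protein, rna_placed, resolution, deposit_date)
  attr(bc, "placement") <- pl
  bc
}

#' Synthetic complex pair with known ground truth
#'
#' Complex A is a protein/RNA pair docked in `binding_mode_id`; complex B
#' uses the same monomers, optionally in a different mode, with optional
#' coordinate noise and a rigid RNA displacement of known size. Binding
#' modes are pairwise >= 30 angstroms apart in RNA centroid position, so
#' same-mode pairs have IRMSD near 0 and different-mode pairs have IRMSD
#' far above the 5-angstrom similarity threshold.
#'
#' @param spec a [fixture_spec()].
#' @return List with `a`, `b` ([binary_complex]es) and `ground_truth`
#'   (`same_mode`, the placement transforms, `noise_sigma`, and
#'   `expected_ligand_rmsd` for template-based recovery of A on B).
#' @export
make_complex_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  prot <- make_protein(spec$protein_length, seed = spec$seed)
  rna <- make_rna(spec$rna_length, seed = spec$seed)
  a <- make_one_complex("syna", prot, rna, spec$binding_mode_id,
                        resolution = 2.0, deposit_date = as.Date("2001-01-01"),
                        seed = spec$seed)
  b <- make_one_complex("synb", prot, rna, spec$binding_mode_b,
                        resolution = 2.5, deposit_date = as.Date("2005-01-01"),
                        sigma = spec$noise_sigma,
                        perturbation = spec$perturbation_rmsd,
                        seed = spec$seed + 1000L)
  list(a = a, b = b, ground_truth = list(
    same_mode = spec$binding_mode_id == spec$binding_mode_b,
    transform_a = attr(a, "placement")$transform,
    transform_b = attr(b, "placement")$transform,
    noise_sigma = spec$noise_sigma,
    expected_ligand_rmsd = spec$perturbation_rmsd))
}

#' Synthetic complex library with planted structure
#'
#' Generates `n_complexes` distinct complexes (varying lengths, binding
#' modes cycling over the mode library) plus `duplicate_groups` planted
#' triplets sharing one RNA (identical sequence and structure, differing
#' resolutions) for redundancy-clustering tests. Deposit dates ascend with
#' the complex index. When `dir` is given, every complex is written as a
#' standard PDB file with HEADER/REMARK 2 metadata, together with a
#' `truth.tsv` manifest.
#'
#' @param n_complexes number of distinct base complexes (>= 2).
#' @param duplicate_groups number of planted duplicate triplets.
#' @param seed integer seed.
#' @param dir optional output directory for PDB files.
#' @return List with `complexes` (list of [binary_complex]), `truth`
#'   (data.frame: id, group, binding mode, resolution, date, duplicate
#'   flag) and `dir`.
#' @export
make_library <- function(n_complexes, duplicate_groups = 0, seed = 1,
                         dir = NULL) {
  if (n_complexes < 2) stop("need at least 2 complexes")
  complexes <- list()
  truth <- NULL
  idx <- 0L
  add <- function(bc, group, dup) {
    idx <<- idx + 1L
    complexes[[idx]] <<- bc
    truth <<- rbind(truth, data.frame(
      id = bc$id, pdb_id = bc$pdb_id, group = group,
      mode = attr(bc, "mode"), resolution = bc$resolution,
      deposit_date = format(bc$deposit_date), duplicate = dup))
  }
  date0 <- as.Date("2000-01-01")
  rlens <- integer(n_complexes)
  for (i in seq_len(n_complexes)) {
    si <- seed + i * 131L
    plen <- 100 + (with_seed(si, sample.int(16, 1)) - 1)        # 100..115
    rlens[i] <- 26 + (with_seed(si + 1L, sample.int(7, 1)) - 1) # 26..32
    mode <- ((i - 1) %% 3) + 1
    prot <- make_protein(plen, seed = si)
    rna <- make_rna(rlens[i], seed = si)
    bc <- make_one_complex(sprintf("s%03d", i), prot, rna, mode,
                           resolution = round(1.5 + ((i * 7) %% 14) / 10, 1),
                           deposit_date = date0 + i * 100L, seed = si)
    attr(bc, "mode") <- mode
    add(bc, group = i, dup = FALSE)
  }
  if (duplicate_groups > 0) {
    for (g in seq_len(duplicate_groups)) {
      # regenerate the canonical (unplaced) RNA of base complex g
      base_rna <- make_rna(rlens[g], seed = seed + g * 131L)
      for (k in 1:2) {   # two extra members -> planted triplet with base
        idn <- sprintf("d%02d%d", g, k)
        prot <- make_protein(105, seed = seed + 9000L + g * 10L + k)
        bc <- make_one_complex(idn, prot, base_rna, ((g + k) %% 3) + 1,
                               resolution = 2.0 + 0.45 * k,
                               deposit_date = date0 + 4000L + g * 50L + k,
                               seed = seed + 9000L + g * 10L + k)
        attr(bc, "mode") <- ((g + k) %% 3) + 1
        add(bc, group = g, dup = TRUE)
      }
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (bc in complexes) {
      write_pdb(list(bc$protein, bc$rna),
                file.path(dir, paste0(bc$pdb_id, ".pdb")),
                header = list(pdb_id = bc$pdb_id, resolution = bc$resolution,
                              deposit_date = bc$deposit_date))
    }
    write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  list(complexes = complexes, truth = truth, dir = dir)
}

#' Synthetic benchmark set with planted templates
#'
#' Twenty (by default) target complexes: `n_good` of them have a planted
#' good template in the library (a noisy copy of the target, same binding
#' mode, noise far below the acceptable-model threshold); the rest use
#' binding modes absent from the library and RNAs long enough that no
#' library template can reach the score cutoff or produce an acceptable
#' model. A handful of small decoy complexes pads the library.
#'
#' @param n_targets number of targets.
#' @param n_good targets with a planted good template.
#' @param seed integer seed.
#' @return List with `targets`, `library` (lists of [binary_complex]) and
#'   `truth` (data.frame with `target_id`, `has_template`,
#'   `template_id`).
#' @export
make_benchmark_set <- function(n_targets = 20, n_good = 12, seed = 1) {
  stopifnot(n_good <= n_targets)
  targets <- list()
  lib <- list()
  truth <- NULL
  date0 <- as.Date("2000-01-01")
  for (i in seq_len(n_targets)) {
    si <- seed + i * 977L
    good <- i <= n_good
    plen <- if (good) 100 + ((i * 3) %% 15) else 135
    # template-less targets carry an RNA longer than any library RNA by
    # more than the cutoff ratio: normalized RNA score <= 32/72 < 0.45,
    # so no template can pass the score cutoff for them
    rlen <- if (good) 28 + (i %% 5) else 72 + (i %% 4) * 2
    mode <- if (good) ((i - 1) %% 3) + 1 else 5
    prot <- make_protein(plen, seed = si)
    rna <- make_rna(rlen, seed = si)
    tgt <- make_one_complex(sprintf("t%03d", i), prot, rna, mode,
                            resolution = 2.0, deposit_date = date0 + 6000 + i,
                            seed = si)
    targets[[i]] <- tgt
    tpl_id <- NA_character_
    if (good) {
      tpl_id <- sprintf("p%03d", i)
      tpl <- make_one_complex(tpl_id, prot, rna, mode, resolution = 2.2,
                              deposit_date = date0 + i, sigma = 0.3,
                              seed = si + 5L)
      lib[[length(lib) + 1L]] <- tpl
    }
    truth <- rbind(truth, data.frame(target_id = tgt$id, has_template = good,
                                     template_id = tpl_id))
  }
  for (k in seq_len(6)) {  # small decoys: bounded scores against every target
    sk <- seed + 33000L + k * 13L
    prot <- make_protein(70, seed = sk)
    rna <- make_rna(12 + k %% 3, seed = sk)
    lib[[length(lib) + 1L]] <- make_one_complex(sprintf("d%03d", k), prot, rna,
                                                ((k - 1) %% 3) + 1,
                                                resolution = 2.5,
                                                deposit_date = date0 + 500 + k,
                                                seed = sk, min_iface = 2)
  }
  list(targets = targets, library = lib, truth = truth)
}
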