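# The template-based docking pipeline: template search and ranking,
# rigid model building by superposition, and model evaluation.

#' Search a template library for a target complex
#'
#' Aligns the target protein to every template protein (TM-score) and the
#' target RNA to every template RNA (normalized backbone score), computes
#' the complex structural score (the minimum of the two), and ranks the
#' hits by the chosen score, descending (ties broken by template id). A
#' template with the same id as the target is never used.
#'
#' @param target a [binary_complex]; protein needs >= 5 Calpha, RNA >= 10
#'   C3'.
#' @param library a `complex_library` or list of template
#'   [binary_complex]es (non-empty).
#' @param ranking `"complex_score"` (default) or `"tm_score"`.
#' @param cutoff score cutoff marking `passes_cutoff` (default 0.45, the
#'   transition point between random and shared binding modes).
#' @return data.frame of class `template_hits`, one row per admissible
#'   template: `template_id`, `tm_score`, `rna_score`, `complex_score`,
#'   `rank` (1..k, no gaps), `passes_cutoff`. Templates skipped for
#'   admissibility are listed in attribute `"skipped"`. The alignments of
#'   each hit are kept in attribute `"alignments"` (keyed by template id)
#'   so models can be built without re-aligning.
#' @export
search_templates <- function(target, library,
                             ranking = c("complex_score", "tm_score"),
                             cutoff = 0.45) {
  ranking <- match.arg(ranking)
  templates <- if (inherits(library, "complex_library")) library$complexes else library
  if (!length(templates)) stop("empty template library")
  if (target$protein$length < 5) stop("target protein has fewer than 5 CA atoms")
  if (target$rna$length < 10) stop("target RNA has fewer than 10 C3' atoms")
  rows <- list()
  aligns <- list()
  skipped <- character()
  for (tpl in templates) {
    if (tpl$id == target$id) next
    if (tpl$protein$length < 5 || tpl$rna$length < 10) {
      skipped <- c(skipped, sprintf("%s: template below minimum monomer length",
                                    tpl$id))
      next
    }
    ap <- align_protein(target$protein, tpl$protein)
    ar <- align_rna(target$rna, tpl$rna)
    s <- complex_structural_score(min(1, ap$normalized_score),
                                  min(1, ar$normalized_score))
    rows[[length(rows) + 1L]] <- data.frame(
      template_id = tpl$id, tm_score = s$tm_score, rna_score = s$rna_score_normalized,
      complex_score = s$complex_score)
    aligns[[tpl$id]] <- list(protein = ap, rna = ar, template = tpl)
  }
  if (!length(rows)) {
    out <- data.frame(template_id = character(), tm_score = numeric(),
                      rna_score = numeric(), complex_score = numeric(),
                      rank = integer(), passes_cutoff = logical())
  } else {
    out <- do.call(rbind, rows)
    o <- order(-out[[ranking]], out$template_id)
    out <- out[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    out$passes_cutoff <- out$complex_score >= cutoff
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  attr(out, "alignments") <- aligns
  attr(out, "ranking") <- ranking
  class(out) <- c("template_hits", "data.frame")
  out
}

#' Build a rigid-body model from a template
#'
#' Applies the protein alignment's transform to every target protein atom
#' and the RNA alignment's transform to every target RNA atom, placing
#' both target monomers in the template frame.
#'
#' @param target,template [binary_complex] objects.
#' @param prot_align,rna_align `struct_align` results of aligning the
#'   target monomers onto the template monomers (must carry transforms).
#' @return Object of class `complex_model`: transformed `protein` and
#'   `rna` chains, `template_id`, `transforms`, and `ligand_rmsd` /
#'   `quality` slots filled by [ligand_rmsd()] / [classify_quality()].
#' @export
build_model <- function(target, template, prot_align, rna_align) {
  if (is.null(prot_align$transform) || is.null(rna_align$transform))
    stop("alignments must carry rigid transforms")
  structure(list(
    protein = transform_chain(target$protein, prot_align$transform),
    rna = transform_chain(target$rna, rna_align$transform),
    target_id = target$id, template_id = template$id,
    transforms = list(protein = prot_align$transform, rna = rna_align$transform),
    scores = list(tm_score = prot_align$normalized_score,
                  rna_score = rna_align$normalized_score,
                  complex_score = min(prot_align$normalized_score,
                                      rna_align$normalized_score)),
    ligand_rmsd = NA_real_, quality = "unknown"
  ), class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model %s on %s> complex score %.3f, ligand RMSD %s, %s\n",
              x$target_id, x$template_id, x$scores$complex_score,
              ifelse(is.na(x$ligand_rmsd), "?", sprintf("%.2f A", x$ligand_rmsd)),
              x$quality))
  invisible(x)
}

#' Ligand RMSD of a model against the native complex
#'
#' Superposes the model protein Calpha trace onto the native protein
#' (Kabsch over the 1:1 residue correspondence - model and native share
#' the same chains), applies that transform to the whole model, and
#' reports the RMSD over RNA C3' atoms. This is the receptor-frame
#' "ligand RMSD" convention of rigid docking.
#'
#' @param model a `complex_model`.
#' @param native the native [binary_complex] of the same target.
#' @return Ligand RMSD in angstroms.
#' @export
ligand_rmsd <- function(model, native) {
  pm <- rep_coords(model$protein); pn <- rep_coords(native$protein)
  rm_ <- rep_coords(model$rna); rn <- rep_coords(native$rna)
  if (nrow(pm) != nrow(pn) || nrow(rm_) != nrow(rn))
    stop("model and native do not share the same residue sets")
  tr <- kabsch_superpose(pm, pn)$transform
  d <- apply_transform(rm_, tr) - rn
  sqrt(mean(rowSums(d^2)))
}

#' Docking model quality class from ligand RMSD
#'
#' Nested classes: `high` (<= 2 angstroms), `medium` (<= 5), `acceptable`
#' (<= 10), `incorrect` (> 10).
#'
#' @param ligand_rmsd nonnegative RMSD in angstroms.
#' @return The innermost class as a string.
#' @export
classify_quality <- function(ligand_rmsd) {
  if (!is.finite(ligand_rmsd) || ligand_rmsd < 0) stop("ligand RMSD must be >= 0")
  if (ligand_rmsd < 2) "high"
  else if (ligand_rmsd <= 5) "medium"
  else if (ligand_rmsd <= 10) "acceptable"
  else "incorrect"
}

quality_at_least <- function(quality, class) {
  lv <- c(incorrect = 0, acceptable = 1, medium = 2, high = 3)
  lv[quality] >= lv[class]
}

#' Evaluate a model against its native structure
#'
#' Fills `ligand_rmsd` and `quality`.
#'
#' @param model a `complex_model`.
#' @param native the native [binary_complex].
#' @return The model with evaluation slots filled.
#' @export
evaluate_model <- function(model, native) {
  model$ligand_rmsd <- ligand_rmsd(model, native)
  model$quality <- classify_quality(model$ligand_rmsd)
  model
}

#' Count inter-molecular heavy-atom clashes in a model
#'
#' Number of protein/RNA heavy-atom pairs at distance strictly below
#' `clash_cutoff`.
#'
#' @param model a `complex_model` (or [binary_complex]).
#' @param clash_cutoff angstroms (default 3.0).
#' @return Integer clash count.
#' @export
count_clashes <- function(model, clash_cutoff = 3.0) {
  cpp_count_close(model$protein$atom_xyz, model$rna$atom_xyz, clash_cutoff)
}

#' Benchmark template-based docking on a target set
#'
#' For every target, searches the library, builds a model from each hit
#' that passes the score cutoff, evaluates the ligand RMSD against the
#' target's own (native) structure, and summarizes success rates: a
#' target is a success at N if at least one of its top-N models reaches
#' the quality class. Targets without any hit passing the cutoff count as
#' failures; success rates are reported both over all targets and over
#' the targets with at least one usable template.
#'
#' @param targets list of [binary_complex] targets with native
#'   coordinates.
#' @param library template `complex_library` or list.
#' @param ranking,cutoff see [search_templates()].
#' @param top_n_max deepest N reported (default 10).
#' @return Object of class `benchmark_summary`: `per_target` (best model
#'   per target), `success` (data.frame: N, class, rate over all targets,
#'   rate over covered targets), `coverage` (fraction of targets with >=
#'   1 passing template), and `histogram` (best-model ligand RMSD in
#'   2-angstrom bins).
#' @export
benchmark <- function(targets, library, ranking = c("complex_score", "tm_score"),
                      cutoff = 0.45, top_n_max = 10) {
  ranking <- match.arg(ranking)
  per_target <- list()
  model_rmsds <- list()
  for (tgt in targets) {
    hits <- search_templates(tgt, library, ranking, cutoff)
    hits_ok <- hits[hits$passes_cutoff, , drop = FALSE]
    aligns <- attr(hits, "alignments")
    rmsds <- numeric(0)
    if (nrow(hits_ok)) {
      use <- hits_ok[seq_len(min(top_n_max, nrow(hits_ok))), , drop = FALSE]
      rmsds <- vapply(use$template_id, function(tid) {
        al <- aligns[[tid]]
        m <- build_model(tgt, al$template, al$protein, al$rna)
        ligand_rmsd(m, tgt)
      }, 1.0)
    }
    model_rmsds[[tgt$id]] <- rmsds
    per_target[[length(per_target) + 1L]] <- data.frame(
      target_id = tgt$id,
      n_templates = nrow(hits_ok),
      best_rank = if (length(rmsds)) which.min(rmsds)[1] else NA_integer_,
      best_ligand_rmsd = if (length(rmsds)) min(rmsds) else NA_real_,
      best_quality = if (length(rmsds)) classify_quality(min(rmsds)) else "unknown")
  }
  per_target <- do.call(rbind, per_target)
  n_tot <- nrow(per_target)
  covered <- per_target$n_templates > 0
  success <- do.call(rbind, lapply(c("acceptable", "medium", "high"), function(cl) {
    thr <- c(acceptable = 10, medium = 5, high = 2)[[cl]]
    do.call(rbind, lapply(seq_len(top_n_max), function(N) {
      ok <- vapply(model_rmsds, function(r)
        length(r) > 0 && {
          rr <- r[seq_len(min(N, length(r)))]
          if (cl == "high") any(rr < thr) else any(rr <= thr)
        }, TRUE)
      data.frame(N = N, class = cl, rate = mean(ok),
                 rate_covered = if (any(covered)) mean(ok[covered]) else NA_real_)
    }))
  }))
  br <- per_target$best_ligand_rmsd[!is.na(per_target$best_ligand_rmsd)]
  edges <- seq(0, max(20, 2 * ceiling(max(c(br, 0)) / 2) + 2), by = 2)
  hist <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                     count = vapply(seq_len(length(edges) - 1), function(k)
                       sum(br >= edges[k] & br < edges[k + 1]), 1L))
  structure(list(per_target = per_target, success = success,
                 coverage = mean(covered), histogram = hist,
                 ranking = ranking, cutoff = cutoff),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> %d targets, coverage %.2f, ranking %s (cutoff %.2f)\n",
              nrow(x$per_target), x$coverage, x$ranking, x$cutoff))
  s <- x$success
  for (cl in unique(s$class)) {
    r <- s[s$class == cl, ]
    cat(sprintf("  %-10s success@1 %.2f  @5 %.2f  @10 %.2f\n", cl,
                r$rate[r$N == 1], r$rate[r$N == min(5, max(r$N))],
                r$rate[r$N == max(r$N)]))
  }
  invisible(x)
}

#' Write a complex model as a PDB file
#'
#' Protein as chain A, RNA as chain B, with REMARK lines recording the
#' template id and the scores.
#'
#' @param model a `complex_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  p <- model$protein; p$chain_id <- "A"
  r <- model$rna; r$chain_id <- "B"
  write_pdb(list(p, r), path, remarks = c(
    sprintf("TEMPLATE %s", model$template_id),
    sprintf("TM-SCORE %.4f RNA-SCORE %.4f COMPLEX-SCORE %.4f",
            model$scores$tm_score, model$scores$rna_score,
            model$scores$complex_score)))
}
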