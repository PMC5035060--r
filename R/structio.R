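# Binary-complex extraction: interface detection and admissibility filters.

#' Detect interface residues between a protein and an RNA chain
#'
#' A residue is interfacial iff any of its heavy atoms lies strictly
#' within `cutoff` of any heavy atom of the partner chain. Computed with a
#' uniform spatial grid (O(N) expected); a brute-force all-pairs scan is
#' used as the test oracle.
#'
#' @param protein,rna [molecular_chain] objects.
#' @param cutoff distance cutoff in angstroms (default 5, strict `<`).
#' @return List with integer vectors `protein_interface` and
#'   `rna_interface` of 1-based residue ordinals.
#' @export
detect_interface <- function(protein, rna, cutoff = 5.0) {
  stopifnot(nrow(protein$atom_xyz) > 0L, nrow(rna$atom_xyz) > 0L)
  r <- cpp_interface(protein$atom_xyz, protein$atom_res,
                     rna$atom_xyz, rna$atom_res, cutoff)
  list(protein_interface = sort(r$a), rna_interface = sort(r$b))
}

#' Construct a binary complex
#'
#' One protein chain plus one RNA chain with precomputed 5-angstrom
#' interface residue sets.
#'
#' @param pdb_id entry identifier (lowercase by convention).
#' @param protein,rna [molecular_chain] objects of the matching kind.
#' @param resolution crystallographic resolution in angstroms, or `NA`.
#' @param deposit_date a `Date`, or `NA`.
#' @return Object of class `binary_complex` with an `id` of the form
#'   `<pdb_id>_<protein chain><rna chain>`.
#' @export
binary_complex <- function(pdb_id, protein, rna, resolution = NA_real_,
                           deposit_date = as.Date(NA)) {
  stopifnot(protein$kind == "protein", rna$kind == "rna")
  iface <- detect_interface(protein, rna)
  structure(list(
    pdb_id = pdb_id, protein = protein, rna = rna,
    resolution = resolution, deposit_date = as.Date(deposit_date),
    protein_interface = iface$protein_interface,
    rna_interface = iface$rna_interface,
    id = paste0(pdb_id, "_", protein$chain_id, rna$chain_id)
  ), class = "binary_complex")
}

#' @export
print.binary_complex <- function(x, ...) {
  cat(sprintf("<binary_complex %s> protein %s (%d aa) + RNA %s (%d nt), interface %d/%d, %s A\n",
              x$id, x$protein$chain_id, x$protein$length,
              x$rna$chain_id, x$rna$length,
              length(x$protein_interface), length(x$rna_interface),
              ifelse(is.na(x$resolution), "?", format(x$resolution))))
  invisible(x)
}

#' Extract admissible binary complexes from the chains of one entry
#'
#' Pairs every protein chain with every RNA chain and keeps pairs passing
#' all admissibility filters: resolution <= 3.0 angstroms (absent
#' resolution rejects the whole entry), protein length >= 30, RNA length
#' >= 20, and at least 5 interfacial residues on each side at the
#' 5-angstrom heavy-atom cutoff.
#'
#' @param chains list of [molecular_chain]s from one entry
#'   (e.g. [read_structure()] output).
#' @param meta list with `pdb_id`, `resolution`, `deposit_date`; defaults
#'   to the `"meta"` attribute of `chains`.
#' @return List of [binary_complex] objects. Attribute `"rejections"` is a
#'   data.frame recording every rejected pair and the first filter it
#'   failed (`no_resolution`, `resolution_too_low`, `protein_too_short`,
#'   `rna_too_short`, `protein_interface_too_small`,
#'   `rna_interface_too_small`).
#' @export
extract_binary_complexes <- function(chains, meta = attr(chains, "meta")) {
  if (is.null(meta)) meta <- list(pdb_id = "xxxx", resolution = NA_real_,
                                  deposit_date = as.Date(NA))
  prots <- Filter(function(ch) ch$kind == "protein", chains)
  rnas <- Filter(function(ch) ch$kind == "rna", chains)
  # deterministic, order-independent output: sort by chain id
  prots <- prots[order(vapply(prots, `[[`, "", "chain_id"))]
  rnas <- rnas[order(vapply(rnas, `[[`, "", "chain_id"))]
  out <- list()
  rej <- data.frame(pdb_id = character(), protein_chain = character(),
                    rna_chain = character(), reason = character())
  note <- function(p, r, why) rbind(rej, data.frame(
    pdb_id = meta$pdb_id, protein_chain = p, rna_chain = r, reason = why))
  for (p in prots) for (r in rnas) {
    reason <- NULL
    if (is.na(meta$resolution)) reason <- "no_resolution"
    else if (meta$resolution > 3.0) reason <- "resolution_too_low"
    else if (p$length < 30L) reason <- "protein_too_short"
    else if (r$length < 20L) reason <- "rna_too_short"
    if (is.null(reason)) {
      bc <- binary_complex(meta$pdb_id, p, r, meta$resolution, meta$deposit_date)
      if (length(bc$protein_interface) < 5L) reason <- "protein_interface_too_small"
      else if (length(bc$rna_interface) < 5L) reason <- "rna_interface_too_small"
      if (is.null(reason)) { out[[length(out) + 1L]] <- bc; next }
    }
    rej <- note(p$chain_id, r$chain_id, reason)
  }
  attr(out, "rejections") <- rej
  out
}

#' Per-entry complex manifest
#'
#' Flattens accepted complexes and rejections into one TSV-ready table.
#'
#' @param complexes output of [extract_binary_complexes()].
#' @param path optional file; when given the table is written as TSV.
#' @return The manifest data.frame, invisibly when `path` is given.
#' @export
complex_manifest <- function(complexes, path = NULL) {
  ok <- if (length(complexes)) do.call(rbind, lapply(complexes, function(b) data.frame(
    pdb_id = b$pdb_id, protein_chain = b$protein$chain_id,
    rna_chain = b$rna$chain_id, protein_length = b$protein$length,
    rna_length = b$rna$length,
    protein_interface = length(b$protein_interface),
    rna_interface = length(b$rna_interface),
    resolution = b$resolution,
    deposit_date = format(b$deposit_date),
    status = "pass", reason = ""))) else NULL
  rej <- attr(complexes, "rejections")
  if (!is.null(rej) && nrow(rej)) {
    rej2 <- data.frame(pdb_id = rej$pdb_id, protein_chain = rej$protein_chain,
                       rna_chain = rej$rna_chain, protein_length = NA_integer_,
                       rna_length = NA_integer_, protein_interface = NA_integer_,
                       rna_interface = NA_integer_, resolution = NA_real_,
                       deposit_date = NA_character_, status = "fail",
                       reason = rej$reason)
    ok <- rbind(ok, rej2)
  }
  if (is.null(ok)) ok <- data.frame()
  if (!is.null(path)) {
    write_tsv(ok, path)
    return(invisible(ok))
  }
  ok
}

# fixed-format TSV writer shared by all table outputs (deterministic bytes)
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
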