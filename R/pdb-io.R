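# PDB / mmCIF reading and writing.
#
# No R package in the dependency stack parses macromolecular coordinate
# files, so a focused reader lives here: fixed-column PDB ATOM/HETATM
# records (plus HEADER / REMARK 2 metadata) and the atom_site loop of
# mmCIF. Only what the pipeline needs is retained: heavy atoms grouped by
# chain and residue, representative backbone atoms, and sequences.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
RNA1 <- c(A = "A", C = "C", G = "G", U = "U")
WATERS <- c("HOH", "DOD", "WAT", "H2O")

res_letter <- function(resname, kind) {
  if (kind == "protein") {
    l <- AA3[resname]
    ifelse(is.na(l), "X", l)
  } else {
    l <- RNA1[resname]
    ifelse(is.na(l), "N", l)
  }
}

#' Construct a molecular chain
#'
#' Low-level constructor used by the readers and the synthetic-structure
#' generator. Atoms are heavy atoms only; the representative atom (Calpha
#' for proteins, C3' for RNA) defines the alignment coordinate array and
#' the chain `length`. Residues without a representative atom stay in the
#' heavy-atom set (they still count for interface detection) but carry no
#' sequence letter.
#'
#' @param chain_id single-character chain identifier.
#' @param kind `"protein"` or `"rna"`.
#' @param resnames residue names in file order.
#' @param auth_ids author residue ids (number + insertion code), same length.
#' @param atom_xyz numeric matrix (heavy atoms x 3), angstroms.
#' @param atom_names atom name per row of `atom_xyz`.
#' @param atom_res 1-based residue ordinal per row of `atom_xyz`.
#' @return An object of class `molecular_chain`.
#' @export
molecular_chain <- function(chain_id, kind, resnames, auth_ids,
                            atom_xyz, atom_names, atom_res) {
  kind <- match.arg(kind, c("protein", "rna"))
  stopifnot(is.matrix(atom_xyz), ncol(atom_xyz) == 3,
            length(atom_names) == nrow(atom_xyz),
            length(atom_res) == nrow(atom_xyz),
            length(auth_ids) == length(resnames))
  if (nrow(atom_xyz) > 0L && !all(is.finite(atom_xyz)))
    stop("non-finite coordinates in chain ", chain_id)
  rep_name <- if (kind == "protein") "CA" else "C3'"
  n_res <- length(resnames)
  rep_atom_idx <- rep(NA_integer_, n_res)
  hit <- which(atom_names == rep_name)
  # first representative atom per residue wins (altlocs resolved upstream)
  for (i in rev(hit)) rep_atom_idx[atom_res[i]] <- i
  has_rep <- !is.na(rep_atom_idx)
  seq_letters <- res_letter(resnames[has_rep], kind)
  structure(list(
    chain_id = chain_id, kind = kind,
    resnames = resnames, auth_ids = auth_ids,
    atom_xyz = atom_xyz, atom_names = atom_names, atom_res = as.integer(atom_res),
    rep_atom_idx = rep_atom_idx,
    rep_residues = which(has_rep),
    sequence = paste0(seq_letters, collapse = ""),
    length = sum(has_rep)
  ), class = "molecular_chain")
}

#' @export
print.molecular_chain <- function(x, ...) {
  cat(sprintf("<molecular_chain %s> %s, %d residues (%d with %s), %d heavy atoms\n",
              x$chain_id, x$kind, length(x$resnames), x$length,
              if (x$kind == "protein") "CA" else "C3'", nrow(x$atom_xyz)))
  invisible(x)
}

#' Representative-atom coordinates of a chain
#'
#' @param chain a [molecular_chain].
#' @return `length x 3` matrix of Calpha (protein) or C3' (RNA) coordinates,
#'   in residue order. Row `i` corresponds to alignment index `i`.
#' @export
rep_coords <- function(chain) {
  idx <- chain$rep_atom_idx[chain$rep_residues]
  m <- chain$atom_xyz[idx, , drop = FALSE]
  rownames(m) <- NULL
  m
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_ok <- rep(TRUE, length(lines))
  mdl <- which(rec == "MODEL ")
  if (length(mdl)) {           # multi-model: MODEL 1 only
    endm <- which(rec == "ENDMDL")
    end1 <- if (length(endm)) endm[1] else length(lines) + 1L
    atom_ok <- seq_along(lines) > mdl[1] & seq_along(lines) < end1
  }
  at <- lines[atom_ok & rec %in% c("ATOM  ", "HETATM")]
  list(
    atom_name = gsub("\\*", "'", trimws(substr(at, 13, 16))),
    altloc = substr(at, 17, 17),
    resname = trimws(substr(at, 18, 20)),
    chain = substr(at, 22, 22),
    auth_id = trimws(substr(at, 23, 27)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(at, 55, 60))),
    element = trimws(substr(at, 77, 78)),
    header = lines[rec == "HEADER"],
    remarks = lines[rec == "REMARK"]
  )
}

parse_mmcif_atoms <- function(lines) {
  # minimal atom_site loop reader; only the columns the pipeline uses
  loop_at <- grep("^loop_", lines)
  start <- NULL
  for (l0 in loop_at) {
    nxt <- l0 + 1L
    if (nxt <= length(lines) && grepl("^_atom_site\\.", lines[nxt])) { start <- l0; break }
  }
  if (is.null(start)) stop("no atom_site loop found in mmCIF file")
  i <- start + 1L
  fields <- character()
  while (i <= length(lines) && grepl("^_atom_site\\.", lines[i])) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[i])))
    i <- i + 1L
  }
  rows <- character()
  while (i <= length(lines) && !grepl("^(loop_|#|_)", lines[i])) {
    if (nzchar(trimws(lines[i]))) rows <- c(rows, lines[i])
    i <- i + 1L
  }
  tok <- strsplit(trimws(rows), "[[:space:]]+")
  bad <- vapply(tok, length, 1L) != length(fields)
  tok <- tok[!bad]
  get <- function(nm, alt = NULL) {
    k <- match(nm, fields)
    if (is.na(k) && !is.null(alt)) k <- match(alt, fields)
    if (is.na(k)) return(NULL)
    vapply(tok, `[[`, "", k)
  }
  strip_q <- function(v) gsub('^"|"$', "", v)
  pdbx_mdl <- get("pdbx_PDB_model_num")
  keep <- if (is.null(pdbx_mdl)) rep(TRUE, length(tok)) else pdbx_mdl == pdbx_mdl[1]
  ins <- get("pdbx_PDB_ins_code")
  ins <- if (is.null(ins)) "" else ifelse(ins %in% c("?", "."), "", ins)
  list(
    atom_name = strip_q(get("label_atom_id"))[keep],
    altloc = {
      a <- get("label_alt_id")
      (if (is.null(a)) rep(" ", length(tok)) else ifelse(a %in% c(".", "?"), " ", a))[keep]
    },
    resname = get("label_comp_id")[keep],
    chain = (if (is.null(get("auth_asym_id"))) get("label_asym_id") else get("auth_asym_id"))[keep],
    auth_id = paste0(get("auth_seq_id", "label_seq_id"), ins)[keep],
    x = as.numeric(get("Cartn_x")[keep]),
    y = as.numeric(get("Cartn_y")[keep]),
    z = as.numeric(get("Cartn_z")[keep]),
    occ = {
      o <- get("occupancy")
      if (is.null(o)) rep(1, sum(keep)) else suppressWarnings(as.numeric(o[keep]))
    },
    element = {
      e <- get("type_symbol")
      if (is.null(e)) rep("", sum(keep)) else e[keep]
    },
    header = character(), remarks = character()
  )
}

is_hydrogen <- function(element, atom_name) {
  el <- toupper(element)
  known <- el %in% c("H", "D")
  # fall back to the atom name when the element column is blank
  blank <- !nzchar(el)
  nm <- sub("^[0-9]+", "", atom_name)
  known | (blank & substr(nm, 1, 1) %in% c("H", "D"))
}

#' Read a coordinate file into molecular chains
#'
#' Parses a PDB or mmCIF file (first MODEL only), resolves alternate
#' locations (highest occupancy wins; ties go to altloc 'A', then
#' alphabetical), drops hydrogens, waters and non-polymer residues, and
#' classifies each chain as protein or RNA when at least 70% of its
#' residues are standard amino acids or A/C/G/U ribonucleotides. DNA,
#' hybrid and other chains are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @return List of [molecular_chain] objects. Attribute `"meta"` carries
#'   `pdb_id`, `resolution` (angstroms, `NA` if absent) and `deposit_date`
#'   (`Date`, `NA` if absent) when the header provides them.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  p <- tryCatch(
    if (dialect == "pdb") parse_pdb_lines(lines) else parse_mmcif_atoms(lines),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (length(p$atom_name) == 0L) stop("no atoms parsed from ", path)

  heavy <- !is_hydrogen(p$element, p$atom_name)
  keep <- heavy & !(p$resname %in% WATERS)
  meta <- list(pdb_id = NA_character_, resolution = NA_real_, deposit_date = as.Date(NA))
  if (length(p$header)) {
    h <- p$header[1]
    meta$pdb_id <- tolower(trimws(substr(h, 63, 66)))
    dd <- trimws(substr(h, 51, 59))
    meta$deposit_date <- tryCatch(as.Date(dd, format = "%d-%b-%y"),
                                  error = function(e) as.Date(NA))
  }
  r2 <- grep("^REMARK   2 RESOLUTION", p$remarks, value = TRUE)
  if (length(r2)) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1", r2[1])))
    if (!is.na(v)) meta$resolution <- v
  }

  chains <- list()
  for (cid in unique(p$chain[keep])) {
    sel <- which(keep & p$chain == cid)
    if (!length(sel)) next
    res_key <- paste(p$auth_id[sel], p$resname[sel])
    ord <- match(res_key, unique(res_key))
    # altloc resolution per (residue, atom name)
    altkey <- paste(ord, p$atom_name[sel])
    if (anyDuplicated(altkey)) {
      occ <- ifelse(is.na(p$occ[sel]), 1, p$occ[sel])
      alt <- ifelse(p$altloc[sel] == " ", "~", p$altloc[sel]) # blank sorts last
      alt[p$altloc[sel] == "A"] <- "!"                        # 'A' preferred
      o <- order(altkey, -occ, alt)
      sel <- sel[o][!duplicated(altkey[o])]
      res_key <- paste(p$auth_id[sel], p$resname[sel])
      ord <- match(res_key, unique(res_key))
    }
    resnames <- p$resname[sel][!duplicated(ord)]
    auth_ids <- p$auth_id[sel][!duplicated(ord)]
    n_res <- length(resnames)
    frac_aa <- mean(resnames %in% names(AA3))
    frac_rna <- mean(resnames %in% names(RNA1))
    kind <- if (frac_aa >= 0.7) "protein" else if (frac_rna >= 0.7) "rna" else NA
    if (is.na(kind)) {
      if (n_res > 1L)  # single hetero residues (ions/ligands) dropped silently
        warning("chain ", cid, " in ", basename(path),
                " is neither protein nor RNA (dropped)", call. = FALSE)
      next
    }
    # keep polymer residues: standard, or carrying the representative atom
    rep_name <- if (kind == "protein") "CA" else "C3'"
    std <- if (kind == "protein") names(AA3) else names(RNA1)
    has_rep_res <- unique(ord[p$atom_name[sel] == rep_name])
    res_keep <- which(resnames %in% std | seq_len(n_res) %in% has_rep_res)
    if (!length(res_keep)) next
    asel <- sel[ord %in% res_keep]
    new_ord <- match(ord[ord %in% res_keep], res_keep)
    chains[[length(chains) + 1L]] <- molecular_chain(
      chain_id = cid, kind = kind,
      resnames = resnames[res_keep], auth_ids = auth_ids[res_keep],
      atom_xyz = cbind(p$x[asel], p$y[asel], p$z[asel]),
      atom_names = p$atom_name[asel], atom_res = new_ord)
  }
  if (!length(chains)) stop("no admissible protein or RNA chains in ", path)
  attr(chains, "meta") <- meta
  chains
}

fmt_atom_line <- function(serial, name, resname, chain, resseq, xyz, element) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name4, " ", substr(resname, 1, 3), chain,
          resseq %% 10000L, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

chain_pdb_lines <- function(chain, serial0 = 0L) {
  n <- nrow(chain$atom_xyz)
  el <- substr(sub("^[0-9']+", "", chain$atom_names), 1, 1)
  vapply(seq_len(n), function(i) {
    fmt_atom_line(serial0 + i, chain$atom_names[i], chain$resnames[chain$atom_res[i]],
                  chain$chain_id, chain$atom_res[i], chain$atom_xyz[i, ], el[i])
  }, "")
}

#' Write chains as a PDB file
#'
#' @param chains list of [molecular_chain] objects.
#' @param path output path.
#' @param header optional list with `pdb_id`, `resolution`, `deposit_date`
#'   written as HEADER / REMARK 2 records so the file round-trips through
#'   [read_structure()].
#' @param remarks optional character vector of extra REMARK lines.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chains, path, header = NULL, remarks = NULL) {
  if (inherits(chains, "molecular_chain")) chains <- list(chains)
  out <- character()
  if (!is.null(header)) {
    dd <- toupper(format(as.Date(header$deposit_date), "%d-%b-%y"))
    out <- c(out, sprintf("HEADER    %-40s%9s   %4s",
                          "SYNTHETIC COMPLEX", dd, toupper(header$pdb_id)))
    if (!is.null(header$resolution) && !is.na(header$resolution))
      out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", header$resolution))
  }
  if (!is.null(remarks)) out <- c(out, sprintf("REMARK 900 %s", remarks))
  serial <- 0L
  for (ch in chains) {
    out <- c(out, chain_pdb_lines(ch, serial), "TER")
    serial <- serial + nrow(ch$atom_xyz)
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Download a PDB entry from RCSB
#'
#' Fetches `https://files.rcsb.org/download/<ID>.pdb` into `dest_dir`.
#' Used only by the optional worked-example checks; everything else in the
#' package runs on synthetic structures.
#'
#' @param pdb_id 4-character accession.
#' @param dest_dir destination directory (created if needed).
#' @param timeout seconds before giving up.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(pdb_id, dest_dir = tempdir(), timeout = 30) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dest_dir, paste0(tolower(pdb_id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(pdb_id))
  old <- options(timeout = timeout); on.exit(options(old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) < 1000) {
    unlink(dest)
    stop("could not download PDB entry ", pdb_id, " (network unavailable?)")
  }
  dest
}
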