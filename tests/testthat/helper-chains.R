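# tiny builders for hand-placed chains

# one residue per row of `coords`; each residue gets its representative
# atom at the given position (plus an optional second dummy atom)
toy_chain <- function(coords, kind = "protein", chain_id = "A",
                      resnames = NULL, extra_atom = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  rep_name <- if (kind == "protein") "CA" else "C3'"
  std <- if (kind == "protein") c("ALA", "GLY", "SER") else c("A", "C", "G", "U")
  if (is.null(resnames)) resnames <- rep(std, length.out = n)
  if (extra_atom) {
    xyz <- coords[rep(seq_len(n), each = 2), , drop = FALSE]
    xyz[seq(2, 2 * n, 2), 1] <- xyz[seq(2, 2 * n, 2), 1] + 1.0
    molecular_chain(chain_id, kind, resnames, as.character(seq_len(n)),
                    xyz, rep(c(rep_name, if (kind == "protein") "CB" else "P"), n),
                    rep(seq_len(n), each = 2))
  } else {
    molecular_chain(chain_id, kind, resnames, as.character(seq_len(n)),
                    coords, rep(rep_name, n), seq_len(n))
  }
}

random_chain <- function(n, kind = "protein", spread = 10, seed = 1) {
  set.seed(seed)
  toy_chain(matrix(runif(3 * n, 0, spread), ncol = 3), kind = kind)
}

# a small bound complex built from hand-placed single-atom residues; the
# resolution/date metadata make it admissible where needed
toy_complex <- function(pcoords, rcoords, pdb_id = "toyc",
                        resolution = 2.0, date = as.Date("2005-06-01")) {
  binary_complex(pdb_id, toy_chain(pcoords, "protein", "A"),
                 toy_chain(rcoords, "rna", "B"), resolution, date)
}
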