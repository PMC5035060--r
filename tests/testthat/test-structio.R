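# PDB reading, chain classification, interface detection, and the
# binary-complex admissibility filters.

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     record = "ATOM  ", altloc = " ", occ = 1.0, element = "") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resname, chain, resseq, x, y, z,
          occ, 0, element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

test_that("read_structure classifies chains and drops non-polymers", {
  lines <- c(
    "HEADER    RIBOSOME                                01-APR-05   1XYZ",
    "REMARK   2 RESOLUTION.    2.40 ANGSTROMS.",
    unlist(lapply(1:5, function(i)
      pdb_line(i, "CA", "ALA", "A", i, i * 3.8, 0, 0, element = "C"))),
    unlist(lapply(1:4, function(i)
      pdb_line(10 + i, "C3'", "G", "B", i, i * 6, 10, 0, element = "C"))),
    pdb_line(20, "O", "HOH", "W", 1, 50, 50, 50, record = "HETATM", element = "O"),
    pdb_line(21, "O", "HOH", "W", 2, 51, 50, 50, record = "HETATM", element = "O"))
  chains <- read_structure(write_toy_pdb(lines))
  expect_length(chains, 2)
  expect_setequal(vapply(chains, `[[`, "", "kind"), c("protein", "rna"))
  meta <- attr(chains, "meta")
  expect_equal(meta$pdb_id, "1xyz")
  expect_equal(meta$resolution, 2.4)
  expect_equal(meta$deposit_date, as.Date("2005-04-01"))
  prot <- chains[[which(vapply(chains, `[[`, "", "kind") == "protein")]]
  expect_equal(prot$length, 5L)
  expect_equal(prot$sequence, "AAAAA")
})

test_that("modified nucleotides with a C3' atom are kept as 'N'", {
  lines <- c(
    unlist(lapply(1:9, function(i)
      pdb_line(i, "C3'", c("A", "C", "G", "U")[(i %% 4) + 1], "B", i,
               i * 6, 0, 0, element = "C"))),
    pdb_line(10, "C3'", "PSU", "B", 10, 60, 0, 0, record = "HETATM", element = "C"))
  chains <- read_structure(write_toy_pdb(lines))
  expect_length(chains, 1)
  expect_equal(chains[[1]]$kind, "rna")
  expect_equal(chains[[1]]$length, 10L)
  expect_equal(substr(chains[[1]]$sequence, 10, 10), "N")
})

test_that("multi-model files keep MODEL 1 only", {
  mk <- function(x0) unlist(lapply(1:5, function(i)
    pdb_line(i, "CA", "GLY", "A", i, x0 + i * 3.8, 0, 0, element = "C")))
  lines <- c("MODEL        1", mk(0), "ENDMDL",
             "MODEL        2", mk(100), "ENDMDL",
             "MODEL        3", mk(200), "ENDMDL")
  chains <- read_structure(write_toy_pdb(lines))
  expect_length(chains, 1)
  expect_equal(rep_coords(chains[[1]])[, 1], (1:5) * 3.8)
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  lines <- c(
    unlist(lapply(1:4, function(i)
      pdb_line(i, "CA", "ALA", "A", i, i * 3.8, 0, 0, element = "C"))),
    pdb_line(5, "CA", "ALA", "A", 5, 1.0, 0, 0, altloc = "A", occ = 0.4, element = "C"),
    pdb_line(6, "CA", "ALA", "A", 5, 2.0, 0, 0, altloc = "B", occ = 0.6, element = "C"),
    pdb_line(7, "CA", "ALA", "A", 6, 3.0, 0, 0, altloc = "B", occ = 0.5, element = "C"),
    pdb_line(8, "CA", "ALA", "A", 6, 4.0, 0, 0, altloc = "A", occ = 0.5, element = "C"))
  ch <- read_structure(write_toy_pdb(lines))[[1]]
  xs <- rep_coords(ch)[, 1]
  expect_equal(xs[5], 2.0)  # higher occupancy wins
  expect_equal(xs[6], 4.0)  # occupancy tie -> altloc A
})

test_that("unparseable and empty files error", {
  expect_error(read_structure(tempfile()), "not found")
  p <- write_toy_pdb("REMARK nothing here")
  expect_error(read_structure(p), "no atoms")
  # a DNA-only chain leaves nothing admissible
  dna <- unlist(lapply(1:10, function(i)
    pdb_line(i, "C3'", "DA", "C", i, i * 6, 0, 0, element = "C")))
  expect_warning(expect_error(read_structure(write_toy_pdb(dna)), "no admissible"),
                 "neither protein nor RNA")
})

test_that("mmCIF dialect parses the atom_site loop", {
  cif <- c("data_toy", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
           unlist(lapply(1:6, function(i) sprintf(
             "ATOM %d C CA . ALA A A %d %.3f 0.000 0.000 1.00 1", i, i, i * 3.8))),
           "#")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  chains <- read_structure(path, dialect = "mmcif")
  expect_length(chains, 1)
  expect_equal(chains[[1]]$length, 6L)
  expect_equal(rep_coords(chains[[1]])[, 1], (1:6) * 3.8)
})

test_that("interface boundary is a strict inequality at the cutoff", {
  p <- toy_chain(matrix(c(0, 0, 0), 1), "protein")
  r499 <- toy_chain(matrix(c(4.99, 0, 0), 1), "rna")
  r500 <- toy_chain(matrix(c(5.00, 0, 0), 1), "rna")
  i1 <- detect_interface(p, r499)
  expect_equal(i1$protein_interface, 1L)
  expect_equal(i1$rna_interface, 1L)
  i2 <- detect_interface(p, r500)
  expect_length(i2$protein_interface, 0)
  expect_length(i2$rna_interface, 0)
})

test_that("grid interface equals the brute-force scan on random geometries", {
  set.seed(71)
  for (k in 1:40) {
    p <- toy_chain(matrix(runif(30, 0, 12), ncol = 3), "protein", extra_atom = TRUE)
    r <- toy_chain(matrix(runif(24, 0, 12), ncol = 3), "rna", extra_atom = TRUE)
    cutoff <- runif(1, 2, 8)
    got <- detect_interface(p, r, cutoff)
    want <- oracle_interface(p, r, cutoff)
    expect_equal(got$protein_interface, want$protein_interface)
    expect_equal(got$rna_interface, want$rna_interface)
  }
})

test_that("interface sets shrink monotonically with the cutoff", {
  set.seed(72)
  p <- toy_chain(matrix(runif(60, 0, 15), ncol = 3), "protein")
  r <- toy_chain(matrix(runif(45, 0, 15), ncol = 3), "rna")
  prev <- detect_interface(p, r, 9)
  for (cutoff in c(7, 5, 3, 1)) {
    cur <- detect_interface(p, r, cutoff)
    expect_true(all(cur$protein_interface %in% prev$protein_interface))
    expect_true(all(cur$rna_interface %in% prev$rna_interface))
    prev <- cur
  }
})

# an admissible protein/RNA pair in tight contact: 30+ residues each side
grid_coords <- function(n, dx, y, z = 0) cbind(seq_len(n) * dx, y, z)

test_that("extract_binary_complexes pairs chains and applies all filters", {
  meta <- list(pdb_id = "test", resolution = 2.5, deposit_date = as.Date("2010-01-01"))
  p1 <- toy_chain(grid_coords(30, 3.8, 0), "protein", "A")
  p2 <- toy_chain(grid_coords(30, 3.8, 8), "protein", "C")
  r1 <- toy_chain(grid_coords(20, 5.9, 4), "rna", "B")
  r2 <- toy_chain(grid_coords(20, 5.9, 4, z = 2), "rna", "D")
  out <- extract_binary_complexes(list(p1, p2, r1, r2), meta)
  expect_length(out, 4)  # full Cartesian pairing, all in contact
  expect_setequal(vapply(out, `[[`, "", "id"),
                  c("test_AB", "test_AD", "test_CB", "test_CD"))

  # order independence
  out2 <- extract_binary_complexes(list(r2, p2, r1, p1), meta)
  expect_equal(vapply(out2, `[[`, "", "id"), vapply(out, `[[`, "", "id"))

  # protein of length 29 -> rejected
  p29 <- toy_chain(grid_coords(29, 3.8, 0), "protein", "A")
  out3 <- extract_binary_complexes(list(p29, r1), meta)
  expect_length(out3, 0)
  expect_equal(attr(out3, "rejections")$reason, "protein_too_short")

  # resolution filters
  out4 <- extract_binary_complexes(list(p1, r1),
                                   modifyList(meta, list(resolution = 3.1)))
  expect_equal(attr(out4, "rejections")$reason, "resolution_too_low")
  out5 <- extract_binary_complexes(list(p1, r1),
                                   modifyList(meta, list(resolution = NA_real_)))
  expect_equal(attr(out5, "rejections")$reason, "no_resolution")
})

test_that("a 5/4 interface is rejected as rna_interface_too_small", {
  meta <- list(pdb_id = "test", resolution = 2.0, deposit_date = as.Date("2010-01-01"))
  # 30-residue protein along x at y=0; 20-nt RNA spread far away except
  # 4 residues placed within 5 A of five protein residues
  p <- toy_chain(grid_coords(30, 3.8, 0), "protein", "A")
  rc <- grid_coords(20, 5.9, 100)             # out of range
  rc[1, ] <- c(1 * 3.8, 4, 0)                 # near protein residue 1
  rc[2, ] <- c(5 * 3.8, 4, 0)
  rc[3, ] <- c(9 * 3.8, 4, 0)
  rc[4, ] <- c(13 * 3.8 + 1.9, 4.3, 0)        # near residues 13 and 14
  r <- toy_chain(rc, "rna", "B")
  want <- oracle_interface(p, r, 5)           # confirm the planted sizes
  expect_length(want$protein_interface, 5)
  expect_length(want$rna_interface, 4)
  out <- extract_binary_complexes(list(p, r), meta)
  expect_length(out, 0)
  expect_equal(attr(out, "rejections")$reason, "rna_interface_too_small")
})

test_that("complex manifest records passes and failures as TSV", {
  meta <- list(pdb_id = "test", resolution = 2.5, deposit_date = as.Date("2010-01-01"))
  p <- toy_chain(grid_coords(30, 3.8, 0), "protein", "A")
  r <- toy_chain(grid_coords(20, 5.9, 4), "rna", "B")
  r_far <- toy_chain(grid_coords(20, 5.9, 90), "rna", "D")
  out <- extract_binary_complexes(list(p, r, r_far), meta)
  path <- tempfile(fileext = ".tsv")
  complex_manifest(out, path)
  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$status, c("pass", "fail"))
})
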