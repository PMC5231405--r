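test_that("a minimal PDB record is parsed field-for-field", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   52.100   52.100  171.800  90.00  90.00 120.00 P 31 2 1      6",
    "ATOM      7  NE2 HIS A 188      12.345  -6.789   0.120  1.00 23.45           N",
    "HETATM    8 MG    MG B 201       1.000   2.000   3.000  0.80 10.00          MG",
    "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(n_atoms(s), 2L)
  a <- s$atoms
  expect_equal(a$serial, c(7L, 8L))
  expect_equal(a$name, c("NE2", "MG"))
  expect_equal(a$resname, c("HIS", "MG"))
  expect_equal(a$chain, c("A", "B"))
  expect_equal(a$resnum, c(188L, 201L))
  expect_equal(a$occ, c(1, 0.8))
  expect_equal(a$b, c(23.45, 10))
  expect_equal(a$element, c("N", "MG"))
  expect_equal(a$het, c(FALSE, TRUE))
  expect_equal(coords(s)[1, ], c(12.345, -6.789, 0.120))
  expect_equal(s$cell, c(52.1, 52.1, 171.8, 90, 90, 120))
  expect_equal(s$sgroup, "P 31 2 1")
})

test_that("write/read round trips are the identity up to format precision", {
  fx <- make_reaction_center(7.6, 3.0, 6.38)
  s <- fx$structure
  s$cell <- c(40, 50, 60, 90, 100, 90)
  s$sgroup <- "P 1 21 1"
  for (fmt in c("pdb", "mmcif")) {
    tmp <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb"
                                 else ".cif")
    write_structure(s, tmp, format = fmt)
    s2 <- read_structure(tmp, format = fmt)
    expect_true(structures_equal(s, s2), label = paste(fmt, "round trip"))
    # chain order preserved
    expect_identical(unique(s2$atoms$chain), unique(s$atoms$chain))
  }
})

test_that("PDB and mmCIF serializations of one model read back identically", {
  fx <- make_reaction_center(6.0, 3.5, 5.0)
  s <- fx$structure
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, p1)
  write_structure(s, p2)
  s1 <- read_structure(p1)
  s2 <- read_structure(p2)
  expect_true(structures_equal(s1, s2))
})

test_that("CRYST1 is emitted for structures carrying a cell", {
  fx <- make_reaction_center(6.0, 3.5, 5.0)
  s <- fx$structure
  s$cell <- c(10, 11, 12, 90, 90, 90)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tmp)
  cl <- grep("^CRYST1", readLines(tmp), value = TRUE)
  expect_length(cl, 1L)
  expect_equal(as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                            substr(cl, 25, 33), substr(cl, 34, 40),
                            substr(cl, 41, 47), substr(cl, 48, 54))),
               c(10, 11, 12, 90, 90, 90))
})

test_that("alternate locations collapse to highest occupancy, ties to 'A'", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       0.000   2.000   0.000  0.50 10.00           C",
    "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(n_atoms(s), 2L)
  ca <- s$atoms[s$atoms$name == "CA", ]
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(ca$x, 1)   # higher occupancy conformer B
  expect_equal(cb$y, 1)   # tie broken lexicographically: A
  s_all <- read_structure(tmp, altloc = "all")
  expect_equal(n_atoms(s_all), 4L)
})

test_that("selections are inclusive conjunctions and idempotent", {
  s <- make_ca_trace()
  sel <- selection(chains = "A", resnums = 190:234, atoms = "CA")
  sub <- select_atoms(s, sel)
  expect_equal(n_atoms(sub), 45L)  # inclusive at both ends
  expect_true(all(sub$atoms$chain == "A"))
  expect_true(all(sub$atoms$resnum >= 190 & sub$atoms$resnum <= 234))
  # idempotence
  expect_identical(select_atoms(sub, sel)$atoms, sub$atoms)
  # composition equals brute-force intersection of single-predicate masks
  m1 <- s$atoms$chain %in% "A"
  m2 <- s$atoms$resnum %in% 190:234
  m3 <- s$atoms$name %in% "CA"
  expect_identical(sub$atoms$serial, s$atoms$serial[m1 & m2 & m3])
  # single named atom
  rc <- make_reaction_center(7.6, 3.0, 6.38)$structure
  expect_equal(n_atoms(select_atoms(rc, selection(atoms = "NE2"))), 1L)
  # hetero policy
  expect_equal(n_atoms(select_atoms(rc, selection(hetero = "only"))), 1L)
  expect_false(any(select_atoms(rc, selection(hetero = "exclude"))$atoms$het))
})

test_that("waters and hydrogens stay out unless requested", {
  at <- data.frame(serial = 1:3, name = c("CA", "O", "H"),
                   element = c("C", "O", "H"),
                   resname = c("GLY", "HOH", "GLY"),
                   chain = "A", resnum = c(1L, 90L, 1L), icode = "",
                   altloc = "", occ = 1, b = 10,
                   x = c(0, 5, 1), y = 0, z = 0,
                   het = c(FALSE, TRUE, FALSE))
  s <- structure_model(at)
  expect_equal(n_atoms(select_atoms(s, selection())), 1L)
  expect_equal(n_atoms(select_atoms(s, selection(waters = TRUE))), 2L)
  expect_equal(n_atoms(select_atoms(s, selection(hydrogens = TRUE))), 2L)
})

test_that("degenerate inputs raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", tmp)
  expect_error(read_structure(tmp), "atoms|parse")
  fx <- make_reaction_center(6, 3.5, 5)
  s <- fx$structure
  s$atoms <- s$atoms[0, ]
  expect_error(write_structure(s, tempfile(fileext = ".pdb")), "empty")
  bad <- fx$structure
  bad$atoms$name[1] <- "TOOLONG"
  expect_error(write_structure(bad, tempfile(fileext = ".pdb")),
               "longer than")
  expect_error(structure_model(fx$structure$atoms,
                               cell = c(-1, 1, 1, 90, 90, 90)), "cell")
  occbad <- fx$structure$atoms
  occbad$occ[1] <- 1.5
  expect_error(structure_model(occbad), "occupanc")
})
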