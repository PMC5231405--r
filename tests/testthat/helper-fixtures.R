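# shared helpers for building tiny in-code fixtures

# a one-residue-per-chain CA trace: chain A residues 180..240, chain B 1..60
make_ca_trace <- function() {
  xyz_a <- cbind(2.3 * cos((0:60) * 1.75), 2.3 * sin((0:60) * 1.75),
                 1.5 * (0:60))
  xyz_b <- cbind(10 + 2.3 * cos((0:59) * 1.75), 2.3 * sin((0:59) * 1.75),
                 1.5 * (0:59))
  at <- rbind(
    data.frame(serial = 1:61, name = "CA", element = "C", resname = "ALA",
               chain = "A", resnum = 180:240, icode = "", altloc = "",
               occ = 1, b = 10, x = xyz_a[, 1], y = xyz_a[, 2],
               z = xyz_a[, 3], het = FALSE),
    data.frame(serial = 62:121, name = "CA", element = "C", resname = "GLY",
               chain = "B", resnum = 1:60, icode = "", altloc = "",
               occ = 1, b = 10, x = xyz_b[, 1], y = xyz_b[, 2],
               z = xyz_b[, 3], het = FALSE))
  structure_model(at, source = "ca-trace")
}

# four-point set with a prescribed torsion, built from the definition:
# p2-p3 along z, p1 in the xz-plane, p4 = p1-analogue rotated by `angle`
make_torsion_points <- function(angle) {
  p2 <- c(0, 0, 0)
  p3 <- c(0, 0, 1.5)
  p1 <- c(1.4, 0, -0.5)
  arm <- c(1.4, 0, 0.5)  # direction of p4 relative to p3 at torsion 0
  th <- angle * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  p4 <- p3 + as.vector(rot %*% (arm - c(0, 0, 0)))
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

# structure from a bare coordinate matrix (GLY CA atoms, chain A)
structure_from_xyz <- function(xyz, chain = "A", source = "xyz") {
  n <- nrow(xyz)
  structure_model(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "GLY",
    chain = chain, resnum = seq_len(n), icode = "", altloc = "",
    occ = 1, b = 10, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = FALSE), source = source)
}

# independent affine oracle for a symmetry operator: evaluates the three
# component expressions numerically (base R eval), never parse_symop()
symop_oracle_matrix <- function(op) {
  comps <- strsplit(gsub("[[:space:]]", "", op), ",")[[1]]
  ev <- function(x, y, z) vapply(comps, function(cc)
    eval(parse(text = cc), list(x = x, y = y, z = z)), numeric(1))
  t0 <- ev(0, 0, 0)
  R <- cbind(ev(1, 0, 0) - t0, ev(0, 1, 0) - t0, ev(0, 0, 1) - t0)
  list(R = unname(R), t = unname(t0))
}

# paths to locally fetched deposited entries; fails the calling test (never
# skips) when a file is absent, naming the fetch command
deposited_or_fail <- function(ids, dir = testthat::test_path("..", "..",
                                                             "data_deposited")) {
  paths <- character(0)
  for (id in ids) {
    p <- suppressMessages(deposited_structure_path(id, dir = dir))
    if (is.na(p)) {
      testthat::fail(paste0(
        "deposited entry ", id, " is not available locally under '", dir,
        "'; fetch it once with: curl -o ", dir, "/", tolower(id),
        ".cif https://files.rcsb.org/download/", toupper(id), ".cif"))
      return(NULL)
    }
    paths <- c(paths, p)
  }
  stats::setNames(paths, ids)
}
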