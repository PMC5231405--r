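#' @section Fixture philosophy:
#' The generators in this file build small, legal coordinate sets whose
#' geometry is known by construction, so that every analysis stage --
#' reading, selecting, superposing, measuring, classifying, surface work --
#' can be validated end-to-end without any deposited structure. Fixtures
#' are written as plausible PDB/mmCIF files (HIS/ASP/MG residue and atom
#' names) so the full I/O path is exercised, not bypassed.
#' @name fixtures
NULL

TCS_DEFAULT_SEED <- 20161212L

fixture_atoms <- function(name, element, resname, chain, resnum, xyz,
                          het = FALSE, serial_start = 1L) {
  n <- length(name)
  data.frame(serial = serial_start + seq_len(n) - 1L,
             name = name, element = element, resname = resname,
             chain = chain, resnum = as.integer(resnum),
             icode = "", altloc = "",
             occ = 1, b = 20,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             het = het, stringsAsFactors = FALSE)
}

#' Synthetic phosphotransfer reaction center
#'
#' Builds a minimal His residue (with NE2), an Asp residue (OD1/OD2), an
#' Mg cation and optionally a phosphorus surrogate placed collinearly on
#' the NE2 -> OD1 axis (the near-linear in-line transfer geometry), at
#' exactly the requested distances. [measure_center()] on the output
#' recovers the requested values to 1e-9 A.
#'
#' @param d_his_asp His NE2 to Asp OD1 distance (Angstrom).
#' @param d_mg_asp Mg to OD1 distance.
#' @param d_mg_his Mg to NE2 distance. The three distances must satisfy the
#'   triangle inequality.
#' @param with_surrogate place a phosphorus surrogate on the His residue?
#' @param d_rxn reaction-coordinate (P -> OD1) distance; default puts the P
#'   1.8 A from NE2 (a P-N bond length) along the transfer axis.
#' @param seed integer; controls only the decorative jitter of non-reactive
#'   atoms. Same seed, same bytes.
#' @return list with `structure` (a `tcs_structure`), `spec` (the matching
#'   [reaction_center_spec()]), and `truth` (requested distances, ratio,
#'   and expected group under the default thresholds).
#' @export
make_reaction_center <- function(d_his_asp, d_mg_asp, d_mg_his,
                                 with_surrogate = TRUE,
                                 d_rxn = d_his_asp - 1.8,
                                 seed = TCS_DEFAULT_SEED) {
  if (d_his_asp <= 0 || d_mg_asp <= 0 || d_mg_his <= 0)
    stop("distances must be positive")
  xm <- (d_his_asp^2 + d_mg_his^2 - d_mg_asp^2) / (2 * d_his_asp)
  ym2 <- d_mg_his^2 - xm^2
  if (ym2 < -1e-9)
    stop(sprintf("infeasible geometry: distances (%.2f, %.2f, %.2f) violate the triangle inequality",
                 d_his_asp, d_mg_asp, d_mg_his))
  ym <- sqrt(max(0, ym2))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  jit <- function(p, scale = 0.3) p + round(stats::runif(3, -scale, scale), 3)
  ne2 <- c(0, 0, 0)
  od1 <- c(d_his_asp, 0, 0)
  mg <- c(xm, ym, 0)
  # decorative His scaffold behind NE2, Asp scaffold beyond OD1
  his_xyz <- rbind(jit(ne2 + c(-4.0, 1.0, 0)),  # N
                   jit(ne2 + c(-3.2, 0.2, 0)),  # CA
                   jit(ne2 + c(-4.0, -1.0, 0)), # C
                   jit(ne2 + c(-5.2, -1.0, 0)), # O
                   jit(ne2 + c(-2.4, 0.5, 1.0)),# CB
                   jit(ne2 + c(-1.8, 0.1, 0.2)),# CG
                   jit(ne2 + c(-1.2, -1.0, 0)), # ND1
                   jit(ne2 + c(-1.0, 1.0, 0)),  # CD2
                   jit(ne2 + c(-0.4, -0.8, 0)), # CE1
                   ne2)                          # NE2 exact
  his <- fixture_atoms(
    c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    c("N", "C", "C", "O", "C", "C", "N", "C", "C", "N"),
    "HIS", "A", 188L, his_xyz)
  asp_xyz <- rbind(jit(od1 + c(4.0, 1.0, 0)),   # N
                   jit(od1 + c(3.2, 0.2, 0)),   # CA
                   jit(od1 + c(4.0, -1.0, 0)),  # C
                   jit(od1 + c(5.2, -1.0, 0)),  # O
                   jit(od1 + c(2.4, 0.5, 1.0)), # CB
                   jit(od1 + c(1.4, 0.1, 0.2)), # CG
                   od1,                          # OD1 exact
                   jit(od1 + c(1.2, -1.1, 0)))  # OD2 (farther from NE2)
  asp <- fixture_atoms(
    c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    c("N", "C", "C", "O", "C", "C", "O", "O"),
    "ASP", "B", 54L, asp_xyz, serial_start = 11L)
  mg_at <- fixture_atoms("MG", "MG", "MG", "B", 201L,
                         matrix(mg, 1, 3), het = TRUE, serial_start = 19L)
  atoms <- rbind(his, asp, mg_at)
  if (with_surrogate) {
    if (d_rxn <= 0 || d_rxn >= d_his_asp)
      stop("d_rxn must lie strictly between 0 and d_his_asp for an in-line surrogate")
    p_at <- fixture_atoms("P", "P", "HIS", "A", 188L,
                          matrix(c(d_his_asp - d_rxn, 0, 0), 1, 3),
                          het = FALSE, serial_start = 20L)
    atoms <- rbind(atoms, p_at)
  }
  s <- structure_model(atoms, source = "synthetic-rc")
  spec <- reaction_center_spec("A", 188, "B", 54,
                               surrogate = if (with_surrogate) "auto"
                               else "none")
  cls <- classify_mechanism(d_his_asp, d_mg_asp / d_mg_his,
                            if (with_surrogate) d_rxn else NA_real_)
  list(structure = s, spec = spec,
       truth = list(d_his_asp = d_his_asp, d_mg_asp = d_mg_asp,
                    d_mg_his = d_mg_his,
                    d_rxn = if (with_surrogate) d_rxn else NA_real_,
                    r_mg = d_mg_asp / d_mg_his, group = cls$group))
}

#' Rigidly transformed point-cloud pair
#'
#' A seeded random cloud (guaranteed non-collinear by three orthogonal
#' anchors) and its copy under a known rotation + translation, with
#' optional Gaussian coordinate noise: the canonical test harness for
#' least-squares superposition.
#'
#' @param n_atoms number of points (>= 4).
#' @param angle rotation angle in degrees.
#' @param axis rotation axis (length-3).
#' @param translation translation vector (length-3, Angstrom).
#' @param noise_sd per-coordinate Gaussian noise sd applied to the moved
#'   copy (default 0).
#' @param seed integer seed.
#' @return list with `a`, `b` (tcs_structures; b = moved a) and
#'   `transform_true` (the `tcs_transform` such that applying it to a's
#'   coordinates yields b's, noise aside).
#' @export
make_rigid_pair <- function(n_atoms = 50, angle = 30, axis = c(0, 0, 1),
                            translation = c(0, 0, 0), noise_sd = 0,
                            seed = TCS_DEFAULT_SEED) {
  stopifnot(n_atoms >= 4)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pts <- rbind(diag(3) * 8,
               matrix(stats::runif((n_atoms - 3) * 3, -10, 10), ncol = 3))
  R <- rotation_about_axis(axis, angle)
  tf <- rigid_transform(R, translation)
  moved <- sweep(pts %*% t(R), 2, translation, "+")
  if (noise_sd > 0)
    moved <- moved + matrix(stats::rnorm(length(moved), 0, noise_sd),
                            ncol = 3)
  mk <- function(xyz, src) structure_model(fixture_atoms(
    rep("CA", n_atoms), rep("C", n_atoms), rep("GLY", n_atoms), "A",
    seq_len(n_atoms), xyz), source = src)
  list(a = mk(pts, "rigid-pair-a"), b = mk(moved, "rigid-pair-b"),
       transform_true = tf)
}

#' Synthetic slippage series
#'
#' A shared rigid DHp-like CA scaffold (chain A, residues 190-234) plus a
#' REC-like CA domain (chain B, residues 1-129) rigidly displaced by a
#' different vector in each entry. Ground truth: the DHp-fit regime cell
#' (i, j) equals |delta_i - delta_j| and every REC-fit regime cell is 0.
#'
#' @param n_complexes number of entries (>= 2).
#' @param displacements n x 3 matrix (or list of length-3 vectors) of REC
#'   displacements; default: seeded random directions with magnitudes
#'   evenly spaced from 0 to 2.4 Angstrom, the scale of receiver-domain
#'   slippage seen across refined HK:RR complexes.
#' @param seed integer seed.
#' @return list with `entries` (list of [complex_entry()]),
#'   `M_dhp_true`, `M_rec_true` (matrices).
#' @export
make_slippage_series <- function(n_complexes = 4, displacements = NULL,
                                 seed = TCS_DEFAULT_SEED) {
  stopifnot(n_complexes >= 2)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (is.null(displacements)) {
    mags <- seq(0, 2.4, length.out = n_complexes)
    dirs <- matrix(stats::rnorm(n_complexes * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    displacements <- dirs * mags
    displacements[1, ] <- 0
  }
  if (is.list(displacements))
    displacements <- do.call(rbind, displacements)
  displacements <- as.matrix(displacements)
  stopifnot(nrow(displacements) == n_complexes, ncol(displacements) == 3)
  # DHp scaffold: ideal helix of CA atoms; REC: seeded globular cloud
  i <- 0:44
  dhp <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
               1.5 * i)
  rec <- matrix(stats::runif(129 * 3, -12, 12), ncol = 3)
  rec <- sweep(rec, 2, c(18, 0, 30), "+")
  entries <- lapply(seq_len(n_complexes), function(k) {
    at <- rbind(
      fixture_atoms(rep("CA", 45), rep("C", 45), rep("GLY", 45), "A",
                    190:234, dhp),
      fixture_atoms(rep("CA", 129), rep("C", 129), rep("ALA", 129), "B",
                    1:129, sweep(rec, 2, displacements[k, ], "+"),
                    serial_start = 46L))
    complex_entry(sprintf("SYN%d", k),
                  structure_model(at, source = sprintf("synthetic-slip-%d", k)),
                  hk_chain = "A", rr_chain = "B")
  })
  n <- n_complexes
  M_dhp <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    M_dhp[a, b] <- sqrt(sum((displacements[a, ] - displacements[b, ])^2))
  labs <- vapply(entries, `[[`, character(1), "label")
  dimnames(M_dhp) <- list(labs, labs)
  list(entries = entries, M_dhp_true = M_dhp,
       M_rec_true = matrix(0, n, n, dimnames = list(labs, labs)))
}

#' Analytic SASA of an isolated sphere
#' @param r sphere (atom) radius, Angstrom.
#' @param probe probe radius, Angstrom.
#' @return 4 pi (r + probe)^2.
#' @export
sphere_sasa_isolated <- function(r, probe = 1.4) 4 * pi * (r + probe)^2

#' Analytic SASA / BSA of a pairwise-overlapping sphere system
#'
#' Closed-form spherical-cap accounting, valid when no point is covered by
#' more than two expanded spheres (the fixture generator guarantees this).
#'
#' @param radii atom radii (Angstrom).
#' @param centers n x 3 matrix of centers.
#' @param probe probe radius.
#' @return list with `per_sphere` accessible areas, `total`, and
#'   `buried_per_sphere` (cap areas lost to each overlap, summed).
#' @export
sphere_system_sasa_analytic <- function(radii, centers, probe = 1.4) {
  centers <- as.matrix(centers)
  n <- length(radii)
  Re <- radii + probe
  iso <- 4 * pi * Re^2
  buried <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (d >= Re[i] + Re[j]) next
    if (d + Re[i] <= Re[j]) { buried[i] <- buried[i] + iso[i]; next }
    if (d + Re[j] <= Re[i]) { buried[j] <- buried[j] + iso[j]; next }
    xi <- (d^2 + Re[i]^2 - Re[j]^2) / (2 * d)
    buried[i] <- buried[i] + 2 * pi * Re[i] * (Re[i] - xi)
    buried[j] <- buried[j] + 2 * pi * Re[j] * (Re[j] - (d - xi))
  }
  per <- iso - buried
  list(per_sphere = per, total = sum(per), buried_per_sphere = buried)
}

#' Sphere-system fixture with analytic surface-area ground truth
#'
#' @param radii atom radii (Angstrom).
#' @param centers n x 3 matrix (or list of length-3 vectors).
#' @param probe probe radius used for the analytic record.
#' @return list with `structure` (carbon pseudo-atoms, one residue per
#'   sphere, alternating chains A/B so partner selections are available),
#'   `radii` (per-atom override vector), and `truth` (analytic areas from
#'   [sphere_system_sasa_analytic()]).
#' @export
make_sphere_system <- function(radii, centers, probe = 1.4) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  n <- length(radii)
  stopifnot(nrow(centers) == n, all(radii > 0))
  at <- fixture_atoms(rep("C", n), rep("C", n), rep("SPH", n),
                      rep(c("A", "B"), length.out = n), seq_len(n),
                      centers, het = TRUE)
  list(structure = structure_model(at, source = "synthetic-spheres"),
       radii = as.numeric(radii),
       truth = sphere_system_sasa_analytic(radii, centers, probe))
}

#' Interlocking-surface fixture for shape complementarity
#'
#' Two parallel walls facing each other across a controlled gap. Each wall
#' is a single dense layer of large, heavily overlapping pseudo-atoms, so
#' its solvent-facing side is flat to well below the dot resolution: the
#' two facing surfaces are then exactly complementary planes separated by
#' `gap`, and as the dot density grows the Lawrence-Colman score
#' approaches the flat-surface limit exp(-w gap^2). A curvature mismatch
#' bends the second wall parabolically, degrading complementarity.
#'
#' @param gap surface-to-surface separation (Angstrom).
#' @param curvature_mismatch curvature (1/Angstrom) of the second wall;
#'   0 = perfectly complementary in the flat limit (only then is the
#'   recorded `sc_flat_limit` meaningful).
#' @param half_extent wall half-width in x and y (default 5 A).
#' @param spacing atom grid spacing (default 1.0 A).
#' @param r_atom pseudo-atom radius (default 15 A; the residual bump
#'   amplitude on the wall face is spacing^2 / (4 r_atom), well under the
#'   dot resolution).
#' @param w Gaussian weight used for the recorded limit (default 0.5).
#' @return list with `structure` (chains A and B, one wall each),
#'   `radii` (per-atom override vector), and `truth` (`sc_flat_limit`).
#' @export
make_sc_surfaces <- function(gap = 0, curvature_mismatch = 0,
                             half_extent = 5, spacing = 1.0, r_atom = 15,
                             w = 0.5) {
  g <- expand.grid(x = seq(-half_extent, half_extent, by = spacing),
                   y = seq(-half_extent, half_extent, by = spacing))
  n1 <- nrow(g)
  za <- rep(0, n1)
  zb <- 2 * r_atom + gap + curvature_mismatch * (g$x^2 + g$y^2) / 2
  at <- rbind(
    fixture_atoms(rep("C", n1), rep("C", n1), rep("SPH", n1), "A",
                  seq_len(n1), cbind(g$x, g$y, za), het = TRUE),
    fixture_atoms(rep("C", n1), rep("C", n1), rep("SPH", n1), "B",
                  seq_len(n1), cbind(g$x, g$y, zb), het = TRUE,
                  serial_start = n1 + 1L))
  # Outside the atom grid the wall faces curve away from each other
  # (spherical overhang), so the buried patch carries a divergent rim of
  # width ~ sqrt(gap_cut * r_atom); the peripheral trim band must cover it
  # for the flat-limit comparison to address the flat core only.
  rim <- sqrt(2 * 1.4 * r_atom) + 1
  list(structure = structure_model(at, source = "synthetic-sc"),
       radii = rep(r_atom, 2 * n1),
       sc_args = list(n_dots = 31000, trim = rim, w = w),
       truth = list(sc_flat_limit = exp(-w * gap^2)))
}

#' Write a fixture with its ground-truth sidecar
#'
#' @param fx a fixture list (any `make_*` output with a `structure`
#'   element).
#' @param path_prefix output path without extension.
#' @param format "pdb" or "mmcif".
#' @return invisibly, the two file paths (structure, JSON ground truth).
#' @export
write_fixture <- function(fx, path_prefix, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  ext <- if (format == "pdb") ".pdb" else ".cif"
  spath <- paste0(path_prefix, ext)
  jpath <- paste0(path_prefix, ".json")
  write_structure(fx$structure, spath, format = format)
  truth <- fx$truth
  if (is.null(truth)) truth <- list()
  jsonlite::write_json(truth, jpath, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(c(structure = spath, truth = jpath))
}
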