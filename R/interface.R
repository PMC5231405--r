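#' Van der Waals radii (Chothia-like set)
#'
#' A single named default table, by element symbol. Values follow the
#' Chothia (1976) convention commonly used for protein surface-area work,
#' with additions for the ions and mimic atoms encountered in
#' phosphotransfer structures.
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
radii_chothia <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00, D = 1.00,
    F = 1.47, CL = 1.77, BR = 1.85,
    MG = 1.73, MN = 1.73, ZN = 1.39, FE = 1.65, CA = 1.95, "NA" = 2.27,
    K = 2.75, BE = 1.40, SE = 1.90)
}

#' Parameters for surface-area computations
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points quadrature points per atom sphere (default 960; >= 92
#'   required). Points come from a fixed golden-spiral set, so results are
#'   bit-reproducible for a given `n_points`.
#' @param radii element -> van der Waals radius table (default
#'   [radii_chothia()]).
#' @param fallback_radius radius used, with a warning, for elements missing
#'   from the table; set NA to make unknown elements an error.
#' @param include_hydrogens include H/D atoms (default FALSE; X-ray
#'   structures at typical resolution carry none).
#' @return object of class `tcs_sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii = radii_chothia(), fallback_radius = 1.8,
                        include_hydrogens = FALSE) {
  stopifnot(probe_radius > 0, n_points >= 92)
  obj <- list(probe_radius = probe_radius, n_points = as.integer(n_points),
              radii = radii, fallback_radius = fallback_radius,
              include_hydrogens = include_hydrogens)
  class(obj) <- "tcs_sasa_params"
  obj
}

#' Deterministic golden-spiral point set on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(s, p, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == n_atoms(s))
    return(as.numeric(override))
  }
  el <- s$atoms$element
  r <- unname(p$radii[el])
  if (anyNA(r)) {
    unk <- unique(el[is.na(r)])
    if (is.na(p$fallback_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unk, collapse = ", "))
    warning("using fallback radius ", p$fallback_radius,
            " A for element(s): ", paste(unk, collapse = ", "))
    r[is.na(r)] <- p$fallback_radius
  }
  r
}

sasa_core <- function(xyz, radii, probe, n_points) {
  # Shrake-Rupley: fraction of quadrature points on each atom's expanded
  # sphere (r_vdw + probe) not occluded by any neighbour's expanded sphere.
  n <- nrow(xyz)
  pts <- golden_spiral(n_points)
  re <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- rowSums(sweep(xyz, 2, ci)^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * re[i]^2
      next
    }
    sp <- sweep(pts * re[i], 2, ci, "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj >= re[j]^2
    }
    out[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param s a `tcs_structure`.
#' @param p a [sasa_params()].
#' @param radii_override optional per-atom radius vector (Angstrom),
#'   bypassing the element table (used by sphere fixtures).
#' @return list with `total` (Angstrom^2), `per_atom` (vector aligned with
#'   the atom table; hydrogens get 0 when excluded), and `per_residue`
#'   (data.frame chain/resnum/resname/area).
#' @export
sasa <- function(s, p = sasa_params(), radii_override = NULL) {
  stopifnot(inherits(p, "tcs_sasa_params"))
  if (n_atoms(s) == 0L) stop("empty structure")
  keep <- if (p$include_hydrogens) rep(TRUE, n_atoms(s))
  else !(s$atoms$element %in% c("H", "D"))
  sub <- s
  sub$atoms <- s$atoms[keep, , drop = FALSE]
  r <- atom_radii(sub, p, if (is.null(radii_override)) NULL
                  else radii_override[keep])
  per <- numeric(n_atoms(s))
  per[keep] <- sasa_core(coords(sub), r, p$probe_radius, p$n_points)
  agg <- stats::aggregate(
    per,
    by = list(chain = s$atoms$chain, resnum = s$atoms$resnum,
              resname = s$atoms$resname),
    FUN = sum)
  names(agg)[4] <- "area"
  list(total = sum(per), per_atom = per, per_residue = agg)
}

subset_structure <- function(s, idx) {
  out <- s
  out$atoms <- s$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Buried surface area of an interface
#'
#' bsa_total = SASA(A) + SASA(B) - SASA(A u B), all three computed with
#' identical parameters. Reported both ways: the summed two-partner burial
#' (the headline convention for helix-face HK:RR interfaces) and the
#' halved "interface area" for cross-tool comparison. A per-domain
#' decomposition of partner A's burial is available through
#' `domains_a`, a named list of residue-number vectors (e.g. DHp vs CA
#' domain ranges).
#'
#' @param s a `tcs_structure` containing both partners.
#' @param a_sel,b_sel disjoint [selection()]s defining the partners.
#' @param p a [sasa_params()].
#' @param domains_a optional named list of residue-number vectors
#'   decomposing partner A's burial.
#' @param radii_override optional per-atom radii (full structure).
#' @return object of class `tcs_interface`: `bsa_total`, `bsa_a`, `bsa_b`,
#'   `interface_area` (= bsa_total / 2), `sasa_a`, `sasa_b`, `sasa_ab`,
#'   `per_domain_a` (named vector, if requested), `per_atom_burial_a/b`.
#' @export
buried_surface <- function(s, a_sel, b_sel, p = sasa_params(),
                           domains_a = NULL, radii_override = NULL) {
  ia <- which(selection_mask(s, a_sel))
  ib <- which(selection_mask(s, b_sel))
  if (length(intersect(ia, ib)))
    stop("partner selections overlap (", length(intersect(ia, ib)),
         " shared atoms)")
  if (!length(ia) || !length(ib)) stop("empty partner selection")
  A <- subset_structure(s, ia)
  B <- subset_structure(s, ib)
  AB <- subset_structure(s, sort(c(ia, ib)))
  ra <- if (is.null(radii_override)) NULL else radii_override[ia]
  rb <- if (is.null(radii_override)) NULL else radii_override[ib]
  rab <- if (is.null(radii_override)) NULL
  else radii_override[sort(c(ia, ib))]
  sa <- sasa(A, p, ra)
  sb <- sasa(B, p, rb)
  sab <- sasa(AB, p, rab)
  in_a <- sort(c(ia, ib)) %in% ia
  burial_a <- sa$per_atom - sab$per_atom[in_a]
  burial_b <- sb$per_atom - sab$per_atom[!in_a]
  res <- list(bsa_total = sa$total + sb$total - sab$total,
              bsa_a = sum(burial_a), bsa_b = sum(burial_b),
              interface_area = (sa$total + sb$total - sab$total) / 2,
              sasa_a = sa$total, sasa_b = sb$total, sasa_ab = sab$total,
              per_atom_burial_a = burial_a, per_atom_burial_b = burial_b)
  if (!is.null(domains_a)) {
    res$per_domain_a <- vapply(domains_a, function(rr)
      sum(burial_a[A$atoms$resnum %in% rr]), numeric(1))
  }
  class(res) <- "tcs_interface"
  res
}

#' @export
print.tcs_interface <- function(x, ...) {
  cat(sprintf("<interface> BSA %.0f A^2 (A %.0f + B %.0f); interface area %.0f A^2\n",
              x$bsa_total, x$bsa_a, x$bsa_b, x$interface_area))
  if (!is.null(x$per_domain_a))
    cat("  partner-A burial by domain:",
        paste(sprintf("%s %.0f", names(x$per_domain_a), x$per_domain_a),
              collapse = ", "), "\n")
  invisible(x)
}

#' Interface footprint: residues of A in contact with B
#'
#' @param s a `tcs_structure`.
#' @param a_sel,b_sel partner [selection()]s.
#' @param cutoff any-atom distance cutoff in Angstrom (default 4.0).
#' @param p [sasa_params()] used for the per-residue buried-area column.
#' @return data.frame with chain, resnum, resname, min_dist, n_contacts,
#'   buried_area for every residue of A within the cutoff of B.
#' @export
interface_footprint <- function(s, a_sel, b_sel, cutoff = 4.0,
                                p = sasa_params()) {
  ia <- which(selection_mask(s, a_sel))
  ib <- which(selection_mask(s, b_sel))
  if (!length(ia) || !length(ib))
    return(data.frame(chain = character(0), resnum = integer(0),
                      resname = character(0), min_dist = numeric(0),
                      n_contacts = integer(0), buried_area = numeric(0)))
  xa <- as.matrix(s$atoms[ia, c("x", "y", "z")])
  xb <- as.matrix(s$atoms[ib, c("x", "y", "z")])
  mind <- vapply(seq_len(nrow(xa)), function(k)
    sqrt(min(rowSums(sweep(xb, 2, xa[k, ])^2))), numeric(1))
  contact <- mind <= cutoff
  if (!any(contact))
    return(data.frame(chain = character(0), resnum = integer(0),
                      resname = character(0), min_dist = numeric(0),
                      n_contacts = integer(0), buried_area = numeric(0)))
  akey <- paste(s$atoms$chain[ia], s$atoms$resnum[ia], sep = "\r")
  bur <- buried_surface(s, a_sel, b_sel, p)
  A_atoms <- s$atoms[ia, , drop = FALSE]
  rows <- lapply(unique(akey[contact]), function(k) {
    sel <- akey == k
    data.frame(chain = A_atoms$chain[sel][1],
               resnum = A_atoms$resnum[sel][1],
               resname = A_atoms$resname[sel][1],
               min_dist = min(mind[sel]),
               n_contacts = sum(mind[sel] <= cutoff),
               buried_area = sum(bur$per_atom_burial_a[sel]))
  })
  out <- do.call(rbind, rows)
  out[order(out$chain, out$resnum), , drop = FALSE]
}
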