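#' Torsion angle defined by four points
#'
#' IUPAC sign convention: looking down the p2->p3 bond, the angle is
#' positive when the far bond (p3->p4) is rotated clockwise from the near
#' bond (p2->p1 projected).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return torsion angle in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

get_bb_atom <- function(s, chain, resnum, name) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resnum == resnum & a$name == name & !a$het)
  if (!length(i)) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' Backbone phi/psi dihedral of a residue
#'
#' phi is C(i-1)-N(i)-CA(i)-C(i); psi is N(i)-CA(i)-C(i)-N(i+1). The sign
#' convention is the standard IUPAC one (trans-planar peptide: psi = 180).
#' Used e.g. to read the proline psi angle that signals whether the
#' receiver-domain beta4-alpha4 "phosphate lid" is open (psi near +126
#' degrees) or closed into a wound alpha4 first turn (psi near -40).
#'
#' @param s a `tcs_structure`.
#' @param chain chain id.
#' @param resnum author residue number.
#' @param angle "phi" or "psi".
#' @return the dihedral in degrees, in (-180, 180].
#' @export
backbone_dihedral <- function(s, chain, resnum, angle = c("phi", "psi")) {
  angle <- match.arg(angle)
  need <- if (angle == "psi")
    list(c(resnum, "N"), c(resnum, "CA"), c(resnum, "C"), c(resnum + 1, "N"))
  else
    list(c(resnum - 1, "C"), c(resnum, "N"), c(resnum, "CA"), c(resnum, "C"))
  pts <- vector("list", 4)
  for (k in seq_along(need)) {
    rn <- as.integer(need[[k]][1]); nm <- need[[k]][2]
    p <- get_bb_atom(s, chain, rn, nm)
    if (is.null(p)) {
      if (rn != resnum)
        stop(sprintf("undefined %s dihedral: chain break, residue %d absent (atom %s) in chain %s",
                     angle, rn, nm, chain))
      stop(sprintf("missing backbone atom %s of residue %d chain %s",
                   nm, rn, chain))
    }
    pts[[k]] <- p
  }
  torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}
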