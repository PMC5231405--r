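#' Lawrence-Colman shape complementarity (Sc)
#'
#' Quantifies how well two buried interface patches mirror each other.
#' Surface dots are sampled on each partner's van der Waals surface
#' (dots falling inside another atom of the same partner are removed, a
#' solvent-excluded-surface approximation). A dot belongs to the buried
#' patch when the opposing partner occludes solvent there, i.e. when the
#' gap to the partner's surface is smaller than a probe diameter. Dots
#' within `trim` of the patch periphery are discarded. For each remaining
#' dot x_a with outward normal n_a, the nearest buried dot x_b on the other
#' patch contributes
#'
#'   S(x_a) = -(n_a . n_b) * exp(-w * |x_a - x_b|^2)
#'
#' so perfectly apposed parallel surfaces score +1. Sc is the mean of the
#' two per-patch medians. Values run from -1 to 1; tight protein interfaces
#' score around 0.7, loose ones lower.
#'
#' @param s a `tcs_structure`.
#' @param a_sel,b_sel partner [selection()]s.
#' @param p a [sasa_params()] (radius table and probe are reused here).
#' @param w Gaussian distance weight in 1/Angstrom^2 (default 0.5).
#' @param n_dots dots per atom sphere (default 320; raise for small
#'   systems).
#' @param trim peripheral band width in Angstrom (default 1.5).
#' @param radii_override optional per-atom radii for the full structure.
#' @param keep_dots also return the surface dot sets and patch indices
#'   (for diagnostics and independent recomputation); default FALSE.
#' @return object of class `tcs_sc`: `sc`, per-patch medians `sc_a`,
#'   `sc_b`, dot counts `n_dots_a`, `n_dots_b`, and the per-dot score
#'   vectors `s_a`, `s_b` (plus `dots` when `keep_dots`).
#' @export
shape_complementarity <- function(s, a_sel, b_sel, p = sasa_params(),
                                  w = 0.5, n_dots = 320, trim = 1.5,
                                  radii_override = NULL, keep_dots = FALSE) {
  ia <- which(selection_mask(s, a_sel))
  ib <- which(selection_mask(s, b_sel))
  if (!length(ia) || !length(ib)) stop("empty partner selection")
  A <- subset_structure(s, ia)
  B <- subset_structure(s, ib)
  ra <- atom_radii(A, p, if (is.null(radii_override)) NULL
                   else radii_override[ia])
  rb <- atom_radii(B, p, if (is.null(radii_override)) NULL
                   else radii_override[ib])
  da <- surface_dots(coords(A), ra, n_dots)
  db <- surface_dots(coords(B), rb, n_dots)
  if (!nrow(da$xyz) || !nrow(db$xyz))
    stop("no exposed surface dots on one of the partners")
  probe <- p$probe_radius
  ba <- patch_split(da, coords(B), rb, 2 * probe, trim)
  bb <- patch_split(db, coords(A), ra, 2 * probe, trim)
  if (!length(ba$buried) || !length(bb$buried))
    stop("undefined Sc: empty buried patch (no interface?)")
  s_a <- dot_scores(da, ba$buried, db, bb$buried_untrimmed, w)
  s_b <- dot_scores(db, bb$buried, da, ba$buried_untrimmed, w)
  obj <- list(sc = (stats::median(s_a) + stats::median(s_b)) / 2,
              sc_a = stats::median(s_a), sc_b = stats::median(s_b),
              n_dots_a = length(s_a), n_dots_b = length(s_b),
              s_a = s_a, s_b = s_b, w = w)
  if (keep_dots)
    obj$dots <- list(a = da, b = db, patch_a = ba, patch_b = bb)
  class(obj) <- "tcs_sc"
  obj
}

#' @export
print.tcs_sc <- function(x, ...) {
  cat(sprintf("<shape complementarity> Sc = %.3f (A-side %.3f over %d dots, B-side %.3f over %d dots)\n",
              x$sc, x$sc_a, x$n_dots_a, x$sc_b, x$n_dots_b))
  invisible(x)
}

# gap from each dot to the nearest point of a sphere-union surface
surface_gap <- function(dots_xyz, xyz, radii) {
  gap <- rep(Inf, nrow(dots_xyz))
  for (j in seq_len(nrow(xyz))) {
    dj <- sqrt((dots_xyz[, 1] - xyz[j, 1])^2 +
                 (dots_xyz[, 2] - xyz[j, 2])^2 +
                 (dots_xyz[, 3] - xyz[j, 3])^2) - radii[j]
    gap <- pmin(gap, dj)
  }
  gap
}

# dots on the van der Waals surface of a set of atoms, with outward normals;
# dots inside any other atom of the same set are removed
surface_dots <- function(xyz, radii, n_dots) {
  base <- golden_spiral(n_dots)
  out_xyz <- list(); out_nrm <- list()
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    sp <- sweep(base * radii[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_dots)
    ci <- xyz[i, ]
    d2c <- (xyz[, 1] - ci[1])^2 + (xyz[, 2] - ci[2])^2 + (xyz[, 3] - ci[3])^2
    nbs <- which(d2c < (radii[i] + radii)^2 & seq_len(n) != i)
    for (j in nbs) {
      if (!any(keep)) break
      dj <- rowSums(sweep(sp[keep, , drop = FALSE], 2, xyz[j, ])^2)
      keep[keep] <- dj >= (radii[j] - 1e-9)^2
    }
    if (any(keep)) {
      out_xyz[[length(out_xyz) + 1L]] <- sp[keep, , drop = FALSE]
      out_nrm[[length(out_nrm) + 1L]] <- base[keep, , drop = FALSE]
    }
  }
  list(xyz = do.call(rbind, out_xyz), nrm = do.call(rbind, out_nrm))
}

# classify dots of one partner against the other partner's atoms:
# buried = gap to the partner's vdW surface < gap_cut; peripheral trim drops
# buried dots closer than `trim` to an exposed dot of the same partner
patch_split <- function(dots, other_xyz, other_radii, gap_cut, trim) {
  gap <- surface_gap(dots$xyz, other_xyz, other_radii)
  buried <- which(gap < gap_cut)
  exposed <- which(gap >= gap_cut)
  keep <- buried
  if (length(buried) && length(exposed) && trim > 0) {
    # only exposed dots near the patch's bounding box can trim anything
    bx <- dots$xyz[buried, , drop = FALSE]
    lo <- apply(bx, 2, min) - trim; hi <- apply(bx, 2, max) + trim
    ex_all <- dots$xyz[exposed, , drop = FALSE]
    nearby <- ex_all[, 1] >= lo[1] & ex_all[, 1] <= hi[1] &
      ex_all[, 2] >= lo[2] & ex_all[, 2] <= hi[2] &
      ex_all[, 3] >= lo[3] & ex_all[, 3] <= hi[3]
    ex <- ex_all[nearby, , drop = FALSE]
    if (nrow(ex)) {
      near_edge <- vapply(seq_len(nrow(bx)), function(k) {
        min((ex[, 1] - bx[k, 1])^2 + (ex[, 2] - bx[k, 2])^2 +
              (ex[, 3] - bx[k, 3])^2) < trim^2
      }, logical(1))
      keep <- buried[!near_edge]
    }
    if (!length(keep)) keep <- buried  # tiny patches: keep untrimmed
  }
  list(buried = keep, buried_untrimmed = buried)
}

dot_scores <- function(da, ia, db, ib, w) {
  xb <- db$xyz[ib, , drop = FALSE]
  nb <- db$nrm[ib, , drop = FALSE]
  vapply(ia, function(k) {
    d2 <- (xb[, 1] - da$xyz[k, 1])^2 + (xb[, 2] - da$xyz[k, 2])^2 +
      (xb[, 3] - da$xyz[k, 3])^2
    j <- which.min(d2)
    -sum(da$nrm[k, ] * nb[j, ]) * exp(-w * d2[j])
  }, numeric(1))
}
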