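#' Construct a rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1 within
#'   1e-8).
#' @param translation numeric length-3 vector (Angstrom).
#' @return object of class `tcs_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1 (no reflections)")
  obj <- list(rotation = rotation, translation = translation)
  class(obj) <- "tcs_transform"
  obj
}

#' Rotation matrix about an arbitrary axis
#' @param axis numeric length-3 axis (need not be unit).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Invert a rigid transform
#' @param t a `tcs_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a structure
#'
#' Maps every position x to R x + t. All pairwise distances are preserved.
#'
#' @param s a `tcs_structure`.
#' @param t a `tcs_transform`.
#' @return the transformed structure.
#' @export
apply_transform <- function(s, t) {
  stopifnot(inherits(t, "tcs_transform"))
  xyz <- coords(s)
  set_coords(s, t(t$rotation %*% t(xyz)) +
               matrix(t$translation, nrow(xyz), 3, byrow = TRUE))
}

atom_keys <- function(s, key, chain_map = NULL) {
  a <- s$atoms
  ch <- a$chain
  if (!is.null(chain_map)) {
    mapped <- chain_map[ch]
    ch <- ifelse(is.na(mapped), ch, mapped)
  }
  if (key == "chain_resnum_atom")
    paste(ch, a$resnum, a$icode, a$name, sep = "\r")
  else
    paste(a$resnum, a$icode, a$name, sep = "\r")
}

#' Pair equivalent atoms between two structures
#'
#' Atoms are matched on (mapped chain, author residue number, insertion
#' code, atom name) or on (residue number, atom name) when chains should be
#' ignored. Unmatched atoms are dropped silently but counted in the result.
#'
#' @param a,b `tcs_structure` objects.
#' @param key "chain_resnum_atom" (default) or "resnum_atom".
#' @param chain_map named character vector mapping a-chain ids to b-chain
#'   ids (e.g. `c(A = "C")`), or NULL for identity.
#' @return data.frame with columns `ia`, `ib` (row indices into the two
#'   atom tables), with attributes `n_unmatched_a`, `n_unmatched_b`.
#' @export
pair_atoms <- function(a, b, key = c("chain_resnum_atom", "resnum_atom"),
                       chain_map = NULL) {
  key <- match.arg(key)
  # map a's chains into b's labelling, then match on b's own labels
  ka <- atom_keys(a, key, chain_map)
  kb <- atom_keys(b, key, NULL)
  if (anyDuplicated(ka)) ka[duplicated(ka)] <- paste0(ka[duplicated(ka)], "+")
  ib <- match(ka, kb)
  sel <- which(!is.na(ib))
  pairs <- data.frame(ia = sel, ib = ib[sel])
  if (nrow(pairs) < 3L)
    stop("insufficient atom pairs for superposition (need >= 3, got ",
         nrow(pairs), ")")
  attr(pairs, "n_unmatched_a") <- nrow(a$atoms) - nrow(pairs)
  attr(pairs, "n_unmatched_b") <- nrow(b$atoms) - nrow(pairs)
  pairs
}

kabsch_core <- function(P, Q) {
  # optimal proper rotation R and translation t minimizing ||(R q + t) - p||
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(Q0, P0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- pc - as.vector(R %*% qc)
  list(R = R, t = t)
}

rmsd_xyz <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation + translation that minimizes the rmsd of b's
#' fitted atoms onto a's; no reflection is ever returned. When an
#' evaluation selection is given, its rmsd is computed with the fitted
#' transform applied as-is, without refitting -- the two-regime contrast
#' used to quantify interface slippage depends on this.
#'
#' @param a reference `tcs_structure`.
#' @param b mobile `tcs_structure`.
#' @param fit_sel [selection()] defining the fitted region (applied to both
#'   structures; NULL fits all paired atoms).
#' @param eval_sel optional [selection()] for a separately evaluated rmsd.
#' @param chain_map named chain mapping from a's chains to b's, or NULL.
#' @param key atom pairing key, see [pair_atoms()].
#' @return object of class `tcs_superposition`: `transform`
#'   (`tcs_transform` to apply to b), `rmsd_fit` (Angstrom), `n_pairs`,
#'   and if requested `rmsd_eval`, `n_eval`.
#' @export
kabsch_fit <- function(a, b, fit_sel = NULL, eval_sel = NULL,
                       chain_map = NULL,
                       key = c("chain_resnum_atom", "resnum_atom")) {
  key <- match.arg(key)
  af <- if (is.null(fit_sel)) a else select_atoms(a, fit_sel)
  bf <- if (is.null(fit_sel)) b else select_atoms(b, fit_sel)
  pr <- pair_atoms(af, bf, key = key, chain_map = chain_map)
  P <- coords(af)[pr$ia, , drop = FALSE]
  Q <- coords(bf)[pr$ib, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
    stop("degenerate (collinear) fit set; superposition is ill-defined")
  k <- kabsch_core(P, Q)
  tf <- rigid_transform(k$R, k$t)
  Qfit <- sweep(Q %*% t(k$R), 2, k$t, "+")
  res <- list(transform = tf,
              rmsd_fit = rmsd_xyz(P, Qfit),
              n_pairs = nrow(pr))
  if (!is.null(eval_sel)) {
    ae <- select_atoms(a, eval_sel)
    be <- select_atoms(b, eval_sel)
    pe <- pair_atoms(ae, be, key = key, chain_map = chain_map)
    Pe <- coords(ae)[pe$ia, , drop = FALSE]
    Qe <- coords(be)[pe$ib, , drop = FALSE]
    Qe <- sweep(Qe %*% t(k$R), 2, k$t, "+")
    res$rmsd_eval <- rmsd_xyz(Pe, Qe)
    res$n_eval <- nrow(pe)
  }
  class(res) <- "tcs_superposition"
  res
}

#' @export
print.tcs_superposition <- function(x, ...) {
  cat(sprintf("<tcs_superposition> rmsd_fit %.4f A over %d pairs%s\n",
              x$rmsd_fit, x$n_pairs,
              if (!is.null(x$rmsd_eval))
                sprintf("; rmsd_eval %.4f A over %d pairs",
                        x$rmsd_eval, x$n_eval) else ""))
  invisible(x)
}

#' Transplant a moiety from a donor structure by superposition
#'
#' Fits the donor onto the target over a shared region and carries
#' donor-only atoms (a phosphoryl group, a BeF3- mimic, a cation, a
#' phospho-His side chain) into the target frame. This is the standard
#' modeling move for completing a reaction center whose crystal lacks a
#' moiety that a homologous structure supplies. The graft's internal
#' geometry is preserved exactly; grafted atoms are flagged with the
#' donor's source id. Grafted atoms closer than `clash_cutoff` to a target
#' atom raise a warning (not an error), with the offending contacts listed.
#'
#' @param target `tcs_structure` receiving the graft.
#' @param donor `tcs_structure` supplying it.
#' @param fit_sel [selection()] on the region shared by both.
#' @param graft_sel [selection()] (applied to the donor) naming the atoms to
#'   carry over.
#' @param chain_map named chain mapping from target chains to donor chains.
#' @param key atom pairing key for the fit.
#' @param clash_cutoff Angstrom; default 1.5.
#' @return the target structure with the grafted atoms appended
#'   (provenance = donor source), with attributes `superposition` (the fit)
#'   and `clashes` (data.frame of short contacts, possibly empty).
#' @export
transplant_moiety <- function(target, donor, fit_sel, graft_sel,
                              chain_map = NULL,
                              key = c("chain_resnum_atom", "resnum_atom"),
                              clash_cutoff = 1.5) {
  key <- match.arg(key)
  fit <- kabsch_fit(target, donor, fit_sel = fit_sel, chain_map = chain_map,
                    key = key)
  graft <- select_atoms(donor, graft_sel)
  if (n_atoms(graft) == 0L)
    stop("graft selection matches no donor atoms")
  graft <- apply_transform(graft, fit$transform)
  ga <- graft$atoms
  ga$provenance <- rep(if (nzchar(donor$source)) donor$source else "donor",
                       nrow(ga))
  ga$serial <- max(target$atoms$serial) + seq_len(nrow(ga))
  # clash screen against the target
  tx <- coords(target); gx <- as.matrix(ga[, c("x", "y", "z")])
  clashes <- data.frame(graft_name = character(0), graft_res = integer(0),
                        target_name = character(0), target_res = integer(0),
                        dist = numeric(0))
  for (i in seq_len(nrow(gx))) {
    d <- sqrt(rowSums(sweep(tx, 2, gx[i, ])^2))
    hit <- which(d < clash_cutoff)
    if (length(hit))
      clashes <- rbind(clashes, data.frame(
        graft_name = ga$name[i], graft_res = ga$resnum[i],
        target_name = target$atoms$name[hit],
        target_res = target$atoms$resnum[hit], dist = d[hit]))
  }
  if (nrow(clashes))
    warning(sprintf("transplant places %d atom contact(s) under %.2f A (closest %.2f A: %s%d ~ %s%d)",
                    nrow(clashes), clash_cutoff, min(clashes$dist),
                    clashes$graft_name[which.min(clashes$dist)],
                    clashes$graft_res[which.min(clashes$dist)],
                    clashes$target_name[which.min(clashes$dist)],
                    clashes$target_res[which.min(clashes$dist)]))
  out <- target
  out$atoms <- rbind(target$atoms, ga)
  rownames(out$atoms) <- NULL
  attr(out, "superposition") <- fit
  attr(out, "clashes") <- clashes
  out
}
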