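#' Build an atom selection
#'
#' A selection is a conjunction of predicates over chains, author residue
#' numbers (inclusive ranges), atom names, and record categories. Waters and
#' hydrogens are excluded unless asked for, matching common practice for
#' X-ray geometry work; hetero (HETATM) atoms are included by default so
#' that cations and phosphoryl surrogates are reachable by name.
#'
#' @param chains character vector of chain ids, or NULL for all.
#' @param resnums integer vector of author residue numbers (e.g. `190:234`),
#'   or NULL for all. Ranges are inclusive at both ends.
#' @param atoms character vector of atom names (e.g. "CA", "NE2"), or NULL.
#' @param hetero "include" (default), "exclude" (ATOM records only) or
#'   "only" (HETATM records only).
#' @param waters include water residues (HOH/WAT/DOD)? Default FALSE.
#' @param hydrogens include hydrogen/deuterium atoms? Default FALSE.
#' @param icodes insertion codes to keep, or NULL for all.
#' @return an object of class `tcs_selection`.
#' @export
selection <- function(chains = NULL, resnums = NULL, atoms = NULL,
                      hetero = c("include", "exclude", "only"),
                      waters = FALSE, hydrogens = FALSE, icodes = NULL) {
  hetero <- match.arg(hetero)
  obj <- list(chains = chains,
              resnums = if (is.null(resnums)) NULL else as.integer(resnums),
              atoms = atoms, hetero = hetero, waters = waters,
              hydrogens = hydrogens, icodes = icodes)
  class(obj) <- "tcs_selection"
  obj
}

#' @export
print.tcs_selection <- function(x, ...) {
  part <- function(lab, v) if (is.null(v)) NULL else
    paste0(lab, "=", paste(utils::head(v, 8), collapse = ","),
           if (length(v) > 8) ",..." else "")
  cat("<tcs_selection>",
      paste(c(part("chain", x$chains),
              part("res", if (is.null(x$resnums)) NULL else range(x$resnums)),
              part("atom", x$atoms),
              paste0("hetero=", x$hetero)), collapse = " "), "\n")
  invisible(x)
}

selection_mask <- function(s, sel) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$resnums)) keep <- keep & a$resnum %in% sel$resnums
  if (!is.null(sel$atoms)) keep <- keep & a$name %in% sel$atoms
  if (!is.null(sel$icodes)) keep <- keep & a$icode %in% sel$icodes
  if (sel$hetero == "exclude") keep <- keep & !a$het
  if (sel$hetero == "only") keep <- keep & a$het
  if (!sel$waters) keep <- keep & !(a$resname %in% c("HOH", "WAT", "DOD"))
  if (!sel$hydrogens) keep <- keep & !(a$element %in% c("H", "D"))
  keep
}

#' Apply a selection to a structure
#'
#' @param s a `tcs_structure`.
#' @param sel a [selection()]. An empty result is valid.
#' @return the sub-structure containing exactly the atoms that satisfy every
#'   predicate, in their original order. Cell and provenance metadata are
#'   retained.
#' @export
select_atoms <- function(s, sel) {
  stopifnot(inherits(sel, "tcs_selection"))
  out <- s
  out$atoms <- s$atoms[selection_mask(s, sel), , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}
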