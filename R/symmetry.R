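#' Parse a crystallographic symmetry operator
#'
#' Accepts operators in fractional notation, e.g. `"x,y,z"`,
#' `"-y,x-y,z+2/3"`, `"1/2+x,1/2-y,-z"`, and returns the affine map acting
#' on fractional coordinates.
#'
#' @param op operator string: three comma-separated affine expressions in
#'   x, y, z with rational constants.
#' @return list with `R` (3x3 matrix) and `t` (length-3 translation, in
#'   fractional units).
#' @export
parse_symop <- function(op) {
  comps <- strsplit(gsub("[[:space:]]", "", op), ",")[[1]]
  if (length(comps) != 3L)
    stop("symmetry operator must have three comma-separated components: ", op)
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- comps[i]
    # tokenize into signed terms: variable terms (x, -y) or rationals (2/3)
    m <- gregexpr("[+-]?([xyz]|[0-9]+(/[0-9]+)?)", expr)[[1]]
    toks <- regmatches(expr, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(expr))
      stop("cannot parse symmetry operator component '", comps[i],
           "' (offending text: '",
           substr(expr, 1, 12), "')")
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        R[i, j] <- R[i, j] + sgn
      } else if (grepl("/", body)) {
        pq <- as.numeric(strsplit(body, "/")[[1]])
        tr[i] <- tr[i] + sgn * pq[1] / pq[2]
      } else {
        tr[i] <- tr[i] + sgn * as.numeric(body)
      }
    }
  }
  list(R = R, t = tr)
}

#' Fractional-to-orthogonal conversion matrix
#'
#' Standard PDB frame: a along x, b in the xy-plane.
#'
#' @param cell numeric length-6 (a, b, c, alpha, beta, gamma), Angstrom and
#'   degrees.
#' @return 3x3 matrix M with orthogonal = M %*% fractional.
#' @export
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Apply a crystallographic symmetry operator to a structure
#'
#' Positions are converted to fractional coordinates using the structure's
#' cell, transformed by the operator, and converted back. Intra-molecular
#' distances are preserved to numerical precision; this is how
#' symmetry-related copies of an asymmetric-unit complex (e.g. the
#' two-fold-completed half complex of a 2:2 HK:RR assembly) are generated.
#'
#' @param s a `tcs_structure` with cell parameters.
#' @param op operator string, see [parse_symop()].
#' @return the transformed structure (cell metadata retained, source tagged
#'   with the operator).
#' @export
apply_symmetry_operator <- function(s, op) {
  if (is.null(s$cell))
    stop("structure has no cell parameters; cannot apply symmetry operator")
  so <- parse_symop(op)
  M <- orth_matrix(s$cell)
  Minv <- solve(M)
  frac <- t(Minv %*% t(coords(s)))
  frac2 <- t(so$R %*% t(frac)) +
    matrix(so$t, nrow(frac), 3, byrow = TRUE)
  out <- set_coords(s, t(M %*% t(frac2)))
  out$source <- paste0(s$source, " [", op, "]")
  out
}
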