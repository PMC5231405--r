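#' Declare one HK:RR complex for the slippage analysis
#'
#' @param label entry name (e.g. an ASU-copy label).
#' @param structure a `tcs_structure` holding the complex.
#' @param hk_chain chain id of the HK protomer carrying the DHp helix that
#'   binds the RR.
#' @param rr_chain chain id of the receiver domain.
#' @param dhp_range author residue numbers of the structurally invariant
#'   DHp region (default 190:234).
#' @param rec_range author residue numbers of the receiver domain (default
#'   1:129).
#' @return object of class `tcs_complex_entry`.
#' @export
complex_entry <- function(label, structure, hk_chain, rr_chain,
                          dhp_range = 190:234, rec_range = 1:129) {
  stopifnot(inherits(structure, "tcs_structure"))
  ca_dhp <- select_atoms(structure,
                         selection(chains = hk_chain, resnums = dhp_range,
                                   atoms = "CA", hetero = "exclude"))
  ca_rec <- select_atoms(structure,
                         selection(chains = rr_chain, resnums = rec_range,
                                   atoms = "CA", hetero = "exclude"))
  if (n_atoms(ca_dhp) == 0L)
    stop("entry ", label, ": no CA atoms in DHp range of chain ", hk_chain)
  if (n_atoms(ca_rec) == 0L)
    stop("entry ", label, ": no CA atoms in REC range of chain ", rr_chain)
  obj <- list(label = label, structure = structure, hk_chain = hk_chain,
              rr_chain = rr_chain, dhp_range = dhp_range,
              rec_range = rec_range)
  class(obj) <- "tcs_complex_entry"
  obj
}

#' Two-regime pairwise superposition ("slippage") matrix
#'
#' For every pair of complexes, two superpositions are computed: one
#' fitting the structurally invariant DHp region of the kinase, one fitting
#' the receiver (REC) domain on itself. In both regimes the reported value
#' is the rmsd over all REC CA atoms, computed with the fitted transform
#' applied as-is (no refitting). A large DHp-regime rmsd combined with a
#' small REC-regime rmsd means the receiver does not change internally but
#' slips as a rigid body along the kinase: the signature of a "slippery"
#' interface. Missing residues in an entry shrink the pair set
#' symmetrically for every cell involving that entry, keeping cells
#' comparable.
#'
#' @param entries list of [complex_entry()] objects (>= 2).
#' @return object of class `tcs_slippage`: `labels`, `M_dhp` and `M_rec`
#'   (symmetric matrices, Angstrom, zero diagonals), `n_rec_pairs` (matrix
#'   of evaluated CA pair counts), and `failures` (per-pair error strings,
#'   if any).
#' @export
superposition_matrix <- function(entries) {
  stopifnot(length(entries) >= 2L,
            all(vapply(entries, inherits, logical(1), "tcs_complex_entry")))
  n <- length(entries)
  labels <- vapply(entries, `[[`, character(1), "label")
  M_dhp <- matrix(0, n, n, dimnames = list(labels, labels))
  M_rec <- matrix(0, n, n, dimnames = list(labels, labels))
  n_pairs <- matrix(0L, n, n, dimnames = list(labels, labels))
  failures <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ei <- entries[[i]]; ej <- entries[[j]]
    cm <- stats::setNames(c(ej$hk_chain, ej$rr_chain),
                          c(ei$hk_chain, ei$rr_chain))
    dhp_sel_i <- selection(chains = ei$hk_chain, resnums = ei$dhp_range,
                           atoms = "CA", hetero = "exclude")
    rec_sel_i <- selection(chains = ei$rr_chain, resnums = ei$rec_range,
                           atoms = "CA", hetero = "exclude")
    res <- tryCatch({
      fit_dhp <- kabsch_fit(ei$structure, ej$structure,
                            fit_sel = dhp_sel_i, eval_sel = rec_sel_i,
                            chain_map = cm)
      fit_rec <- kabsch_fit(ei$structure, ej$structure,
                            fit_sel = rec_sel_i, eval_sel = rec_sel_i,
                            chain_map = cm)
      list(dhp = fit_dhp$rmsd_eval, rec = fit_rec$rmsd_eval,
           np = fit_dhp$n_eval)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s ~ %s: %s", labels[i], labels[j],
                                      conditionMessage(res)))
      M_dhp[i, j] <- M_dhp[j, i] <- NA_real_
      M_rec[i, j] <- M_rec[j, i] <- NA_real_
    } else {
      M_dhp[i, j] <- M_dhp[j, i] <- res$dhp
      M_rec[i, j] <- M_rec[j, i] <- res$rec
      n_pairs[i, j] <- n_pairs[j, i] <- res$np
    }
  }
  slippage_matrix(labels, M_dhp, M_rec, n_rec_pairs = n_pairs,
                  failures = failures)
}

#' Assemble a slippage matrix from precomputed values
#'
#' Also the entry point for published rmsd matrices transcribed as data:
#' supply the symmetric DHp-regime and REC-regime matrices directly.
#'
#' @param labels entry labels.
#' @param M_dhp,M_rec square symmetric matrices (Angstrom), zero diagonal.
#' @param n_rec_pairs optional matrix of evaluated pair counts.
#' @param failures optional character vector of per-pair failures.
#' @return object of class `tcs_slippage`.
#' @export
slippage_matrix <- function(labels, M_dhp, M_rec, n_rec_pairs = NULL,
                            failures = character(0)) {
  n <- length(labels)
  M_dhp <- as.matrix(M_dhp); M_rec <- as.matrix(M_rec)
  stopifnot(all(dim(M_dhp) == n), all(dim(M_rec) == n))
  for (M in list(M_dhp, M_rec)) {
    if (any(abs(diag(M)) > 1e-9, na.rm = TRUE))
      stop("slippage matrix diagonals must be zero")
    if (max(abs(M - t(M)), na.rm = TRUE) > 1e-6)
      stop("slippage matrices must be symmetric within 1e-6 A")
  }
  dimnames(M_dhp) <- dimnames(M_rec) <- list(labels, labels)
  obj <- list(labels = labels, M_dhp = M_dhp, M_rec = M_rec,
              n_rec_pairs = n_rec_pairs, failures = failures)
  class(obj) <- "tcs_slippage"
  obj
}

#' Load a slippage matrix from a Table-5-style mixed-triangle TSV
#'
#' The conventional publication layout stores the DHp-fit regime below the
#' main diagonal and the REC-fit regime above it, in one square table.
#'
#' @param path TSV file: first column labels, remaining columns the square
#'   mixed matrix, blank/NA diagonal allowed.
#' @return object of class `tcs_slippage` with both triangles symmetrized.
#' @export
read_slippage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  n <- nrow(m)
  stopifnot(ncol(m) == n)
  labels <- rownames(m)
  M_dhp <- matrix(0, n, n); M_rec <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i > j) M_dhp[i, j] <- M_dhp[j, i] <- m[i, j]
    if (i < j) M_rec[i, j] <- M_rec[j, i] <- m[i, j]
  }
  slippage_matrix(labels, M_dhp, M_rec)
}

off_diag <- function(M) M[upper.tri(M)]

#' Summary statistics of a slippage matrix
#'
#' @param m a `tcs_slippage`.
#' @return list with `max_dhp`, `mean_dhp`, `max_rec`, `mean_rec`, the
#'   contrast `mean_dhp - mean_rec`, the per-cell difference matrix
#'   `diff = M_dhp - M_rec`, and `n_violations`, the number of cells where
#'   the DHp-regime rmsd is (unexpectedly) smaller than the REC-regime
#'   rmsd.
#' @export
slippage_summary <- function(m) {
  stopifnot(inherits(m, "tcs_slippage"))
  dh <- off_diag(m$M_dhp); re <- off_diag(m$M_rec)
  list(max_dhp = max(dh, na.rm = TRUE),
       mean_dhp = mean(dh, na.rm = TRUE),
       max_rec = max(re, na.rm = TRUE),
       mean_rec = mean(re, na.rm = TRUE),
       contrast = mean(dh, na.rm = TRUE) - mean(re, na.rm = TRUE),
       diff = m$M_dhp - m$M_rec,
       n_violations = sum(dh < re, na.rm = TRUE))
}

#' Write a slippage matrix in the mixed-triangle publication layout
#'
#' Lower triangle: DHp-fit regime; upper: REC-fit regime; empty diagonal.
#' A long-format companion table (pair, regime, rmsd) is written next to it
#' with suffix `_long.tsv`.
#'
#' @param m a `tcs_slippage`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_slippage_tsv <- function(m, path) {
  n <- length(m$labels)
  out <- matrix("", n, n, dimnames = list(m$labels, m$labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i > j) out[i, j] <- sprintf("%.3f", m$M_dhp[i, j])
    if (i < j) out[i, j] <- sprintf("%.3f", m$M_rec[i, j])
  }
  utils::write.table(cbind(label = m$labels, out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(m$M_dhp), arr.ind = TRUE)
  long <- rbind(
    data.frame(a = m$labels[idx[, 1]], b = m$labels[idx[, 2]],
               regime = "dhp_fit", rmsd = m$M_dhp[idx]),
    data.frame(a = m$labels[idx[, 1]], b = m$labels[idx[, 2]],
               regime = "rec_fit", rmsd = m$M_rec[idx]))
  utils::write.table(long, sub("\\.tsv$", "_long.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
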