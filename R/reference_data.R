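#' Published reaction-center benchmark table
#'
#' Reactive His(NE2)-Asp(OD1) distances, reaction-coordinate distances and
#' Mg2+ asymmetry ratios reported for deposited two-component-system
#' complexes (PDB ids 2FTK, 2R25, 4EUK, 4QPJ, 4BIW, 4KP4, 5DKF, 3DGE,
#' 5IUK, 3KYJ), one row per independently refined complex in each
#' asymmetric unit, together with the published Group I/II assignment.
#' Used to validate [classify_mechanism()] against the published partition
#' and as the benchmark for recomputation when the deposited coordinate
#' files are available locally.
#'
#' @return data.frame with columns complex, pdb_id, copy, category,
#'   d_his_asp, d_rxn, r_mg, group_published, direction, mg_modeled_from,
#'   note.
#' @export
reference_rc_table <- function() {
  path <- system.file("extdata", "rc_benchmark.tsv", package = "tcsgeom",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
}

#' Published slippage-matrix benchmark
#'
#' The 9 x 9 two-regime superposition matrix reported for the nine
#' independently refined DesKC:DesR-REC pairs (three from the phosphatase
#' crystal form including its symmetry-completed copy, labelled STAB1-3,
#' and six from the three phosphotransferase forms, labelled E188_1-6):
#' DHp-regime rmsds below the diagonal, REC-regime rmsds above it, in
#' Angstrom over the 129 receiver CA atoms.
#'
#' @return a `tcs_slippage` object (see [slippage_matrix()]).
#' @export
reference_slippage_matrix <- function() {
  path <- system.file("extdata", "slippage_benchmark.tsv",
                      package = "tcsgeom", mustWork = TRUE)
  read_slippage_tsv(path)
}

#' Locate a locally fetched deposited structure
#'
#' The package never downloads coordinates. Deposited entries must be
#' fetched once by the user and placed (as `<id>.pdb` or `<id>.cif`) in
#' the directory given here or by `options(tcsgeom.structure_dir = ...)`.
#'
#' @param id 4-character PDB accession, e.g. "5IUN".
#' @param dir directory to search (default the `tcsgeom.structure_dir`
#'   option, falling back to "data_deposited").
#' @return the file path, or NA (with the canonical fetch command in a
#'   message) when the file is absent.
#' @export
deposited_structure_path <- function(id,
                                     dir = getOption("tcsgeom.structure_dir",
                                                     "data_deposited")) {
  for (ext in c(".pdb", ".cif", ".ent", ".mmcif")) {
    p <- file.path(dir, paste0(tolower(id), ext))
    if (file.exists(p)) return(p)
    p <- file.path(dir, paste0(toupper(id), ext))
    if (file.exists(p)) return(p)
  }
  message("Deposited entry ", id, " not found under '", dir, "'. Fetch it with:\n",
          "  curl -O https://files.rcsb.org/download/", toupper(id), ".cif\n",
          "and place it in that directory.")
  NA_character_
}
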