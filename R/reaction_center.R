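#' Describe a phosphotransfer reaction center
#'
#' Names the atoms that define His->Asp phosphotransfer geometry: the
#' phosphorylatable histidine (HK side), the receiver aspartate (RR side),
#' the divalent cation, and the phosphoryl group or its surrogate.
#'
#' @param hk_chain,his_resnum chain and author residue number of the
#'   reactive His.
#' @param rr_chain,asp_resnum chain and author residue number of the
#'   receiver Asp.
#' @param mg "auto" (nearest Mg-like cation within `mg_radius` of the Asp
#'   Od atoms), "none", or `list(chain =, resnum =)` naming it explicitly.
#' @param surrogate phosphoryl-group surrogate to look for: "auto" (P on a
#'   phospho-His residue, then Be of a BeF3- ligand near the Asp, then an
#'   ATP-analog gamma-phosphorus), "phis", "bef", "gammap", or "none".
#' @param od_policy "OD1" (the conventional reported atom) or "nearest"
#'   (whichever of OD1/OD2 is nearer the His NE2; crystallographic OD1/OD2
#'   labelling is chemically arbitrary).
#' @param entering "asp_od" for His->Asp transfer (the reaction-coordinate
#'   distance runs surrogate -> Asp Od) or "his_ne2" for autophosphorylation
#'   geometries (surrogate -> His NE2).
#' @param mg_radius Angstrom search radius for "auto" cation lookup
#'   (default 8).
#' @param phis_resnames residue codes recognized as phosphorylated His
#'   variants (default NEP, HIP, HISP).
#' @return object of class `tcs_rc_spec`.
#' @export
reaction_center_spec <- function(hk_chain, his_resnum, rr_chain, asp_resnum,
                                 mg = "auto",
                                 surrogate = c("auto", "phis", "bef",
                                               "gammap", "none"),
                                 od_policy = c("OD1", "nearest"),
                                 entering = c("asp_od", "his_ne2"),
                                 mg_radius = 8,
                                 phis_resnames = c("NEP", "HIP", "HISP")) {
  obj <- list(hk_chain = hk_chain, his_resnum = as.integer(his_resnum),
              rr_chain = rr_chain, asp_resnum = as.integer(asp_resnum),
              mg = mg, surrogate = match.arg(surrogate),
              od_policy = match.arg(od_policy),
              entering = match.arg(entering),
              mg_radius = mg_radius, phis_resnames = phis_resnames)
  class(obj) <- "tcs_rc_spec"
  obj
}

atom_index <- function(s, chain, resnum, name) {
  a <- s$atoms
  which(a$chain == chain & a$resnum == resnum & a$name %in% name)
}

atom_pos <- function(s, i) c(s$atoms$x[i], s$atoms$y[i], s$atoms$z[i])

#' Locate the reactive atoms of a phosphotransfer center
#'
#' @param s a `tcs_structure`.
#' @param spec a [reaction_center_spec()].
#' @return list with atom-row indices `ne2`, `od` (plus `od_name`), and, if
#'   found, `mg` and `p` (plus `p_kind`); absent optional atoms are NA, not
#'   errors.
#' @export
locate_reactive_atoms <- function(s, spec) {
  stopifnot(inherits(spec, "tcs_rc_spec"))
  a <- s$atoms
  his_rows <- which(a$chain == spec$hk_chain & a$resnum == spec$his_resnum)
  if (!length(his_rows))
    stop(sprintf("residue %d not found in chain %s", spec$his_resnum,
                 spec$hk_chain))
  ne2 <- his_rows[a$name[his_rows] == "NE2"]
  if (!length(ne2))
    stop(sprintf("atom NE2 absent from residue %s%d chain %s",
                 a$resname[his_rows[1]], spec$his_resnum, spec$hk_chain))
  ne2 <- ne2[1]
  asp_rows <- which(a$chain == spec$rr_chain & a$resnum == spec$asp_resnum)
  if (!length(asp_rows))
    stop(sprintf("residue %d not found in chain %s", spec$asp_resnum,
                 spec$rr_chain))
  od_rows <- asp_rows[a$name[asp_rows] %in% c("OD1", "OD2")]
  if (!length(od_rows))
    stop(sprintf("atoms OD1/OD2 absent from residue %s%d chain %s",
                 a$resname[asp_rows[1]], spec$asp_resnum, spec$rr_chain))
  if (spec$od_policy == "OD1") {
    od <- od_rows[a$name[od_rows] == "OD1"]
    if (!length(od))
      stop(sprintf("atom OD1 absent from residue %d chain %s",
                   spec$asp_resnum, spec$rr_chain))
    od <- od[1]
  } else {
    pn <- atom_pos(s, ne2)
    d <- vapply(od_rows, function(i) sqrt(sum((atom_pos(s, i) - pn)^2)),
                numeric(1))
    od <- od_rows[which.min(d)]
  }
  res <- list(ne2 = ne2, od = od, od_name = a$name[od],
              mg = NA_integer_, p = NA_integer_, p_kind = NA_character_)
  # cation
  if (is.list(spec$mg)) {
    mg <- atom_index(s, spec$mg$chain, spec$mg$resnum, c("MG", "MN", "ZN"))
    if (!length(mg))
      stop(sprintf("no cation atom at chain %s residue %d",
                   spec$mg$chain, spec$mg$resnum))
    res$mg <- mg[1]
  } else if (identical(spec$mg, "auto")) {
    cand <- which(a$het & a$element %in% c("MG", "MN", "ZN"))
    if (length(cand)) {
      ref <- as.matrix(a[od_rows, c("x", "y", "z")])
      dmin <- vapply(cand, function(i) {
        min(sqrt(rowSums(sweep(ref, 2, atom_pos(s, i))^2)))
      }, numeric(1))
      ok <- which(dmin <= spec$mg_radius)
      if (length(ok)) res$mg <- cand[ok[which.min(dmin[ok])]]
    }
  }
  # phosphoryl surrogate
  find_phis <- function() {
    i <- his_rows[a$name[his_rows] == "P" |
                    (a$resname[his_rows] %in% spec$phis_resnames &
                       grepl("^P", a$name[his_rows]))]
    if (length(i)) i[1] else NA_integer_
  }
  find_bef <- function() {
    i <- which(a$resname %in% c("BEF", "BF3") & a$element == "BE")
    if (!length(i)) return(NA_integer_)
    po <- atom_pos(s, res$od)
    d <- vapply(i, function(j) sqrt(sum((atom_pos(s, j) - po)^2)), numeric(1))
    j <- i[which.min(d)]
    if (min(d) <= 6) j else NA_integer_
  }
  find_gammap <- function() {
    i <- which(a$het & a$name == "PG" & a$element == "P")
    if (!length(i)) return(NA_integer_)
    pn <- atom_pos(s, res$ne2)
    d <- vapply(i, function(j) sqrt(sum((atom_pos(s, j) - pn)^2)), numeric(1))
    i[which.min(d)]
  }
  res$p <- switch(spec$surrogate,
                  none = NA_integer_,
                  phis = find_phis(),
                  bef = find_bef(),
                  gammap = find_gammap(),
                  auto = {
                    p <- find_phis(); kind <- "phis"
                    if (is.na(p)) { p <- find_bef(); kind <- "bef" }
                    if (is.na(p)) { p <- find_gammap(); kind <- "gammap" }
                    if (!is.na(p)) res$p_kind <- kind
                    p
                  })
  if (spec$surrogate != "auto" && spec$surrogate != "none" && !is.na(res$p))
    res$p_kind <- spec$surrogate
  if (spec$surrogate %in% c("phis", "bef", "gammap") && is.na(res$p))
    stop("requested ", spec$surrogate, " surrogate not found in structure")
  res
}

#' Measure the reaction-center geometry
#'
#' Computes the reactive His(NE2)-Asp(Od) distance, the reaction-coordinate
#' distance (phosphorus surrogate to the entering atom, defined only when a
#' surrogate is present), the cation-to-Asp and cation-to-His distances and
#' their asymmetry ratio r = d(Mg-AspOd) / d(Mg-HisNE2). All distances in
#' Angstrom at full internal precision; display rounding (1 decimal for
#' distances, 2 for the ratio) is left to the reporting layer.
#'
#' @param s a `tcs_structure`.
#' @param spec a [reaction_center_spec()].
#' @return object of class `tcs_rc_geometry` with fields `d_his_asp`,
#'   `d_rxn`, `d_mg_asp`, `d_mg_his`, `r_mg`, `od_used`, `surrogate_kind`,
#'   `modeled_flags` (provenance strings of any transplanted atom used).
#' @export
measure_center <- function(s, spec) {
  loc <- locate_reactive_atoms(s, spec)
  d <- function(i, j) sqrt(sum((atom_pos(s, i) - atom_pos(s, j))^2))
  g <- list(d_his_asp = d(loc$ne2, loc$od),
            d_rxn = NA_real_, d_mg_asp = NA_real_, d_mg_his = NA_real_,
            r_mg = NA_real_, od_used = loc$od_name,
            surrogate_kind = loc$p_kind)
  if (!is.na(loc$p)) {
    entering <- if (spec$entering == "asp_od") loc$od else loc$ne2
    g$d_rxn <- d(loc$p, entering)
  }
  if (!is.na(loc$mg)) {
    g$d_mg_asp <- d(loc$mg, loc$od)
    g$d_mg_his <- d(loc$mg, loc$ne2)
    g$r_mg <- g$d_mg_asp / g$d_mg_his
  }
  used <- c(loc$ne2, loc$od, loc$mg, loc$p)
  used <- used[!is.na(used)]
  prov <- unique(s$atoms$provenance[used])
  g$modeled_flags <- prov[!is.na(prov)]
  class(g) <- "tcs_rc_geometry"
  g
}

#' @export
print.tcs_rc_geometry <- function(x, ...) {
  cat(sprintf("<reaction center> d(His NE2 - Asp %s) = %.1f A; d_rxn = %s; r_Mg = %s%s\n",
              x$od_used, x$d_his_asp,
              if (is.na(x$d_rxn)) "ND" else sprintf("%.1f A", x$d_rxn),
              if (is.na(x$r_mg)) "ND" else sprintf("%.2f", x$r_mg),
              if (length(x$modeled_flags))
                paste0(" [modeled: ",
                       paste(x$modeled_flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Classify a reaction center as associative- or dissociative-type
#'
#' Group I (associative-compatible, reversible-transfer geometry) requires
#' a short reactive distance AND a near-symmetric cation; Group II
#' (dissociative, unidirectional His->Asp geometry) a long distance AND an
#' asymmetric cation. Anything else -- including exact threshold hits -- is
#' ambiguous. When the ratio is unavailable the call is made on distance
#' alone and flagged lower-confidence. A note records when the
#' reaction-coordinate distance (>= 4.9 A) leaves room for a fully
#' dissociated metaphosphate intermediate; the related van-der-Waals bound
#' for full dissociation in terms of the N-O distance (6.6 A) is reported
#' as context, not used as a second threshold.
#'
#' @param g a `tcs_rc_geometry`, or a numeric `d_his_asp`.
#' @param r_mg cation asymmetry ratio (ignored when `g` is a geometry
#'   object).
#' @param d_rxn optional reaction-coordinate distance.
#' @param d_cut distance threshold in Angstrom (default 6.5).
#' @param r_cut ratio threshold (default 0.6).
#' @return object of class `tcs_mechanism`: `group` ("I", "II" or
#'   "ambiguous"), `mechanism`, `confidence`, `d_cut`, `r_cut`, `note`.
#' @export
classify_mechanism <- function(g, r_mg = NA_real_, d_rxn = NA_real_,
                               d_cut = 6.5, r_cut = 0.6) {
  if (inherits(g, "tcs_rc_geometry")) {
    d <- g$d_his_asp; r <- g$r_mg; dr <- g$d_rxn
  } else {
    d <- as.numeric(g); r <- r_mg; dr <- d_rxn
  }
  if (is.na(d)) stop("d_his_asp is required for classification")
  confidence <- "full"
  if (is.na(r)) {
    confidence <- "distance-only"
    group <- if (d < d_cut) "I" else if (d > d_cut) "II" else "ambiguous"
  } else {
    group <- if (d < d_cut && r > r_cut) "I"
    else if (d > d_cut && r < r_cut) "II"
    else "ambiguous"
  }
  mech <- switch(group,
                 I = "associative-compatible",
                 II = "dissociative",
                 ambiguous = "ambiguous")
  note <- character(0)
  if (!is.na(dr) && dr >= 4.9)
    note <- c(note, sprintf(
      "reaction coordinate %.1f A >= 4.9 A: room for a fully dissociated metaphosphate",
      dr))
  obj <- list(group = group, mechanism = mech, confidence = confidence,
              d_cut = d_cut, r_cut = r_cut,
              note = if (length(note)) paste(note, collapse = "; ") else "")
  class(obj) <- "tcs_mechanism"
  obj
}

#' @export
print.tcs_mechanism <- function(x, ...) {
  cat(sprintf("<mechanism> Group %s (%s)%s%s\n", x$group, x$mechanism,
              if (x$confidence != "full") paste0(" [", x$confidence, "]")
              else "",
              if (nzchar(x$note)) paste0(" -- ", x$note) else ""))
  invisible(x)
}

#' Batch reaction-center table
#'
#' One row per HK:RR complex (each independently refined copy in an
#' asymmetric unit is its own entry), with measured geometry, mechanism
#' call, and modeled-moiety provenance. The `d_his_asp` and `r_mg` columns
#' are the two axes of the distance-vs-asymmetry scatter on which Group I
#' and Group II complexes separate into two clusters. Per-row failures are
#' recorded in the `error` column; the batch continues.
#'
#' @param entries list of lists, each with `structure`, `spec` and `label`.
#' @param d_cut,r_cut classification thresholds, see
#'   [classify_mechanism()].
#' @return data.frame with columns label, source, d_his_asp, d_rxn,
#'   d_mg_asp, d_mg_his, r_mg, od_used, surrogate, group, mechanism,
#'   confidence, modeled, note, error.
#' @export
rc_table <- function(entries, d_cut = 6.5, r_cut = 0.6) {
  stopifnot(length(entries) >= 1L)
  rows <- lapply(entries, function(e) {
    base <- data.frame(label = e$label,
                       source = e$structure$source,
                       d_his_asp = NA_real_, d_rxn = NA_real_,
                       d_mg_asp = NA_real_, d_mg_his = NA_real_,
                       r_mg = NA_real_, od_used = NA_character_,
                       surrogate = NA_character_, group = NA_character_,
                       mechanism = NA_character_,
                       confidence = NA_character_, modeled = "",
                       note = "", error = "",
                       stringsAsFactors = FALSE)
    tryCatch({
      g <- measure_center(e$structure, e$spec)
      m <- classify_mechanism(g, d_cut = d_cut, r_cut = r_cut)
      base$d_his_asp <- g$d_his_asp
      base$d_rxn <- g$d_rxn
      base$d_mg_asp <- g$d_mg_asp
      base$d_mg_his <- g$d_mg_his
      base$r_mg <- g$r_mg
      base$od_used <- g$od_used
      base$surrogate <- if (is.na(g$surrogate_kind)) "" else g$surrogate_kind
      base$group <- m$group
      base$mechanism <- m$mechanism
      base$confidence <- m$confidence
      base$modeled <- paste(g$modeled_flags, collapse = ";")
      base$note <- m$note
      base
    }, error = function(err) {
      base$error <- conditionMessage(err)
      base
    })
  })
  do.call(rbind, rows)
}
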