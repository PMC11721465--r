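#' Parse a point-variant name into mutated positions
#'
#' Variant names are slash-separated point substitutions such as
#' `"L69D/L71D"`; `"WT"` parses to an empty position set.
#'
#' @param name Variant name.
#' @return Integer vector of 1-based mutated positions.
#' @export
parse_variant <- function(name) {
  if (toupper(name) == "WT") return(integer(0))
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", parts)
  if (!all(ok))
    stop("cannot parse variant name '", name, "'", call. = FALSE)
  as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", parts))
}

#' Residue-to-site assignment for the TREM2 Ig domain panel
#'
#' The structural site of each mutated residue in the bundled variant
#' panel: the hydrophobic site (CDR-loop residues), the basic site
#' (arginine-rich strands), basic-adjacent residues, site 2 (around
#' 122-123), and `ad_risk` for AD-risk positions (87, 96) that sit in
#' none of the structural sites.  AD-risk variants at structural
#' positions (R47H, R62H) carry their structural label and are flagged
#' separately at the variant level.
#'
#' @return Named character vector: names are residue positions, values
#'   are site labels.
#' @export
trem2_site_assignment <- function() {
  sites <- c(
    `41` = "hydrophobic", `44` = "hydrophobic", `69` = "hydrophobic",
    `70` = "hydrophobic", `71` = "hydrophobic", `74` = "hydrophobic",
    `89` = "hydrophobic",
    `46` = "basic", `47` = "basic", `62` = "basic", `76` = "basic",
    `77` = "basic",
    `75` = "basic_adjacent", `78` = "basic_adjacent", `85` = "basic_adjacent",
    `122` = "site2", `123` = "site2",
    `87` = "ad_risk", `96` = "ad_risk")
  sites
}

.ad_risk_variants <- c("R47H", "R62H", "D87N", "T96K")

#' Site label of a variant
#'
#' @param name Variant name ("WT" has no site).
#' @param assignment Residue-site map, default [trem2_site_assignment()].
#' @return Site label; errors if residues of one variant span sites.
#' @export
variant_site <- function(name, assignment = trem2_site_assignment()) {
  pos <- parse_variant(name)
  if (!length(pos)) return(NA_character_)
  labs <- assignment[as.character(pos)]
  if (any(is.na(labs)))
    stop("no site assignment for residue(s) ",
         paste(pos[is.na(labs)], collapse = ", "), " in '", name, "'",
         call. = FALSE)
  u <- unique(labs)
  if (length(u) != 1)
    stop("variant '", name, "' spans multiple sites", call. = FALSE)
  unname(u)
}

.unit_to_molar <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Read a variant-panel TSV
#'
#' Expected columns: `variant`, `ligand`, `KD` (numeric or empty),
#' `KD_unit` (M, mM, uM, nM, pM), `class` (binding |
#' decreased_binding | binding_not_fit | no_binding_detected) and
#' optionally `fold_printed` (the tabulated fold change as printed, kept
#' as a string so its decimal precision is known).
#'
#' @param path TSV path; default is the bundled ligand panel
#'   transcription.
#' @return data.frame with `KD_M` added (K_D in molar).
#' @export
read_panel <- function(path = system.file("extdata", "trem2_ligand_panels.tsv",
                                          package = "bliscan")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(fold_printed = "character"),
                         fileEncoding = "UTF-8-BOM")
  need <- c("variant", "ligand", "KD", "KD_unit", "class")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("panel format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !d$KD_unit %in% names(.unit_to_molar) & !is.na(d$KD)
  if (any(bad))
    stop("panel format error: unknown KD unit '", d$KD_unit[bad][1], "'",
         call. = FALSE)
  d$KD_M <- d$KD * .unit_to_molar[d$KD_unit]
  d
}

#' Build variant records with fold changes versus wild type
#'
#' Joins a panel table with per-ligand WT references, computes fold
#' changes via [fold_change()], and attaches site labels and AD-risk
#' flags.  Variants with no measurable binding carry class
#' `no_binding_detected` and an undefined fold.
#'
#' @param panel data.frame from [read_panel()] (or of the same shape).
#' @param assignment Residue-site map.
#' @return data.frame: `variant, ligand, site, ad_risk, KD_M, class,
#'   fold, fold_2dp, direction`.
#' @export
build_panel <- function(panel, assignment = trem2_site_assignment()) {
  out <- lapply(split(panel, panel$ligand), function(d) {
    wt <- d[toupper(d$variant) == "WT", , drop = FALSE]
    if (nrow(wt) != 1)
      stop("missing WT reference for ligand '", d$ligand[1], "'",
           call. = FALSE)
    # a qualitative panel (class calls only, no WT K_D) gets NA folds
    quantitative <- is.finite(wt$KD_M)
    d$site <- vapply(d$variant, function(v)
      if (toupper(v) == "WT") NA_character_
      else variant_site(v, assignment), character(1))
    d$ad_risk <- d$variant %in% .ad_risk_variants
    fc <- lapply(seq_len(nrow(d)), function(i) {
      if (!quantitative || !is.finite(d$KD_M[i]) ||
          d$class[i] == "no_binding_detected")
        return(list(ratio = NA_real_, ratio_2dp = NA_real_,
                    direction = NA_character_))
      fold_change(d$KD_M[i], wt$KD_M)
    })
    d$fold <- vapply(fc, `[[`, numeric(1), "ratio")
    d$fold_2dp <- vapply(fc, `[[`, numeric(1), "ratio_2dp")
    d$direction <- vapply(fc, `[[`, character(1), "direction")
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Check computed fold changes against a printed fold column
#'
#' Recomputes every fold change from the K_D columns, rounds half-up to
#' the precision of the printed value, and reports agreement.  Rows
#' whose recomputed value differs from the printed one by exactly one
#' unit in the last printed digit are flagged as rounding notes rather
#' than silently passed (or hidden).
#'
#' @param panel data.frame from [build_panel()] with a `fold_printed`
#'   character column.
#' @return data.frame: `variant, ligand, fold_printed, fold_computed,
#'   match, note`.
#' @export
check_fold_table <- function(panel) {
  d <- panel[!is.na(panel$fold_printed) & nzchar(panel$fold_printed) &
             is.finite(panel$fold), , drop = FALSE]
  res <- lapply(seq_len(nrow(d)), function(i) {
    printed <- d$fold_printed[i]
    digs <- if (grepl(".", printed, fixed = TRUE))
      nchar(sub("^[^.]*\\.", "", printed)) else 0L
    comp <- round_half_up(d$fold[i], digs)
    pv <- as.numeric(printed)
    unit <- 10^-digs
    note <- if (isTRUE(all.equal(comp, pv))) ""
            else if (abs(comp - pv) <= unit + 1e-9) "one_unit_rounding_mismatch"
            else "mismatch"
    data.frame(variant = d$variant[i], ligand = d$ligand[i],
               fold_printed = pv, fold_computed = comp,
               match = note == "", note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-site verdicts and primary-site call for one ligand
#'
#' Aggregates a ligand's variant records into one verdict per
#' structural site, from the strongest effect among that site's
#' variants: `ablating` (any no-binding variant) > `severe` (fold
#' decrease >= `severe_fold`) > `moderate` (fold decrease >=
#' `moderate_fold`, or a qualitative decreased-binding call) >
#' `neutral`.  A site whose only effect is a >= `moderate_fold` affinity
#' *increase* is `enhancing`; sites with both inhibitory and enhancing
#' variants keep the inhibitory verdict and set `has_enhancing`
#' (conflicts are reported, not resolved).  AD-risk-only records never
#' determine the primary site.  The primary site is the site with the
#' strongest verdict (ties broken by largest fold decrease); the
#' secondary site is the next site at moderate or stronger.
#'
#' @param panel data.frame from [build_panel()].
#' @param ligand Ligand name to call.
#' @param severe_fold,moderate_fold Verdict thresholds (defaults 10, 2).
#' @return `site_call` object with `ligand`, `verdicts` (data.frame),
#'   `primary`, `secondary`.
#' @export
call_sites <- function(panel, ligand, severe_fold = 10, moderate_fold = 2) {
  d <- panel[panel$ligand == ligand & !is.na(panel$site), , drop = FALSE]
  if (!nrow(d)) stop("no variant records for ligand '", ligand, "'",
                     call. = FALSE)
  struct <- d[d$site != "ad_risk", , drop = FALSE]
  if (length(unique(struct$site)) < 2)
    stop("panel must cover >= 2 structural sites for ligand '", ligand, "'",
         call. = FALSE)
  rank_of <- c(ablating = 4, severe = 3, moderate = 2,
               enhancing = 1, neutral = 0)
  verdicts <- lapply(split(d, d$site), function(s) {
    dec <- s$direction == "decrease" & is.finite(s$fold)
    inc <- s$direction == "increase" & is.finite(s$fold)
    max_dec <- if (any(dec)) max(s$fold[dec]) else NA_real_
    has_enh <- any(inc & s$fold >= moderate_fold)
    v <- if (any(s$class == "no_binding_detected")) "ablating"
      else if (any(dec & s$fold >= severe_fold)) "severe"
      else if (any(dec & s$fold >= moderate_fold) ||
               any(s$class == "decreased_binding")) "moderate"
      else if (has_enh) "enhancing"
      else "neutral"
    data.frame(site = s$site[1], verdict = v, max_fold_decrease = max_dec,
               has_enhancing = has_enh, n_variants = nrow(s),
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- NULL
  vs <- verdicts[verdicts$site != "ad_risk", , drop = FALSE]
  vs$rank <- rank_of[vs$verdict]
  vs <- vs[order(-vs$rank, -ifelse(is.na(vs$max_fold_decrease), 0,
                                   vs$max_fold_decrease)), ]
  primary <- if (vs$rank[1] >= rank_of["moderate"]) vs$site[1] else NA_character_
  secondary <- if (nrow(vs) > 1 && vs$rank[2] >= rank_of["moderate"])
    vs$site[2] else NA_character_
  structure(list(ligand = ligand, verdicts = verdicts,
                 primary = primary, secondary = secondary),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("Site call for %s: primary = %s, secondary = %s\n",
              x$ligand, x$primary %||% "none",
              if (is.na(x$secondary)) "none" else x$secondary))
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Ligand-by-site verdict matrix
#'
#' @param calls List of `site_call` objects (one per ligand).
#' @return data.frame: one row per ligand, one column per site
#'   (stable order: hydrophobic, basic, basic_adjacent, site2, ad_risk)
#'   plus `primary`.
#' @export
ligand_site_matrix <- function(calls) {
  if (inherits(calls, "site_call")) calls <- list(calls)
  site_order <- c("hydrophobic", "basic", "basic_adjacent", "site2", "ad_risk")
  rows <- lapply(calls, function(x) {
    v <- stats::setNames(rep("not_tested", length(site_order)), site_order)
    v[x$verdicts$site] <- x$verdicts$verdict
    c(list(ligand = x$ligand), as.list(v),
      list(primary = x$primary %||% NA_character_))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out[order(out$ligand), , drop = FALSE]
}

#' Region annotations used by the hydropathy screen
#'
#' Bundled sequence-region definitions for the TREM2 Ig domain (18-130),
#' its CDR loops (CDR1 39-46, CDR2 69-75, CDR3 88-91) and basic-site
#' strands (47-50, 62-68, 76-78, 112-114), the mature IL-34 region
#' (excluding the residue 1-20 signal peptide), and the five clustered
#' candidate regions on IL-34 (71-85, 90-100, 119-129, 142-151,
#' 156-179).  The IL-34 cluster coordinates are region annotations on
#' the screen's *output* scale; they are not claimed to be the helix
#' boundaries used as screen motifs.
#'
#' @return data.frame: `protein, name, start, end, kind`.
#' @export
region_annotations <- function() {
  d <- rbind(
    data.frame(protein = "TREM2", name = "ig_domain", start = 18, end = 130,
               kind = "domain"),
    data.frame(protein = "TREM2", name = c("CDR1", "CDR2", "CDR3"),
               start = c(39, 69, 88), end = c(46, 75, 91), kind = "cdr_loop"),
    data.frame(protein = "TREM2",
               name = paste0("basic_strand", 1:4),
               start = c(47, 62, 76, 112), end = c(50, 68, 78, 114),
               kind = "basic_strand"),
    data.frame(protein = "IL34", name = "mature", start = 21, end = 241,
               kind = "domain"),
    data.frame(protein = "IL34",
               name = paste0("cluster_helix", c(2, 3, 4, 5, 6)),
               start = c(71, 90, 119, 142, 156),
               end = c(85, 100, 129, 151, 179),
               kind = "predicted_region"))
  rownames(d) <- NULL
  d
}

#' Read / write a region-annotation JSON config
#'
#' @param path JSON file.
#' @param regions data.frame as from [region_annotations()].
#' @return `read_region_config` returns the data.frame.
#' @export
write_region_config <- function(regions, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required for JSON configs", call. = FALSE)
  jsonlite::write_json(regions, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_config
#' @export
read_region_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite required for JSON configs", call. = FALSE)
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
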