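# MS1 matching of observed features against the candidate library, MS/MS
# diagnostic-fragment corroboration, control-group exclusion and annotation
# confidence levels.

#' Diagnostic fragment rules for conjugate classes (negative mode)
#'
#' For each conjugate class: the diagnostic fragment anions (elemental
#' composition, theoretical m/z via [anion_mz()]) and the neutral losses whose
#' complement reveals the aglycone. Glucuronides show the glucuronic acid
#' anion ladder (175.0248, 113.0244, 99.0088, 85.0295, 75.0088, 59.0139) and
#' lose the intact C6H8O6 moiety (176.0321). Sulfates show the SO3 radical
#' anion (79.9574) and lose SO3. Taurine conjugates show the taurine anion
#' (124.0074), C2H3O3S- (106.9808) and SO3; the amide can cleave on either
#' side, so both C2H5NO2S (ester-type) and C2H4O3S (amide-type, nitrogen
#' retained on the aglycone) are accepted as complement-defining losses.
#' Glycine conjugates show the glycinate anion (74.0247) and lose CO2 or
#' HCOOH from the precursor.
#'
#' @return A named list of class `fragment_rules`; one element per conjugate
#'   class with data frames `diagnostics` (`formula`, `mz`) and `losses`
#'   (`formula`, `mass`).
#' @export
fragment_rules <- function() {
  mk <- function(diag, loss) {
    list(diagnostics = data.frame(
           formula = diag,
           mz = vapply(diag, anion_mz, numeric(1)),
           stringsAsFactors = FALSE, row.names = NULL),
         losses = data.frame(
           formula = loss,
           mass = vapply(loss, monoisotopic_mass, numeric(1)),
           stringsAsFactors = FALSE, row.names = NULL))
  }
  structure(list(
    glucuronide = mk(c("C6H7O6", "C5H5O3", "C4H3O3", "C4H5O2", "C2H3O3",
                       "C2H3O2"),
                     "C6H8O6"),
    sulfate = mk("SO3", "SO3"),
    taurine = mk(c("C2H6NO3S", "C2H3O3S", "SO3"),
                 c("C2H5NO2S", "C2H4O3S")),
    glycine = mk("C2H4NO2", c("CO2", "CH2O2"))
  ), class = "fragment_rules")
}

#' Match observed features against a candidate library at MS1 level
#'
#' Every (feature, candidate) pair whose signed mass error is within
#' `tol_ppm` becomes a hit. Hits for one feature are ranked by absolute ppm
#' error, then by the number of transformations (simpler candidates first),
#' then by label; ties are reported, never silently dropped.
#'
#' @param features Data frame with at least `feature_id`, `mz` and optionally
#'   `rt` columns (see [read_features()]).
#' @param library A `candidate_library` from [enumerate_candidates()].
#' @param tol_ppm MS1 tolerance in ppm (default 10).
#' @param ion Which theoretical ion to match, `"[M-H]-"` or `"[M+H]+"`.
#' @return An `annotation_hits` data frame: `feature_id`, `rt`, `obs_mz`,
#'   `label`, `formula`, `theo_mz`, `ppm_error` (full precision), `n_steps`,
#'   `conjugate`, `rank`, `isotope_score` (NA until scored). Attribute
#'   `unmatched` lists feature ids with no hit.
#' @export
match_features <- function(features, library, tol_ppm = 10,
                           ion = c("[M-H]-", "[M+H]+")) {
  ion <- match.arg(ion)
  if (tol_ppm < 0) stop("tol_ppm must be >= 0", call. = FALSE)
  if (NROW(library) == 0L) stop("empty candidate library", call. = FALSE)
  theo <- if (ion == "[M-H]-") library$mz_mh else library$mz_ph
  res <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    err <- ppm_error(theo, features$mz[i])
    sel <- which(abs(err) <= tol_ppm)
    if (!length(sel)) next
    ord <- sel[order(abs(err[sel]), library$n_steps[sel], library$label[sel])]
    res[[i]] <- data.frame(
      feature_id = features$feature_id[i],
      rt = if ("rt" %in% names(features)) features$rt[i] else NA_real_,
      obs_mz = features$mz[i],
      label = library$label[ord],
      formula = library$formula[ord],
      theo_mz = theo[ord],
      ppm_error = err[ord],
      n_steps = library$n_steps[ord],
      conjugate = library$conjugate[ord],
      rank = seq_along(ord),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, res)
  if (is.null(hits))
    hits <- data.frame(feature_id = character(0), rt = numeric(0),
                       obs_mz = numeric(0), label = character(0),
                       formula = character(0), theo_mz = numeric(0),
                       ppm_error = numeric(0), n_steps = integer(0),
                       conjugate = character(0), rank = integer(0),
                       stringsAsFactors = FALSE)
  hits$isotope_score <- rep(NA_real_, nrow(hits))
  rownames(hits) <- NULL
  attr(hits, "unmatched") <-
    setdiff(features$feature_id,
            unique(hits$feature_id))
  class(hits) <- c("annotation_hits", "data.frame")
  hits
}

#' Keep only the top-ranked candidate per feature
#'
#' @param hits An `annotation_hits` data frame.
#' @return The subset with `rank == 1`.
#' @export
best_hits <- function(hits) {
  out <- hits[hits$rank == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Corroborate hits with MS/MS diagnostic fragments
#'
#' For each hit whose candidate carries a conjugate with a known fragment
#' rule, records which diagnostic fragments are present in the feature's
#' MS/MS spectrum and whether an aglycone complement (precursor theoretical
#' m/z minus a class neutral loss) is observed. Diagnostics heavier than the
#' precursor are never matched.
#'
#' @param hits `annotation_hits` data frame.
#' @param spectra Named list of MS/MS spectra keyed by `feature_id`; each a
#'   data frame with `mz` and `intensity_rel` columns (see [read_mgf()]).
#' @param rules A [fragment_rules()] list.
#' @param tol_mz Absolute fragment tolerance in Th (default 0.005; printed
#'   qToF fragment lists deviate from theory by up to ~5 mTh).
#' @return `hits` with added columns `has_ms2`, `n_diagnostics`,
#'   `diagnostics_matched` (semicolon-joined compositions) and
#'   `complement_matched`.
#' @export
assign_fragments <- function(hits, spectra, rules = fragment_rules(),
                             tol_mz = 0.005) {
  hits$has_ms2 <- hits$feature_id %in% names(spectra) &
    vapply(hits$feature_id, function(id) NROW(spectra[[id]]) > 0, logical(1))
  hits$n_diagnostics <- 0L
  hits$diagnostics_matched <- ""
  hits$complement_matched <- FALSE
  for (i in seq_len(nrow(hits))) {
    conj <- hits$conjugate[i]
    if (!nzchar(conj) || !hits$has_ms2[i]) next
    rule <- rules[[conj]]
    if (is.null(rule))
      stop("no fragment rule for conjugate class '", conj, "'", call. = FALSE)
    sp <- spectra[[hits$feature_id[i]]]
    diag <- rule$diagnostics[rule$diagnostics$mz <= hits$theo_mz[i] + tol_mz, ,
                             drop = FALSE]
    found <- vapply(diag$mz, function(m) any(abs(sp$mz - m) <= tol_mz),
                    logical(1))
    hits$n_diagnostics[i] <- sum(found)
    hits$diagnostics_matched[i] <- paste(diag$formula[found], collapse = ";")
    compl <- hits$theo_mz[i] - rule$losses$mass
    hits$complement_matched[i] <-
      any(vapply(compl, function(m) any(abs(sp$mz - m) <= tol_mz), logical(1)))
  }
  hits
}

#' Score hits against theoretical isotope patterns
#'
#' Advisory corroboration: where an observed isotope pattern is available for
#' a feature, compares it to the theoretical pattern of the candidate's
#' anion composition with [pattern_score()]. Features without an observed
#' pattern keep `isotope_score = NA` and are not penalized.
#'
#' @param hits `annotation_hits` data frame.
#' @param patterns Named list of observed `isotope_pattern`s by `feature_id`.
#' @param max_offset,prune Passed to [isotope_pattern()].
#' @return `hits` with `isotope_score` filled in where patterns were given.
#' @export
score_isotopes <- function(hits, patterns, max_offset = 3L, prune = 1e-4) {
  for (i in seq_len(nrow(hits))) {
    obs <- patterns[[hits$feature_id[i]]]
    if (is.null(obs)) next
    theo <- isotope_pattern(hits$formula[i], max_offset = max_offset,
                            prune = prune)
    hits$isotope_score[i] <- pattern_score(obs, theo)
  }
  hits
}

#' Flag hits whose feature is present in control groups
#'
#' A xenobiotic metabolite must be absent from non-exposed animals.
#' "Absent" is operationalized as near-absence: a hit is flagged
#' `control_present` when its mean intensity in any control group exceeds
#' `threshold` times its mean intensity across the exposed groups (or when it
#' has no signal in exposed samples at all).
#'
#' @param hits `annotation_hits` data frame.
#' @param features Feature table carrying one intensity column per sample id.
#' @param metadata Sample metadata with `sample_id` and `group` columns.
#' @param control_groups Group labels of non-exposed animals.
#' @param threshold Presence threshold as a fraction of the exposed-group
#'   mean (default 0.05).
#' @return `hits` with a logical `control_present` column; identified
#'   metabolites are the rows with `control_present == FALSE`.
#' @export
control_exclusion <- function(hits, features, metadata,
                              control_groups = c("NL", "HL"),
                              threshold = 0.05) {
  ctrl <- metadata$sample_id[metadata$group %in% control_groups]
  trt <- metadata$sample_id[!(metadata$group %in% control_groups)]
  if (!length(ctrl)) stop("no control samples in metadata", call. = FALSE)
  ctrl <- intersect(ctrl, names(features))
  trt <- intersect(trt, names(features))
  idx <- match(hits$feature_id, features$feature_id)
  flag <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    fi <- idx[i]
    trt_mean <- mean(as.numeric(features[fi, trt]))
    if (!is.finite(trt_mean) || trt_mean <= 0) { flag[i] <- TRUE; next }
    grp_means <- vapply(unique(metadata$group[metadata$sample_id %in% ctrl]),
                        function(g) {
      ids <- intersect(metadata$sample_id[metadata$group == g], ctrl)
      mean(as.numeric(features[fi, ids]))
    }, numeric(1))
    flag[i] <- any(grp_means > threshold * trt_mean)
  }
  hits$control_present <- flag
  hits
}

#' Assign annotation confidence levels
#'
#' Metabolomics-standards-style tiers for putative annotations: level `"2"`
#' when at least one diagnostic fragment or an aglycone complement is matched
#' (MS/MS-corroborated), level `"3"` for MS1-only matches, and `"rejected"`
#' when an available isotope score falls below `isotope_floor`. No level 1 is
#' ever assigned (that would require an authentic standard).
#'
#' @param hits `annotation_hits`, ideally after [assign_fragments()] and
#'   [score_isotopes()].
#' @param isotope_floor Rejection floor for the advisory isotope score
#'   (default 0.5); `NA` scores never reject.
#' @return `hits` with an `msi_level` character column (`"2"`, `"3"`,
#'   `"rejected"`).
#' @export
msi_level <- function(hits, isotope_floor = 0.5) {
  n_diag <- if ("n_diagnostics" %in% names(hits)) hits$n_diagnostics else
    rep(0L, nrow(hits))
  compl <- if ("complement_matched" %in% names(hits)) hits$complement_matched
    else rep(FALSE, nrow(hits))
  lev <- ifelse(n_diag > 0L | compl, "2", "3")
  rej <- !is.na(hits$isotope_score) & hits$isotope_score < isotope_floor
  lev[rej] <- "rejected"
  hits$msi_level <- lev
  hits
}

#' Assign positional-isomer suffixes by retention time
#'
#' Candidates are mass-level objects, so positional isomers share a label.
#' Where several features carry the same top-ranked label, they are suffixed
#' I, II, III ... in order of ascending retention time.
#'
#' @param hits Best-hit `annotation_hits` (one row per feature) with `rt`.
#' @return `hits` with a `display_label` column.
#' @export
assign_isomer_suffixes <- function(hits) {
  hits$display_label <- hits$label
  for (lab in unique(hits$label)) {
    rows <- which(hits$label == lab)
    if (length(rows) < 2L) next
    ord <- rows[order(hits$rt[rows])]
    hits$display_label[ord] <-
      paste(lab, as.character(utils::as.roman(seq_along(ord))))
  }
  hits
}
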