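# End-to-end convenience wrappers: screen the packaged reference feature set
# against the default limonene library, and build the matching demo
# simulation preset.

#' Screen the packaged limonene reference set
#'
#' Runs the whole annotation chain on the packaged metabolite fixture:
#' enumerates the default limonene candidate library, matches the 23
#' reference features at `tol_ppm`, corroborates with the printed MS/MS
#' fragment lists, assigns isomer suffixes by retention time, and counts
#' distinct metabolite identities (isomer groups collapsed) per tissue.
#'
#' @param tol_ppm MS1 tolerance in ppm (default 10).
#' @param frag_tol_mz Absolute fragment tolerance in Th (default 0.005).
#' @return A list: `hits` (best hit per feature, fragment-annotated, with
#'   `display_label` and `tissue`), `library`, `n_urine`, `n_liver`,
#'   `urine_labels`, `liver_labels`.
#' @examples
#' res <- screen_reference_set()
#' c(res$n_urine, res$n_liver)
#' @export
screen_reference_set <- function(tol_ppm = 10, frag_tol_mz = 0.005) {
  fixture <- load_fixture("limonene_metabolites")
  library <- enumerate_candidates("C10H16", default_rules(),
                                  parent_id = "limonene")
  features <- data.frame(feature_id = fixture$id, mz = fixture$mz,
                         rt = fixture$rt, stringsAsFactors = FALSE)
  hits <- match_features(features, library, tol_ppm = tol_ppm)
  top <- best_hits(hits)
  top <- assign_fragments(top, fixture_spectra(fixture),
                          tol_mz = frag_tol_mz)
  top <- msi_level(top)
  top <- assign_isomer_suffixes(top)
  top$tissue <- fixture$tissue[match(top$feature_id, fixture$id)]
  urine <- top[grepl("U", top$tissue), , drop = FALSE]
  liver <- top[grepl("L", top$tissue), , drop = FALSE]
  list(hits = top, library = library,
       n_urine = length(unique(urine$label)),
       n_liver = length(unique(liver$label)),
       urine_labels = sort(unique(urine$label)),
       liver_labels = sort(unique(liver$label)),
       unmatched = attr(hits, "unmatched"))
}

#' Demo simulation preset mirroring the reference urinary profile
#'
#' Builds a [sim_config()] whose planted metabolites are the 16 urinary
#' metabolite identities of the packaged fixture, with group mean
#' intensities proportional to the reported percent-of-total columns of the
#' two dose groups (scaled by `intensity_scale`). Isomer groups are
#' collapsed by summing their percentages, since mass-level candidates
#' cannot distinguish positional isomers.
#'
#' @param seed Integer seed for the cohort.
#' @param n_per_group Animals per group (default 8).
#' @param intensity_scale Raw-intensity scale factor (default 1e5).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
reference_sim_config <- function(seed, n_per_group = 8L,
                                 intensity_scale = 1e5, ...) {
  fixture <- load_fixture("limonene_metabolites")
  lo <- tapply(fixture$hl01_pct, fixture$label, sum)
  hi <- tapply(fixture$hl08_pct, fixture$label, sum)
  planted <- data.frame(label = names(lo),
                        HL0.1 = as.numeric(lo) / 100 * intensity_scale,
                        HL0.8 = as.numeric(hi) / 100 * intensity_scale,
                        stringsAsFactors = FALSE, check.names = FALSE)
  sim_config(planted,
             groups = c(NL = n_per_group, HL = n_per_group,
                        HL0.1 = n_per_group, HL0.8 = n_per_group),
             seed = seed, ...)
}
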