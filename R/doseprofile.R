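# Creatinine-normalized quantitative profiling across dose groups,
# percent-of-total composition, two-group statistics with normality routing,
# metabolic-switching classification and dose-accounting arithmetic.

#' Normalize urinary intensities by creatinine
#'
#' Divides each intensity by the corresponding urinary creatinine
#' concentration, correcting for urine dilution. Homogeneous of degree 1 in
#' intensity and -1 in creatinine; zero intensity stays zero.
#'
#' @param intensity Numeric vector of raw peak intensities (>= 0).
#' @param creatinine Creatinine concentrations (> 0), recycled if length 1.
#' @return Normalized intensities.
#' @export
normalize_by_creatinine <- function(intensity, creatinine) {
  if (any(creatinine <= 0))
    stop("creatinine must be positive", call. = FALSE)
  intensity / creatinine
}

#' Percent of total metabolite signal
#'
#' Expresses each metabolite's group-mean intensity as a percentage of the
#' summed means of all metabolites in the group. Sums to 100 exactly before
#' display rounding.
#'
#' @param means Named non-negative numeric vector of per-metabolite group
#'   means; at least one must be positive.
#' @return Named vector of percentages.
#' @export
percent_of_total <- function(means) {
  if (any(means < 0)) stop("means must be non-negative", call. = FALSE)
  total <- sum(means)
  if (total <= 0) stop("all metabolite means are zero", call. = FALSE)
  means / total * 100
}

#' Per-group creatinine-normalized metabolite profile
#'
#' Maps feature intensities to metabolite labels, normalizes by per-sample
#' creatinine, and summarizes per (metabolite, group): arithmetic mean
#' (zeros included -- a non-detected metabolite contributes 0), SD, and
#' percent of the group total.
#'
#' @param features Feature table (one intensity column per sample id).
#' @param metadata Sample metadata with `sample_id`, `group` and `creatinine`
#'   columns; rows with a `tissue` column are restricted to `"urine"`.
#' @param assignments Data frame mapping `feature_id` to metabolite `label`
#'   (e.g. `best_hits()` output, optionally with isomer `display_label`s).
#' @param groups Which groups to profile (default: all groups in metadata).
#' @return A `profile_table` data frame: `label`, `group`, `mean_norm`,
#'   `sd_norm`, `percent`.
#' @export
profile_table <- function(features, metadata, assignments, groups = NULL) {
  if ("tissue" %in% names(metadata))
    metadata <- metadata[metadata$tissue == "urine", , drop = FALSE]
  if (is.null(groups)) groups <- unique(metadata$group)
  lab_col <- if ("display_label" %in% names(assignments)) "display_label"
    else "label"
  labels <- assignments[[lab_col]]
  rows <- list()
  for (g in groups) {
    ids <- metadata$sample_id[metadata$group == g]
    ids <- intersect(ids, names(features))
    if (!length(ids)) stop("no samples for group '", g, "'", call. = FALSE)
    creat <- metadata$creatinine[match(ids, metadata$sample_id)]
    norm <- do.call(rbind, lapply(seq_len(nrow(assignments)), function(i) {
      fi <- match(assignments$feature_id[i], features$feature_id)
      normalize_by_creatinine(as.numeric(features[fi, ids]), creat)
    }))
    means <- rowMeans(norm)
    sds <- apply(norm, 1, stats::sd)
    pct <- percent_of_total(structure(means, names = labels))
    rows[[g]] <- data.frame(label = labels, group = g, mean_norm = means,
                            sd_norm = sds, percent = as.numeric(pct),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("profile_table", "data.frame")
  out
}

#' Two-group comparison with normality routing
#'
#' Both groups are checked with the Shapiro-Wilk test at `alpha`; if both
#' pass, a two-sided two-sample t test is used, otherwise the Wilcoxon
#' rank-sum test. The record states which branch was taken.
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @param alpha Normality-test significance level (default 0.05).
#' @param var_equal Passed to [stats::t.test()] when routed to t.
#' @return A `group_comparison` list: `test` (`"t"` or `"wilcoxon"`),
#'   `statistic`, `p_value`, `shapiro_p` (length 2).
#' @export
group_compare <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations", call. = FALSE)
  sw <- c(a = stats::shapiro.test(a)$p.value,
          b = stats::shapiro.test(b)$p.value)
  if (all(sw >= alpha)) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(test = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, shapiro_p = sw)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value, shapiro_p = sw)
  }
  structure(res, class = "group_comparison")
}

#' Metabolic-switching report between two dose groups
#'
#' Compares percent participation of each metabolite between a low- and a
#' high-dose profile and classifies the change as increased, decreased or
#' stable within a dead-band. Because both profiles sum to 100, the deltas
#' sum to zero.
#'
#' @param pct_low,pct_high Named percent vectors over the same metabolite
#'   set (e.g. columns of [profile_table()] output).
#' @param dead_band Half-width in percentage points of the "stable" band
#'   (default 0.5).
#' @return A `switching_report` data frame: `label`, `pct_low`, `pct_high`,
#'   `delta`, `direction`.
#' @export
switching_report <- function(pct_low, pct_high, dead_band = 0.5) {
  if (is.null(names(pct_low)) || is.null(names(pct_high)) ||
      !setequal(names(pct_low), names(pct_high)))
    stop("profiles must cover the same metabolite set", call. = FALSE)
  pct_high <- pct_high[names(pct_low)]
  delta <- unname(pct_high - pct_low)
  dir <- ifelse(delta > dead_band, "increased",
                ifelse(delta < -dead_band, "decreased", "stable"))
  out <- data.frame(label = names(pct_low), pct_low = unname(pct_low),
                    pct_high = unname(pct_high), delta = delta,
                    direction = dir, stringsAsFactors = FALSE)
  class(out) <- c("switching_report", "data.frame")
  out
}

#' Percent loss of an analyte between nominal and measured content
#'
#' @param nominal Nominal content (> 0), e.g. g analyte per 100 g feed.
#' @param measured Measured content in the same units.
#' @return `(nominal - measured) / nominal * 100`.
#' @examples
#' percent_loss(0.8, 0.67) # 16.25
#' @export
percent_loss <- function(nominal, measured) {
  if (any(nominal <= 0)) stop("nominal content must be positive", call. = FALSE)
  (nominal - measured) / nominal * 100
}

#' Human-equivalent dose by body-surface-area scaling
#'
#' Converts an animal dose (mg/kg) to a human-equivalent dose with the
#' standard Km correction factors (body weight / surface area): HED =
#' dose * Km_animal / Km_human. Defaults use mouse (Km 3) to human (Km 37).
#'
#' @param dose Animal dose in mg/kg (>= 0).
#' @param km_animal,km_human Km factors (> 0).
#' @return Human-equivalent dose in mg/kg.
#' @examples
#' human_equivalent_dose(90) # 7.3
#' @export
human_equivalent_dose <- function(dose, km_animal = 3, km_human = 37) {
  if (any(dose < 0) || km_animal <= 0 || km_human <= 0)
    stop("dose must be >= 0 and Km factors positive", call. = FALSE)
  dose * km_animal / km_human
}
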