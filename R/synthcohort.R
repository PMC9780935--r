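# Seeded generator of synthetic LC-MS cohorts (feature tables, MS/MS spectra,
# sample metadata, ground truth) with the statistical structure the screening
# pipeline assumes: planted metabolites with ppm-scale m/z jitter and
# log-normal between-animal variability, decoy background features kept away
# from any library mass, and template-based conjugate MS/MS spectra.

#' Configuration for a synthetic cohort
#'
#' @param planted Data frame with a `label` column (must exist in the
#'   candidate library) and one numeric column per exposed group giving the
#'   true mean raw intensity of that metabolite in that group.
#' @param groups Named integer vector: animals per group. Groups absent from
#'   `planted`'s columns are controls and receive zero intensity for planted
#'   metabolites (unless `control_leakage > 0`).
#' @param cv Between-animal coefficient of variation of intensities
#'   (log-normal model; default 0.4, the scale of the high interindividual
#'   variability seen in xenobiotic metabolism studies).
#' @param mz_sigma_ppm Gaussian m/z jitter SD in ppm (default 2, a typical
#'   calibrated-qToF mass accuracy).
#' @param n_decoys Number of decoy background features (default 50).
#' @param decoy_margin Minimum distance in Th between a decoy m/z and any
#'   library mass (default 0.05, far beyond 10 ppm below m/z 1000).
#' @param decoy_mz_range m/z range decoys are drawn from.
#' @param decoy_mean Mean raw intensity of decoys (present in all groups).
#' @param creatinine_mean,creatinine_cv Log-normal creatinine distribution
#'   for urine samples (arbitrary concentration units, mean 1).
#' @param ms2_dropout Per-fragment dropout probability in simulated spectra.
#' @param ms2_jitter_pct Relative-abundance jitter SD in percent of the
#'   template abundance.
#' @param control_leakage Fraction of the exposed-group mean leaked into
#'   control groups (default 0 = strict absence; nonzero values stress-test
#'   [control_exclusion()]).
#' @param seed Mandatory integer seed; identical configurations produce
#'   bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(planted,
                       groups = c(NL = 8L, HL = 8L, HL0.1 = 8L, HL0.8 = 8L),
                       cv = 0.4, mz_sigma_ppm = 2, n_decoys = 50L,
                       decoy_margin = 0.05, decoy_mz_range = c(100, 600),
                       decoy_mean = 5e4,
                       creatinine_mean = 1, creatinine_cv = 0.3,
                       ms2_dropout = 0.1, ms2_jitter_pct = 10,
                       control_leakage = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(groups >= 1L), cv >= 0, mz_sigma_ppm >= 0,
            creatinine_cv >= 0, ms2_dropout >= 0, ms2_dropout <= 1,
            control_leakage >= 0, decoy_margin > 0)
  exposed <- intersect(names(planted), names(groups))
  if (!length(exposed))
    stop("planted must have a mean column for at least one group",
         call. = FALSE)
  structure(list(planted = planted, groups = groups, cv = cv,
                 mz_sigma_ppm = mz_sigma_ppm, n_decoys = as.integer(n_decoys),
                 decoy_margin = decoy_margin, decoy_mz_range = decoy_mz_range,
                 decoy_mean = decoy_mean, creatinine_mean = creatinine_mean,
                 creatinine_cv = creatinine_cv, ms2_dropout = ms2_dropout,
                 ms2_jitter_pct = ms2_jitter_pct,
                 control_leakage = control_leakage,
                 exposed_groups = exposed, seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal draws with arithmetic mean `mean` and coefficient of variation
# `cv` (sdlog = sqrt(log(1 + cv^2))); degenerate at cv = 0
.rlnorm_meancv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  sl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sl^2 / 2, sdlog = sl)
}

#' Simulate a synthetic cohort
#'
#' Plants one feature per configured metabolite label at its theoretical
#' `[M-H]-` m/z perturbed by Gaussian ppm jitter, with log-normal per-animal
#' intensities at the configured group means (zero in control groups), adds
#' decoy features present in every group at m/z values rejected within
#' `decoy_margin` of any library mass, draws per-sample urinary creatinine,
#' and emits template MS/MS spectra for conjugated planted candidates.
#' Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param library A `candidate_library`; all planted labels must exist in it.
#' @return A `synthetic_cohort` list: `features` (feature table), `spectra`
#'   (named list), `metadata` (sample metadata with creatinine), `truth`
#'   (per-feature ground truth with `label`, `is_decoy`).
#' @export
simulate_cohort <- function(config, library) {
  stopifnot(inherits(config, "sim_config"))
  missing_lab <- setdiff(config$planted$label, library$label)
  if (length(missing_lab))
    stop("planted label(s) not in library: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  set.seed(config$seed)
  groups <- config$groups
  sample_id <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%02d", g, seq_len(groups[[g]]))), use.names = FALSE)
  group <- rep(names(groups), unname(groups))
  metadata <- data.frame(
    sample_id = sample_id, group = group, tissue = "urine",
    creatinine = .rlnorm_meancv(length(sample_id), config$creatinine_mean,
                                config$creatinine_cv),
    stringsAsFactors = FALSE)

  n_plant <- nrow(config$planted)
  lib_idx <- match(config$planted$label, library$label)
  theo <- library$mz_mh[lib_idx]
  mz <- theo * (1 + stats::rnorm(n_plant, 0, config$mz_sigma_ppm) * 1e-6)
  rt <- round(stats::runif(n_plant, 1.5, 5.0), 2)

  intens <- matrix(0, nrow = n_plant, ncol = length(sample_id),
                   dimnames = list(NULL, sample_id))
  for (g in names(groups)) {
    ids <- sample_id[group == g]
    for (i in seq_len(n_plant)) {
      m <- if (g %in% config$exposed_groups) config$planted[[g]][i]
        else config$control_leakage *
          mean(as.numeric(config$planted[i, config$exposed_groups]))
      intens[i, ids] <- .rlnorm_meancv(length(ids), m, config$cv)
    }
  }

  # decoys: uniform m/z, rejection-sampled away from every library mass
  decoy_mz <- numeric(config$n_decoys)
  for (i in seq_len(config$n_decoys)) {
    for (try in 1:1000) {
      m <- stats::runif(1, config$decoy_mz_range[1], config$decoy_mz_range[2])
      if (min(abs(library$mz_mh - m)) >= config$decoy_margin) break
      if (try == 1000)
        stop("cannot place a decoy outside the exclusion margin",
             call. = FALSE)
    }
    decoy_mz[i] <- m
  }
  decoy_rt <- round(stats::runif(config$n_decoys, 0.5, 6.0), 2)
  decoy_int <- matrix(
    .rlnorm_meancv(config$n_decoys * length(sample_id), config$decoy_mean,
                   config$cv),
    nrow = config$n_decoys, ncol = length(sample_id),
    dimnames = list(NULL, sample_id))

  feature_id <- c(sprintf("P%03d", seq_len(n_plant)),
                  if (config$n_decoys) sprintf("D%03d",
                                               seq_len(config$n_decoys)))
  features <- cbind(
    data.frame(feature_id = feature_id,
               mz = c(mz, decoy_mz), rt = c(rt, decoy_rt),
               stringsAsFactors = FALSE),
    as.data.frame(rbind(intens, decoy_int)))
  rownames(features) <- NULL

  spectra <- list()
  for (i in seq_len(n_plant)) {
    conj <- library$conjugate[lib_idx[i]]
    if (!nzchar(conj)) next
    sp <- simulate_ms2(conj, precursor_mz = theo[i],
                       dropout = config$ms2_dropout,
                       jitter_pct = config$ms2_jitter_pct)
    if (!is.null(sp)) spectra[[feature_id[i]]] <- sp
  }

  truth <- data.frame(
    feature_id = feature_id,
    label = c(config$planted$label, rep(NA_character_, config$n_decoys)),
    is_decoy = c(rep(FALSE, n_plant), rep(TRUE, config$n_decoys)),
    stringsAsFactors = FALSE)

  structure(list(features = features, spectra = spectra,
                 metadata = metadata, truth = truth, config = config),
            class = "synthetic_cohort")
}

# template relative abundances for simulated conjugate spectra, loosely
# shaped like typical negative-mode conjugate fragmentation
.ms2_templates <- list(
  glucuronide = c(5, 40, 15, 50, 80, 100),
  sulfate = 100,
  taurine = c(10, 10, 100),
  glycine = 100
)

#' Simulate a template MS/MS spectrum for a conjugated candidate
#'
#' Builds the spectrum from the conjugate class's diagnostic fragments plus
#' the aglycone complement(s) at template abundances; each peak is
#' independently dropped with probability `dropout` and its abundance
#' jittered by a Gaussian factor. The result is renormalized to base peak
#' 100. If every fragment drops out, `NULL` is returned (no spectrum).
#'
#' @param conjugate Conjugate class name (must have a fragment rule).
#' @param precursor_mz Theoretical precursor `[M-H]-` m/z.
#' @param rules A [fragment_rules()] list.
#' @param dropout Per-fragment dropout probability in `[0, 1]`.
#' @param jitter_pct Abundance jitter SD in percent of the template value.
#' @return A data frame with `mz` and `intensity_rel` (percent of base
#'   peak), or `NULL`.
#' @export
simulate_ms2 <- function(conjugate, precursor_mz, rules = fragment_rules(),
                         dropout = 0, jitter_pct = 0) {
  rule <- rules[[conjugate]]
  if (is.null(rule))
    stop("no fragment rule for conjugate class '", conjugate, "'",
         call. = FALSE)
  tmpl <- .ms2_templates[[conjugate]]
  mz <- c(rule$diagnostics$mz, precursor_mz - rule$losses$mass)
  rel <- c(tmpl, rep(40, nrow(rule$losses)))
  keep <- mz <= precursor_mz & stats::runif(length(mz)) >= dropout
  mz <- mz[keep]; rel <- rel[keep]
  if (!length(mz)) return(NULL)
  if (jitter_pct > 0)
    rel <- pmax(rel * (1 + stats::rnorm(length(rel), 0, jitter_pct / 100)),
                0.1)
  rel <- rel / max(rel) * 100
  data.frame(mz = mz, intensity_rel = rel)
}
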