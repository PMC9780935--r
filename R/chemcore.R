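# Molecular-formula algebra, monoisotopic masses, ion m/z, ppm errors and
# coarse isotope-pattern simulation. This is the pure numeric kernel that every
# other layer builds on; nothing here does I/O.

# Fixed internal atomic data (monoisotopic masses to 8 decimals, natural
# isotope abundances). Deliberately not user-editable so that printed-value
# tests stay stable across installations.
.suspectms_elements <- list(
  C = list(mono = 12.0,
           iso = data.frame(offset = c(0L, 1L),
                            mass = c(12.0, 13.00335484),
                            abundance = c(0.9893, 0.0107))),
  H = list(mono = 1.00782503,
           iso = data.frame(offset = c(0L, 1L),
                            mass = c(1.00782503, 2.01410178),
                            abundance = c(0.999885, 0.000115))),
  N = list(mono = 14.00307401,
           iso = data.frame(offset = c(0L, 1L),
                            mass = c(14.00307401, 15.00010890),
                            abundance = c(0.99636, 0.00364))),
  O = list(mono = 15.99491462,
           iso = data.frame(offset = c(0L, 1L, 2L),
                            mass = c(15.99491462, 16.99913176, 17.99915961),
                            abundance = c(0.99757, 0.00038, 0.00205))),
  S = list(mono = 31.97207117,
           iso = data.frame(offset = c(0L, 1L, 2L, 4L),
                            mass = c(31.97207117, 32.97145890, 33.96786700,
                                     35.96708071),
                            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)))
)

#: rest mass of the electron in Da; included in all ion m/z arithmetic
.electron_mass <- 0.00054858

.proton_mass <- function() .suspectms_elements$H$mono - .electron_mass

.monoisotopic_table <- function() {
  vapply(.suspectms_elements, function(e) e$mono, numeric(1))
}

# --- formula parsing and arithmetic -----------------------------------------

# Internal: parse "C10H16"-style text into a named integer count vector.
# Accepts an empty string (used for transformation deltas); the exported
# constructor enforces the at-least-one-atom invariant.
.parse_counts <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string", call. = FALSE)
  if (text == "") return(integer(0))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    stop("malformed formula string: '", text, "'", call. = FALSE)
  m <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  elements <- sub("[0-9]*$", "", m)
  counts <- sub("^[A-Za-z]+", "", m)
  unknown <- setdiff(elements, names(.suspectms_elements))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  n <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  if (anyNA(n) || any(n <= 0L))
    stop("malformed element count in '", text, "'", call. = FALSE)
  out <- tapply(n, elements, sum)
  storage.mode(out) <- "integer"
  counts_vec <- as.integer(out)
  names(counts_vec) <- names(out)
  .order_counts(counts_vec)
}

# Hill-order the counts (C, then H, then remaining elements alphabetically)
.order_counts <- function(counts) {
  counts <- counts[counts != 0L]
  rest <- sort(setdiff(names(counts), c("C", "H")))
  ord <- intersect(c("C", "H", rest), names(counts))
  counts[ord]
}

#' Parse a molecular formula string
#'
#' Turns text such as `"C10H16"` into a `mol_formula` object, a named integer
#' vector of element counts in Hill order. Only the elements C, H, N, O and S
#' are supported; parentheses, charges and isotope labels are rejected --
#' conjugate chemistry is done through formula deltas, never by string editing.
#'
#' @param text A single formula string, e.g. `"C10H16"` (limonene) or
#'   `"C16H23O10"` (a glucuronide anion).
#' @return A `mol_formula` object.
#' @examples
#' parse_formula("C10H16")
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  mol_formula(.parse_counts(text))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector of element counts (names are element
#'   symbols among C, H, N, O, S). All counts must be non-negative and at
#'   least one must be positive.
#' @return A `mol_formula` object.
#' @export
mol_formula <- function(counts) {
  if (length(counts) == 0L || all(counts == 0L))
    stop("a molecular formula needs at least one atom", call. = FALSE)
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be named by element symbol", call. = FALSE)
  unknown <- setdiff(names(counts), names(.suspectms_elements))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(counts < 0L))
    stop("element counts must be non-negative", call. = FALSE)
  cnt <- as.integer(round(counts))
  names(cnt) <- names(counts)
  structure(.order_counts(cnt), class = "mol_formula")
}

# internal constructor that keeps the class on arithmetic results
.as_formula <- function(counts) {
  counts <- .order_counts(counts)
  structure(counts, class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "  (", round(monoisotopic_mass(x), 5),
      " Da)\n", sep = "")
  invisible(x)
}

#' Combine or subtract element counts of two formulas
#'
#' `formula_add()` merges counts; `formula_subtract()` removes them and fails
#' if any count would go negative (a chemically impossible operation).
#'
#' @param f,g `mol_formula` objects or named count vectors.
#' @return A `mol_formula`.
#' @export
formula_add <- function(f, g) {
  els <- union(names(f), names(g))
  counts <- vapply(els, function(e) {
    sum(c(unclass(f)[e], unclass(g)[e]), na.rm = TRUE)
  }, numeric(1))
  storage.mode(counts) <- "integer"
  .as_formula(counts)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  els <- union(names(f), names(g))
  counts <- vapply(els, function(e) {
    a <- unclass(f)[e]; b <- unclass(g)[e]
    sum(a, na.rm = TRUE) - sum(b, na.rm = TRUE)
  }, numeric(1))
  if (any(counts < 0))
    stop("formula subtraction would give a negative ",
         paste(els[counts < 0], collapse = ","), " count", call. = FALSE)
  if (all(counts == 0))
    stop("formula subtraction leaves no atoms", call. = FALSE)
  storage.mode(counts) <- "integer"
  .as_formula(counts)
}

# --- masses and ions --------------------------------------------------------

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times the monoisotopic atomic masses of the fixed
#' internal table (C 12 exactly, H 1.00782503, N 14.00307401, O 15.99491462,
#' S 31.97207117 Da). Additive over formula composition.
#'
#' @param f A `mol_formula` or a formula string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C10H16O3") # 184.1099
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  masses <- .monoisotopic_table()
  sum(masses[names(f)] * unclass(f))
}

#' Theoretical m/z of a singly charged ion
#'
#' Computes the deprotonated `[M-H]-` or protonated `[M+H]+` m/z of a neutral
#' formula. The electron mass is included (`[M-H]-` loses a proton but keeps
#' the extra electron), which is what reproduces printed qToF mass errors that
#' proton-only arithmetic misses by about 1.5 ppm at m/z 350.
#'
#' @param f Neutral `mol_formula` or formula string.
#' @param ion Adduct, `"[M-H]-"` (default, negative mode) or `"[M+H]+"`.
#' @return Theoretical m/z in Th.
#' @examples
#' ion_mz("C16H22O8", "[M-H]-") # 341.12419, cf. an observed 341.1243
#' @export
ion_mz <- function(f, ion = c("[M-H]-", "[M+H]+")) {
  if (is.character(f)) f <- parse_formula(f)
  ion <- match.arg(ion)
  m <- monoisotopic_mass(f)
  h <- .suspectms_elements$H$mono
  if (ion == "[M-H]-") {
    if (is.na(unclass(f)["H"]) || unclass(f)["H"] < 1L)
      stop("cannot deprotonate a formula without hydrogen", call. = FALSE)
    m - h + .electron_mass
  } else {
    m + h - .electron_mass
  }
}

#' m/z of an anion given directly by its (deprotonated or radical) formula
#'
#' Adds one electron mass to the monoisotopic mass of the stated composition;
#' used for diagnostic fragment anions such as the glucuronide marker
#' C6H7O6- (175.0248) or the sulfate radical anion SO3 (79.9574).
#'
#' @param f Anion elemental composition (`mol_formula` or string).
#' @return m/z in Th at charge 1.
#' @export
anion_mz <- function(f) {
  monoisotopic_mass(f) + .electron_mass
}

#' Signed mass error in parts per million
#'
#' Uses the convention `(theoretical - observed) / theoretical * 1e6`, i.e. an
#' observed m/z above the theoretical value gives a negative error. Internal
#' comparisons keep full precision; round only for display.
#'
#' @param theoretical Theoretical m/z (> 0). Vectorized.
#' @param observed Observed m/z. Vectorized.
#' @return Signed error in ppm.
#' @examples
#' ppm_error(ion_mz("C16H22O8"), 341.1243) # about -0.3
#' @export
ppm_error <- function(theoretical, observed) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be positive", call. = FALSE)
  (theoretical - observed) / theoretical * 1e6
}

# --- isotope patterns -------------------------------------------------------

#' Coarse theoretical isotope pattern of a formula
#'
#' Aggregates the isotopologue distribution by nominal mass offset (M+0, M+1,
#' M+2, ...) via exact convolution of the per-element isotope abundance
#' vectors, one atom at a time. Fine isotope structure is deliberately not
#' resolved; the per-offset m/z is the abundance-weighted mean isotopologue
#' mass, which is what a qToF pattern check compares against.
#'
#' @param f `mol_formula` or formula string (neutral composition).
#' @param max_offset Largest nominal offset to retain (default 3).
#' @param prune Drop peaks below this fraction of the base peak (default
#'   1e-4). Use 0 to keep everything up to `max_offset`.
#' @return An `isotope_pattern`: data frame with columns `offset`, `mz`
#'   (mean isotopologue mass) and `abundance` (fraction of base peak, base
#'   = 1). Attribute `total_probability` holds the unnormalized probability
#'   mass retained before pruning, useful for conservation checks.
#' @examples
#' isotope_pattern("C16H24O10", max_offset = 2)
#' @export
isotope_pattern <- function(f, max_offset = 3L, prune = 1e-4) {
  if (is.character(f)) f <- parse_formula(f)
  if (max_offset < 0L) stop("max_offset must be >= 0", call. = FALSE)
  if (prune < 0 || prune >= 1) stop("prune must be in [0, 1)", call. = FALSE)
  k <- max_offset + 1L
  p <- c(1, rep(0, max_offset))      # probability per offset
  s <- rep(0, k)                     # probability-weighted mass per offset
  for (el in names(f)) {
    iso <- .suspectms_elements[[el]]$iso
    for (atom in seq_len(unclass(f)[[el]])) {
      p_new <- rep(0, k); s_new <- rep(0, k)
      for (j in seq_len(nrow(iso))) {
        off <- iso$offset[j]
        if (off >= k) next
        idx <- seq_len(k - off)
        p_new[idx + off] <- p_new[idx + off] + p[idx] * iso$abundance[j]
        s_new[idx + off] <- s_new[idx + off] +
          (s[idx] + p[idx] * iso$mass[j]) * iso$abundance[j]
      }
      p <- p_new; s <- s_new
    }
  }
  total <- sum(p)
  keep <- p > 0
  offset <- which(keep) - 1L
  mz <- s[keep] / p[keep]
  abundance <- p[keep] / max(p)
  sel <- abundance >= prune | abundance == 1
  out <- data.frame(offset = offset[sel], mz = mz[sel],
                    abundance = abundance[sel])
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"),
            total_probability = total)
}

#' Agreement score between two isotope patterns
#'
#' Aligns the two patterns on the union of their nominal offsets (absent
#' offsets count as abundance 0) and returns
#' `max(0, 1 - mean(|a_obs - a_theo|))` over the aligned relative abundances.
#' Identical patterns score 1; the score is symmetric in its arguments.
#'
#' @param observed,theoretical `isotope_pattern` objects (or data frames with
#'   `offset` and `abundance` columns).
#' @return A score in `[0, 1]`.
#' @export
pattern_score <- function(observed, theoretical) {
  if (NROW(observed) == 0L || NROW(theoretical) == 0L)
    stop("patterns must be non-empty", call. = FALSE)
  offs <- sort(union(observed$offset, theoretical$offset))
  a <- observed$abundance[match(offs, observed$offset)]
  b <- theoretical$abundance[match(offs, theoretical$offset)]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  max(0, 1 - mean(abs(a - b)))
}
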