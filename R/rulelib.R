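# Biotransformation rules as formula deltas, and combinatorial enumeration of
# the candidate metabolite library. Candidates are mass-level objects only:
# positional isomers share a formula and a label and are disambiguated
# downstream by retention-time order.

#' Define a biotransformation rule
#'
#' A rule is a formula delta (`added` minus `removed`) with a phase tag, a
#' label token used in canonical metabolite labels, a per-candidate
#' multiplicity bound, and -- for phase II conjugations -- a chemical
#' prerequisite on the phase I scaffold.
#'
#' @param id Unique rule identifier.
#' @param phase `"I"` (functionalization) or `"II"` (conjugation).
#' @param token Label token, e.g. `"+COOH"` or `"glucuronide"`.
#' @param added,removed Formula strings for the atoms gained / lost
#'   (`""` for none).
#' @param max_per_candidate How many times the rule may be applied to one
#'   candidate (phase I only; conjugations are bounded at the rule-set level).
#' @param requires Prerequisite for conjugation: `"none"`,
#'   `"oxygen_handle"` (at least one oxygen-adding phase I step) or
#'   `"carboxyl_handle"` (a carboxylation step).
#' @param provides Handles this rule makes available to later conjugation;
#'   defaults to `"oxygen_handle"` for oxygen-adding phase I rules.
#' @param enabled Whether the rule participates in enumeration.
#' @return A `transformation` object.
#' @export
transformation <- function(id, phase = c("I", "II"), token = id,
                           added = "", removed = "",
                           max_per_candidate = 1L,
                           requires = c("none", "oxygen_handle",
                                        "carboxyl_handle"),
                           provides = NULL, enabled = TRUE) {
  phase <- match.arg(phase)
  requires <- match.arg(requires)
  added_c <- .parse_counts(added)
  removed_c <- .parse_counts(removed)
  if (length(added_c) == 0L && length(removed_c) == 0L)
    stop("transformation '", id, "' has an empty delta", call. = FALSE)
  if (is.null(provides)) {
    net_o <- sum(added_c["O"], na.rm = TRUE) - sum(removed_c["O"], na.rm = TRUE)
    provides <- if (phase == "I" && net_o > 0) "oxygen_handle" else character(0)
  }
  delta_mass <- sum(.monoisotopic_table()[names(added_c)] * added_c) -
    sum(.monoisotopic_table()[names(removed_c)] * removed_c)
  structure(list(id = id, phase = phase, token = token,
                 added = added_c, removed = removed_c,
                 max_per_candidate = as.integer(max_per_candidate),
                 requires = requires, provides = provides,
                 delta_mass = delta_mass, enabled = isTRUE(enabled)),
            class = "transformation")
}

#' Bundle transformations into a rule set
#'
#' @param transformations List of [transformation()] objects with unique ids.
#' @param max_phase_I_steps Global bound on the number of phase I steps per
#'   candidate (default 4, enough for carboxylation + hydroxylation + two
#'   hydrogenations).
#' @param max_phase_II_conjugates Bound on simultaneous conjugates
#'   (default 1; multiple conjugation is not enumerated unless raised).
#' @return A `rule_set` object.
#' @export
rule_set <- function(transformations, max_phase_I_steps = 4L,
                     max_phase_II_conjugates = 1L) {
  ids <- vapply(transformations, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate rule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(transformations) <- ids
  structure(list(transformations = transformations,
                 max_phase_I_steps = as.integer(max_phase_I_steps),
                 max_phase_II_conjugates = as.integer(max_phase_II_conjugates)),
            class = "rule_set")
}

#' Default biotransformation rule set for monoterpene screening
#'
#' Phase I: carboxylation (+O2 -H2, once), hydroxylation (+O, once),
#' diol formation via epoxidation/hydrolysis (+O2H2, once, labelled
#' `+OH+OH`), hydrogenation (+H2, up to `hydrogenation_max` times).
#' Phase II: glucuronidation (+C6H8O6) and sulfation (+SO3), both gated on an
#' oxygen handle; glycine (+C2H3NO) and taurine (+C2H5NO2S) conjugation,
#' gated on a carboxyl handle. The gates keep chemically absurd candidates
#' (e.g. a glucuronide of the bare hydrocarbon parent) out of the library.
#' A dehydrogenation rule (-H2) is available but disabled by default; no
#' reference metabolite requires it.
#'
#' @param hydrogenation_max Per-candidate bound on hydrogenation (default 2).
#' @param include_dehydrogenation Enable the optional -H2 rule.
#' @param max_phase_I_steps,max_phase_II_conjugates Passed to [rule_set()].
#' @return A `rule_set`.
#' @export
default_rules <- function(hydrogenation_max = 2L,
                          include_dehydrogenation = FALSE,
                          max_phase_I_steps = 4L,
                          max_phase_II_conjugates = 1L) {
  tr <- list(
    transformation("carboxylation", "I", "+COOH", added = "O2", removed = "H2",
                   provides = c("oxygen_handle", "carboxyl_handle")),
    transformation("hydroxylation", "I", "+OH", added = "O"),
    transformation("diol", "I", "+OH+OH", added = "O2H2"),
    transformation("hydrogenation", "I", "+H2", added = "H2",
                   max_per_candidate = hydrogenation_max),
    transformation("dehydrogenation", "I", "-H2", removed = "H2",
                   enabled = include_dehydrogenation),
    transformation("glucuronidation", "II", "glucuronide", added = "C6H8O6",
                   requires = "oxygen_handle"),
    transformation("sulfation", "II", "sulfate", added = "SO3",
                   requires = "oxygen_handle"),
    transformation("glycine_conjugation", "II", "glycine", added = "C2H3NO",
                   requires = "carboxyl_handle"),
    transformation("taurine_conjugation", "II", "taurine", added = "C2H5NO2S",
                   requires = "carboxyl_handle")
  )
  tr <- tr[vapply(tr, `[[`, logical(1), "enabled")]
  rule_set(tr, max_phase_I_steps = max_phase_I_steps,
           max_phase_II_conjugates = max_phase_II_conjugates)
}

#' Apply one biotransformation to a formula
#'
#' Adds `t$added` and removes `t$removed` from the element counts. Errors if
#' any count would go negative or if the product loses its carbon skeleton
#' (transformations are defined for organic scaffolds only).
#'
#' @param f `mol_formula` or formula string.
#' @param t A [transformation()].
#' @return The transformed `mol_formula`.
#' @examples
#' rules <- default_rules()
#' apply_transformation("C10H16", rules$transformations$carboxylation)
#' @export
apply_transformation <- function(f, t) {
  if (is.character(f)) f <- parse_formula(f)
  counts <- unclass(f)
  for (el in names(t$added))
    counts[el] <- sum(counts[el], na.rm = TRUE) + t$added[[el]]
  for (el in names(t$removed)) {
    counts[el] <- sum(counts[el], na.rm = TRUE) - t$removed[[el]]
    if (is.na(counts[el]) || counts[el] < 0L)
      stop("transformation '", t$id, "' cannot remove ", el,
           " from ", format(f), call. = FALSE)
  }
  if (sum(counts["C"], na.rm = TRUE) < 1L)
    stop("transformation '", t$id, "' leaves no carbon skeleton",
         call. = FALSE)
  .as_formula(counts[counts > 0L])
}

# canonical ordering of phase I tokens in labels
.phase1_token_order <- c("+COOH", "+OH", "+OH+OH", "+H2", "-H2")

#' Canonical label of a candidate metabolite
#'
#' Parent id, then phase I tokens in a fixed order (`+COOH`, `+OH`, `+OH+OH`,
#' `+H2` repeated per application), then the conjugate token separated by a
#' space. Deterministic for a given transformation multiset, so reports are
#' diff-stable. Positional-isomer suffixes (I/II/III) are not part of the
#' canonical label; they are assigned downstream from retention-time order.
#'
#' @param parent_id Parent compound name, e.g. `"limonene"`.
#' @param phase1_tokens Character vector of phase I tokens, one entry per
#'   application (repeats allowed).
#' @param conjugate Conjugate token or `""`.
#' @return A single label string.
#' @examples
#' canonical_label("limonene", c("+OH", "+COOH", "+H2"), "glucuronide")
#' @export
canonical_label <- function(parent_id, phase1_tokens = character(0),
                            conjugate = "") {
  ord <- order(match(phase1_tokens, .phase1_token_order,
                     nomatch = length(.phase1_token_order) + 1L),
               phase1_tokens)
  lab <- paste0(parent_id, paste0(phase1_tokens[ord], collapse = ""))
  if (nzchar(conjugate)) lab <- paste(lab, conjugate)
  lab
}

#' Enumerate the candidate metabolite library
#'
#' Forms every multiset of enabled phase I transformations within the
#' per-rule and global bounds, then optionally extends each by conjugates
#' whose chemical prerequisite is met (an oxygen-adding phase I step for
#' glucuronide/sulfate, a carboxylation for glycine/taurine). Candidates are
#' deduplicated on (neutral formula, label) and returned label-sorted.
#'
#' @param parent Neutral parent formula (`mol_formula` or string).
#' @param rules A [rule_set()].
#' @param parent_id Name used in labels (default `"limonene"`).
#' @return A `candidate_library` data frame with columns `label`, `formula`,
#'   `mz_mh` (theoretical `[M-H]-`), `mz_ph` (theoretical `[M+H]+`),
#'   `phase1_tokens`, `conjugate`, `n_phase1` and `n_steps` (phase I steps
#'   plus conjugates; the tie-breaking complexity measure).
#' @examples
#' lib <- enumerate_candidates("C10H16", default_rules())
#' nrow(lib)
#' @export
enumerate_candidates <- function(parent, rules, parent_id = "limonene") {
  if (is.character(parent)) parent <- parse_formula(parent)
  stopifnot(inherits(rules, "rule_set"))
  tr <- rules$transformations
  p1 <- tr[vapply(tr, function(t) t$phase == "I" && t$enabled, logical(1))]
  p2 <- tr[vapply(tr, function(t) t$phase == "II" && t$enabled, logical(1))]

  grids <- lapply(p1, function(t) 0:t$max_per_candidate)
  combos <- if (length(grids)) expand.grid(grids) else
    data.frame(row.names = 1)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    counts <- if (ncol(combos)) as.integer(combos[i, ]) else integer(0)
    if (sum(counts) > rules$max_phase_I_steps) next
    f <- parent
    ok <- TRUE
    tokens <- character(0)
    handles <- character(0)
    for (j in seq_along(p1)) {
      if (counts[j] == 0L) next
      for (k in seq_len(counts[j])) {
        f <- tryCatch(apply_transformation(f, p1[[j]]), error = function(e) NULL)
        if (is.null(f)) { ok <- FALSE; break }
      }
      if (!ok) break
      tokens <- c(tokens, rep(p1[[j]]$token, counts[j]))
      handles <- union(handles, p1[[j]]$provides)
    }
    if (!ok) next
    base <- list(formula = f, tokens = tokens, conj = character(0))
    rows[[length(rows) + 1L]] <- base
    if (rules$max_phase_II_conjugates >= 1L) {
      eligible <- p2[vapply(p2, function(t)
        t$requires == "none" || t$requires %in% handles, logical(1))]
      conj_sets <- .conjugate_multisets(names(eligible),
                                        rules$max_phase_II_conjugates)
      for (cs in conj_sets) {
        fc <- f
        for (cid in cs) fc <- apply_transformation(fc, p2[[cid]])
        rows[[length(rows) + 1L]] <-
          list(formula = fc, tokens = tokens,
               conj = vapply(cs, function(cid) p2[[cid]]$token, character(1)))
      }
    }
  }
  lab <- vapply(rows, function(r)
    canonical_label(parent_id, r$tokens, paste(r$conj, collapse = " ")),
    character(1))
  out <- data.frame(
    label = lab,
    formula = vapply(rows, function(r) format(r$formula), character(1)),
    mz_mh = vapply(rows, function(r) ion_mz(r$formula, "[M-H]-"), numeric(1)),
    mz_ph = vapply(rows, function(r) ion_mz(r$formula, "[M+H]+"), numeric(1)),
    phase1_tokens = vapply(rows, function(r)
      paste(r$tokens, collapse = " "), character(1)),
    conjugate = vapply(rows, function(r)
      paste(r$conj, collapse = " "), character(1)),
    n_phase1 = vapply(rows, function(r) length(r$tokens), integer(1)),
    n_steps = vapply(rows, function(r)
      length(r$tokens) + length(r$conj), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("formula", "label")]), , drop = FALSE]
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_library", "data.frame")
  out
}

# non-empty multisets (with repetition) of conjugate ids up to size max_n
.conjugate_multisets <- function(ids, max_n) {
  if (length(ids) == 0L || max_n < 1L) return(list())
  out <- lapply(ids, function(i) i)
  if (max_n >= 2L) {
    prev <- out
    for (n in 2:max_n) {
      nxt <- list()
      for (s in prev) {
        last <- match(s[length(s)], ids)
        for (j in last:length(ids)) nxt[[length(nxt) + 1L]] <- c(s, ids[j])
      }
      out <- c(out, nxt)
      prev <- nxt
    }
  }
  out
}
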