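test_that("single transformations apply as formula deltas with guards", {
  rules <- default_rules()$transformations
  expect_equal(format(apply_transformation("C10H16", rules$carboxylation)),
               "C10H14O2")
  expect_equal(format(apply_transformation("C10H14O2", rules$hydrogenation)),
               "C10H16O2")
  expect_equal(format(apply_transformation("C10H14O2", rules$sulfation)),
               "C10H14O5S")
  expect_error(apply_transformation("H2", rules$carboxylation), "carbon")
  expect_error(apply_transformation("C10H1", rules$carboxylation), "remove")
})

test_that("net formula delta is independent of application order", {
  rules <- default_rules()$transformations
  seqs <- list(c("carboxylation", "hydroxylation", "hydrogenation"),
               c("hydrogenation", "carboxylation", "hydroxylation"),
               c("hydroxylation", "hydrogenation", "carboxylation"))
  out <- lapply(seqs, function(s) {
    f <- parse_formula("C10H16")
    for (id in s) f <- apply_transformation(f, rules[[id]])
    format(f)
  })
  expect_length(unique(unlist(out)), 1L)
  expect_equal(out[[1]], "C10H16O3")
})

test_that("canonical labels order tokens deterministically", {
  expect_equal(
    canonical_label("limonene", c("+OH", "+H2", "+COOH"), "glucuronide"),
    "limonene+COOH+OH+H2 glucuronide")
  expect_equal(canonical_label("limonene"), "limonene")
  expect_equal(canonical_label("limonene", "+COOH", "taurine"),
               "limonene+COOH taurine")
  expect_equal(canonical_label("limonene", c("+COOH", "+OH+OH"),
                               "glucuronide"),
               "limonene+COOH+OH+OH glucuronide")
})

test_that("enumeration covers the reference metabolite formulas", {
  lib <- enumerate_candidates("C10H16", default_rules())
  fixture <- load_fixture("limonene_metabolites")
  neutral <- vapply(fixture$anion_formula, function(a)
    format(formula_add(parse_formula(a), parse_formula("H"))), character(1))
  expect_true(all(neutral %in% lib$formula))
  # and the reference labels themselves are all enumerated
  expect_true(all(fixture$label %in% lib$label))
  # deterministic label-sorted order
  expect_equal(lib$label, sort(lib$label))
  expect_false(anyDuplicated(lib[, c("formula", "label")]) > 0)
})

test_that("library size equals the brute-force multiset count", {
  lib <- enumerate_candidates("C10H16", default_rules())
  expect_equal(nrow(lib), oracle_default_library_size())

  # degenerate rule sets
  empty <- rule_set(list())
  expect_equal(enumerate_candidates("C10H16", empty)$label, "limonene")

  small <- rule_set(list(
    transformation("hydroxylation", "I", "+OH", added = "O"),
    transformation("glucuronidation", "II", "glucuronide", added = "C6H8O6",
                   requires = "oxygen_handle")))
  lib_small <- enumerate_candidates("C10H16", small)
  expect_setequal(lib_small$label,
                  c("limonene", "limonene+OH", "limonene+OH glucuronide"))
})

test_that("candidate ion masses differ from the parent by the summed deltas", {
  rules <- default_rules()
  lib <- enumerate_candidates("C10H16", rules)
  parent_mz <- ion_mz("C10H16", "[M-H]-")
  token_mass <- c("+COOH" = rules$transformations$carboxylation$delta_mass,
                  "+OH" = rules$transformations$hydroxylation$delta_mass,
                  "+OH+OH" = rules$transformations$diol$delta_mass,
                  "+H2" = rules$transformations$hydrogenation$delta_mass,
                  "glucuronide" = rules$transformations$glucuronidation$delta_mass,
                  "sulfate" = rules$transformations$sulfation$delta_mass,
                  "glycine" = rules$transformations$glycine_conjugation$delta_mass,
                  "taurine" = rules$transformations$taurine_conjugation$delta_mass)
  for (i in seq_len(nrow(lib))) {
    tokens <- c(strsplit(lib$phase1_tokens[i], " ")[[1]],
                strsplit(lib$conjugate[i], " ")[[1]])
    tokens <- tokens[nzchar(tokens)]
    expect_equal(lib$mz_mh[i], parent_mz + sum(token_mass[tokens]),
                 tolerance = 1e-9, label = lib$label[i])
  }
})

test_that("conjugation is gated on the chemical handles", {
  lib <- enumerate_candidates("C10H16", default_rules())
  # no conjugate of the bare hydrocarbon parent
  expect_false(any(lib$n_phase1 == 0 & nzchar(lib$conjugate)))
  # amino acid conjugates only on carboxylated scaffolds
  aa <- lib[lib$conjugate %in% c("glycine", "taurine"), ]
  expect_true(all(grepl("\\+COOH", aa$label)))
})
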