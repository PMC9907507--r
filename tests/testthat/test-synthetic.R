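test_that("zero substitution rate clones the ancestor", {
  fam <- generate_family(family_spec(n_species = 5, p_sub = 0, seed = 1,
                                     short_isoform_prob = 0))
  expect_true(all(fam$records$residues == fam$ancestors$CtBP))
  expect_equal(global_align(fam$records$residues[1],
                            fam$records$residues[2])$identity_pct, 100)
})

test_that("the same spec and seed reproduce the family exactly", {
  spec <- family_spec(n_species = 6, seed = 99, short_isoform_prob = 0.5,
                      indel_prob = 0.02)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$true_alignment, f2$true_alignment)
  expect_identical(f1$true_labels, f2$true_labels)

  f3 <- generate_family(family_spec(n_species = 6, seed = 100,
                                    short_isoform_prob = 0.5))
  expect_false(identical(f1$records$residues, f3$records$residues))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(generate_family(family_spec(n_species = 3, seed = 123)))
  expect_identical(.Random.seed, before)
})

test_that("per-site identity at unprotected sites matches the closed form", {
  # two independent descents at rate p: a site matches if neither lineage
  # substituted, or both substituted to the same of the 19 alternatives
  p <- 0.1
  expected <- (1 - p)^2 + p^2 / 19
  matches <- 0L; n_sites <- 0L
  for (s in 1:25) {
    fam <- generate_family(family_spec(n_species = 2, p_sub = p,
                                       seed = 9000 + s,
                                       short_isoform_prob = 0))
    free <- unprotected_positions(fam)
    a <- strsplit(fam$records$residues[1], "")[[1]][free]
    b <- strsplit(fam$records$residues[2], "")[[1]][free]
    matches <- matches + sum(a == b)
    n_sites <- n_sites + length(free)
  }
  expect_gte(n_sites, 10000)
  se <- sqrt(expected * (1 - expected) / n_sites)
  expect_lt(abs(matches / n_sites - expected), 5 * se + 0.005)
})

test_that("expected spacer composition has its closed form", {
  uniform <- family_spec(spacer_weights = setNames(
    rep(1, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_equal(expected_spacer_composition(uniform)$frac_pga, 3 / 20)

  all_p <- family_spec(spacer_weights = c(
    P = 1, setNames(rep(0, 19), setdiff(strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]], "P"))))
  expect_equal(expected_spacer_composition(all_p)$frac_pga, 1)

  defaults <- expected_spacer_composition(family_spec())
  expect_equal(defaults$frac_pga, 0.45)
  expect_equal(defaults$fcr, 0.14)

  bad <- family_spec()
  bad$spacer_weights[] <- 0
  expect_error(expected_spacer_composition(bad), "zero total")
})

test_that("realized spacer composition recovers the generator weights", {
  # one ancestral spacer draw per family, so replicate over families
  pga <- unlist(lapply(1:60, function(s) {
    fam <- generate_family(family_spec(n_species = 1, seed = 4000 + s))
    composition_profile(spacer_residues(fam))$frac_pga
  }))
  expect_length(pga, 60)
  expect_lt(abs(mean(pga) -
                  expected_spacer_composition(family_spec())$frac_pga),
            0.03)
})

test_that("spec violations are rejected before any sampling", {
  expect_error(family_spec(p_sub = 1.5), "p_sub")
  expect_error(family_spec(core_template = "AAAANCVN"), "RPLVALL")
  expect_error(family_spec(core_template = paste0(
    "RPLVALLAAAANCVNAAAANCVN")), "NCVN")
  expect_error(family_spec(spacer_lengths = c(10, 10)), "spacer")
  w <- default_spacer_weights(); w["P"] <- -1
  expect_error(family_spec(spacer_weights = w), "non-negative")
})

test_that("true labels are recovered by the downstream classifiers", {
  fam <- generate_family(family_spec(
    n_species = 20, seed = 77, p_sub = 0.05, block_protection = 0,
    short_isoform_prob = 0.5,
    paralog_families = default_paralog_families()))

  # isoform typing reproduces the generator's long/short truth
  segs <- segment_records(fam$records)
  iso <- vapply(seq_len(nrow(fam$records)), function(k) {
    classify_isoform(segment_domains(fam$records$residues[k]),
                     fam$records$residues[k])$form
  }, character(1))
  expect_identical(iso, fam$true_labels$form)

  # short endings are read back verbatim
  short <- fam$true_labels$form == "short"
  endings <- vapply(which(short), function(k)
    classify_isoform(segment_domains(fam$records$residues[k]),
                     fam$records$residues[k])$ending_label, character(1))
  expect_identical(endings, fam$true_labels$ending[short])

  # paralog families called with 100% accuracy on concordant signals
  long <- !short
  calls <- classify_paralogs(fam$records[long, ],
                             fam$ancestors$CtBP1_like,
                             fam$ancestors$CtBP2_like)
  expect_identical(calls$family, fam$true_labels$family[long])
})

test_that("deletions stay inside spacers and truths remain consistent", {
  fam <- generate_family(family_spec(n_species = 8, seed = 55,
                                     indel_prob = 0.1,
                                     short_isoform_prob = 0))
  # alignment rows reproduce the records once gaps are removed
  expect_identical(gsub("-", "", fam$true_alignment$seqs, fixed = TRUE),
                   fam$records$residues)
  # true boundaries still tile each record
  b <- fam$true_boundaries
  expect_true(all(b$ctd_end == b$length))
  expect_true(all(nchar(fam$records$residues) == b$length))
  # core length (RPLVALL..NCVN window) is untouched by spacer-only deletions
  core_window <- nchar(fam$spec$core_template) -
    (regexpr("RPLVALL", fam$spec$core_template, fixed = TRUE)[1] - 1L)
  expect_true(all(b$core_end - b$core_start + 1L == core_window))
})
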