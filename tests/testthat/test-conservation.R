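# build a small MSA from explicit column vectors
msa_from_columns <- function(cols) {
  rows <- apply(do.call(cbind, cols), 1, paste, collapse = "")
  read_msa(write_temp_msa(sprintf("r%02d", seq_along(rows)), rows))
}

test_that("column classes follow the majority and chemical-group rules", {
  msa <- msa_from_columns(list(
    c("A", "A", "A", "G"),      # conserved A (75%)
    c("S", "S", "T", "T"),      # chemical hydroxyl (pooled 100%)
    c("A", "C", "G", "P")))     # nothing above 50%
  ann <- annotate_columns(msa)
  expect_equal(ann$primary_class, c("conserved", "chemical", "none"))
  expect_equal(ann$primary_residue[1:2], c("A", "hydroxyl"))

  # secondary residue in the closed [25%, 50%] band
  msa8 <- msa_from_columns(list(c("A", "A", "A", "A", "A", "G", "G", "C")))
  ann8 <- annotate_columns(msa8)
  expect_equal(ann8$primary_class, "conserved")
  expect_equal(ann8$primary_residue, "A")
  expect_equal(ann8$secondary_residue, "G")

  # under 50% occupancy -> none, regardless of residue agreement
  gappy <- msa_from_columns(list(c("A", "-", "-", "-"),
                                 c("C", "C", "C", "C")))
  expect_equal(annotate_columns(gappy)$primary_class[1], "none")
})

test_that("annotation is invariant to row order", {
  set.seed(404)
  rows <- vapply(1:6, function(i) random_protein(40), character(1))
  ids <- sprintf("r%d", 1:6)
  a1 <- annotate_columns(read_msa(write_temp_msa(ids, rows)))
  perm <- c(4, 2, 6, 1, 5, 3)
  a2 <- annotate_columns(read_msa(write_temp_msa(ids[perm], rows[perm])))
  expect_identical(a1, a2)
})

test_that("conserved blocks merge across short breaks and honour min_len", {
  classes <- c(rep("none", 3), rep("conserved", 10), rep("none", 4),
               rep("conserved", 3), "none", rep("conserved", 2),
               rep("none", 3))
  ann <- data.frame(column = seq_along(classes), primary_class = classes,
                    primary_residue = "A", secondary_residue = NA,
                    majority_residue = "A", occupancy = 1,
                    stringsAsFactors = FALSE)
  blocks <- find_conserved_blocks(ann, min_len = 5, max_break = 1)
  # 10-run stands alone; the 3+1+2 pattern merges into one 6-column block
  expect_equal(blocks$start, c(4L, 18L))
  expect_equal(blocks$end, c(13L, 23L))
  expect_equal(blocks$length, c(10L, 6L))

  none <- find_conserved_blocks(ann, min_len = 20)
  expect_equal(nrow(none), 0)
})

test_that("a protected central block survives moderate substitution", {
  fam <- generate_family(family_spec(n_species = 10, p_sub = 0.05,
                                     seed = 21, short_isoform_prob = 0))
  ann <- annotate_columns(fam$true_alignment)
  blocks <- find_conserved_blocks(ann, min_len = 5, max_break = 1)
  central <- fam$layout[fam$layout$segment == "block2", ]  # PELNGAIYRY
  covered <- sum(ann$primary_class[central$start:central$end] %in%
                   c("conserved", "chemical"))
  expect_gte(covered, 8)  # at least 8 of its 10 columns conserved
  # and some block overlaps it
  expect_true(any(blocks$start <= central$start + 2 &
                    blocks$end >= central$end - 2))
})

test_that("raising the substitution rate does not gain conserved columns", {
  mean_conserved <- function(p) {
    counts <- vapply(1:10, function(s) {
      fam <- generate_family(family_spec(n_species = 6, p_sub = p,
                                         seed = 500 + s,
                                         short_isoform_prob = 0))
      sum(annotate_columns(fam$true_alignment)$primary_class == "conserved")
    }, numeric(1))
    mean(counts)
  }
  rates <- c(0, 0.05, 0.15, 0.30)
  means <- vapply(rates, mean_conserved, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("gappy columns are dropped by threshold", {
  msa <- msa_from_columns(list(c("-", "-", "-", "-"),
                               c("A", "A", "-", "-"),
                               c("A", "A", "A", "A")))
  trimmed <- drop_gappy_columns(msa, max_gap_fraction = 0.8)
  expect_equal(trimmed$n_columns, 2L)
  expect_equal(trimmed$seqs[1], "AA")

  # no column above threshold: identity transform
  full <- msa_from_columns(list(c("A", "A"), c("C", "C")))
  expect_identical(drop_gappy_columns(full), full)

  half_gap <- msa_from_columns(list(c("A", "-"), c("-", "A")))
  expect_error(drop_gappy_columns(half_gap, 0.4), "all columns")
})
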