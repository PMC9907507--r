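# two-paralog family with intact (fully protected) signal motifs
make_paralog_family <- function(n_species, seed, p_sub = 0.05) {
  generate_family(family_spec(
    n_species = n_species, seed = seed, p_sub = p_sub,
    block_protection = 0, short_isoform_prob = 0,
    paralog_families = default_paralog_families()))
}

test_that("concordant identity and motif signals give the family call", {
  fam <- make_paralog_family(6, seed = 31)
  ref1 <- fam$ancestors$CtBP1_like
  ref2 <- fam$ancestors$CtBP2_like
  q1 <- fam$records[fam$records$id == "sp001_CtBP1_like_L", ]
  call1 <- classify_paralog(q1, ref1, ref2)
  expect_equal(call1$family, "CtBP1_like")
  expect_gte(call1$identity_to_ref1, call1$identity_to_ref2)
  expect_equal(call1$ctd_start_motif, "KEYL")

  q2 <- fam$records[fam$records$id == "sp001_CtBP2_like_L", ]
  call2 <- classify_paralog(q2, ref1, ref2)
  expect_equal(call2$family, "CtBP2_like")
  expect_equal(call2$ctd_end_motif, "LTEQ")
})

test_that("conflicting identity and motif signals are left unresolved", {
  fam <- make_paralog_family(4, seed = 32)
  ref1 <- fam$ancestors$CtBP1_like
  ref2 <- fam$ancestors$CtBP2_like
  idx <- which(fam$records$id == "sp002_CtBP1_like_L")
  q <- fam$records[idx, ]
  b <- fam$true_boundaries[fam$true_boundaries$id == q$id, ]
  # graft the CtBP2-family CTD motifs onto a CtBP1-family core
  s <- q$residues
  substr(s, b$ctd_start, b$ctd_start + 3L) <- "KEFF"
  substr(s, b$ctd_end - 3L, b$ctd_end) <- "LTEQ"
  q$residues <- s
  call <- classify_paralog(q, ref1, ref2)
  expect_equal(call$family, "unresolved")
  expect_true(any(grepl("conflict", call$evidence)))
  expect_true(any(grepl("identity", call$evidence)))
  expect_true(any(grepl("motif", call$evidence)))
})

test_that("paralog calls are deterministic and row-order independent", {
  fam <- make_paralog_family(4, seed = 33)
  ref1 <- fam$ancestors$CtBP1_like
  ref2 <- fam$ancestors$CtBP2_like
  calls1 <- classify_paralogs(fam$records, ref1, ref2)
  calls2 <- classify_paralogs(fam$records, ref1, ref2)
  expect_identical(calls1, calls2)
  perm <- rev(seq_len(nrow(fam$records)))
  calls3 <- classify_paralogs(fam$records[perm, ], ref1, ref2)
  reord <- calls3[match(calls1$query_id, calls3$query_id), ]
  rownames(reord) <- NULL
  expect_identical(calls1$family, reord$family)
})

test_that("within a species the lower-identity CtBP1-family paralog becomes CtBP1a", {
  fam <- make_paralog_family(3, seed = 34)
  ref1 <- fam$ancestors$CtBP1_like
  ref2 <- fam$ancestors$CtBP2_like
  # duplicate each CtBP1-family record with extra core noise
  recs <- fam$records
  dup <- recs[grepl("CtBP1_like", recs$id), ]
  dup$id <- sub("_L$", "b_L", dup$id)
  set.seed(1)
  dup$residues <- vapply(dup$residues, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(40:300, 12)  # inside the core, away from anchors
    for (i in idx) ch[i] <- sample(setdiff(LETTERS[LETTERS %in% ch], ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1))
  all <- rbind(recs, dup)
  calls <- classify_paralogs(all, ref1, ref2)
  for (sp in unique(all$species)) {
    fams <- calls$family[calls$species == sp]
    expect_equal(sum(fams == "CtBP1_like"), 1)
    expect_equal(sum(fams == "CtBP1a"), 1)
  }
})

test_that("SUMO consensus scan reports all overlapping psi-K-x-acidic sites", {
  one <- scan_sumo_sites("AVKSE")
  expect_equal(one$k_position, 3L)
  expect_equal(one$context, "VKSE")

  expect_equal(nrow(scan_sumo_sites("AVKSG")), 0)  # alpha not acidic

  two <- scan_sumo_sites("VKVEVKLD")
  expect_equal(two$k_position, c(2L, 6L))
})

test_that("SUMO scan equals the sliding-window oracle on random strings", {
  set.seed(505)
  for (k in 1:200) {
    s <- random_protein(sample(4:60, 1))
    expect_equal(scan_sumo_sites(s)$k_position,
                 oracle_sumo_positions(s), info = s)
  }
})

test_that("reference-site audits report conservation through the alignment", {
  set.seed(88)
  ch <- strsplit(random_protein(100), "")[[1]]  # non-repetitive reference
  ch[c(2, 3, 100)] <- c("S", "K", "R")
  ref <- paste(ch, collapse = "")
  sites <- data.frame(name = c("S2", "K3", "R100"),
                      position = c(2L, 3L, 100L),
                      expected = c("S", "K", "R"),
                      stringsAsFactors = FALSE)
  self <- audit_reference_sites(ref, ref, sites)
  expect_true(all(self$conserved))

  mutated <- ref
  substr(mutated, 2, 2) <- "A"
  aud <- audit_reference_sites(mutated, ref, sites)
  expect_false(aud$conserved[aud$name == "S2"])
  expect_true(aud$conserved[aud$name == "K3"])

  truncated <- substr(ref, 1, 60)
  aud2 <- audit_reference_sites(truncated, ref, sites)
  expect_equal(aud2$query_residue[aud2$name == "R100"], "-")
  expect_false(aud2$conserved[aud2$name == "R100"])

  bad <- data.frame(name = "S999", position = 999L, expected = "S")
  expect_error(audit_reference_sites(ref, ref, bad), "out of reference range")
})

test_that("terminal endings are cataloged with longest-motif tie-break", {
  recs <- data.frame(
    id = c("a", "b", "c"),
    species = c("spA", "spA", "spB"),
    residues = c(paste0(strrep("Q", 30), "APECARP"),
                 paste0(strrep("Q", 30), "PEPSEVH"),
                 paste0(strrep("Q", 30), "WWWWWWW")),
    stringsAsFactors = FALSE)
  out <- catalog_endings(recs)
  expect_equal(out$calls$label, c("APECARP", "PEPSEVH", "novel"))
  expect_equal(out$calls$terminal_kmer[3], "WWWWWWW")
  expect_true(out$presence["spA", "APECARP"])
  expect_false(out$presence["spB", "APECARP"])
})
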