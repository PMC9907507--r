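#' Default CTD start/end motifs of the vertebrate paralog families
#'
#' CtBP1-like/1a CTDs typically start and end with KEYL...PADQ, and
#' CtBP2-like CTDs with KEFF...LTEQ. Matching allows Hamming distance 1
#' over each 4-mer because the motifs are typical rather than absolute.
#'
#' @return A data.frame with columns `family_root` (`"CtBP1"`,
#'   `"CtBP2"`), `start_motif` and `end_motif`.
#' @export
paralog_motif_table <- function() {
  data.frame(family_root = c("CtBP1", "CtBP2"),
             start_motif = c("KEYL", "KEFF"),
             end_motif = c("PADQ", "LTEQ"),
             stringsAsFactors = FALSE)
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(.chars(a) != .chars(b))
}

#' Classify one vertebrate CtBP paralog
#'
#' Rule-based paralog calling: the query's anchored core window
#' (RPLVALL...NCVN) is compared by [window_identity()] against the two
#' reference proteins (designated CtBP1 and CtBP2), giving a provisional
#' family by nearest reference. The call is then refined with CTD
#' motifs: a CTD starting KEYL-like and ending PADQ-like supports the
#' CtBP1 family, KEFF-like...LTEQ-like the CtBP2 family (Hamming
#' distance <= 1 per 4-mer; a family must win both distances summed
#' strictly, otherwise the motif signal is ambiguous). Concordant
#' identity and motif signals yield `CtBP1_like` / `CtBP2_like`;
#' conflicting signals yield `unresolved` with both rule firings
#' recorded; absent motif signal falls back to the identity call
#' (`CtBP1` / `CtBP2`). When `species_context` holds co-occurring
#' 1-family calls from the same species, a query outranked in
#' core identity by another CtBP1-family paralog is demoted to
#' `CtBP1a` (within-species identity ranking is the implementable
#' reading of the 1-like vs 1a distinction and is flagged in the
#' evidence).
#'
#' @param query,ref1,ref2 Residue strings or records; `ref1`/`ref2` are
#'   the designated CtBP1/CtBP2 references.
#' @param species_context Optional data.frame of prior calls from the
#'   same species, with columns `family` and `identity_to_ref1`.
#' @param motifs Motif table, see [paralog_motif_table()].
#' @param motif_max_mismatch Hamming tolerance per motif.
#' @return A `paralog_call`: list with `query_id`, `family`,
#'   `identity_to_ref1`, `identity_to_ref2`, `ctd_start_motif`,
#'   `ctd_end_motif` (matched catalog motifs or `NA`) and `evidence`
#'   (character vector of rule firings).
#' @export
classify_paralog <- function(query, ref1, ref2, species_context = NULL,
                             motifs = paralog_motif_table(),
                             motif_max_mismatch = 1L) {
  qid <- .record_id(query)
  id1 <- window_identity(query, ref1)$identity_pct
  id2 <- window_identity(query, ref2)$identity_pct
  seg <- segment_domains(query)
  ctd <- domain_sequences(seg, query)$ctd

  evidence <- character(0)
  identity_family <- if (id1 >= id2) "CtBP1" else "CtBP2"
  evidence <- c(evidence, sprintf(
    "identity: core %.1f%% to ref1 vs %.1f%% to ref2 -> %s family",
    id1, id2, identity_family))

  ctd_start_motif <- NA_character_
  ctd_end_motif <- NA_character_
  motif_family <- NA_character_
  min_need <- max(nchar(motifs$start_motif)) + max(nchar(motifs$end_motif))
  if (nchar(ctd) >= min_need) {
    d_start <- vapply(motifs$start_motif, function(m)
      .hamming(substr(ctd, 1L, nchar(m)), m), numeric(1))
    d_end <- vapply(motifs$end_motif, function(m)
      .hamming(substr(ctd, nchar(ctd) - nchar(m) + 1L, nchar(ctd)), m),
      numeric(1))
    total <- ifelse(d_start <= motif_max_mismatch, d_start, Inf) +
             ifelse(d_end <= motif_max_mismatch, d_end, Inf)
    if (any(is.finite(total))) {
      best <- which(total == min(total))
      if (length(best) == 1L) {
        motif_family <- motifs$family_root[best]
        ctd_start_motif <- motifs$start_motif[best]
        ctd_end_motif <- motifs$end_motif[best]
        evidence <- c(evidence, sprintf(
          "motif: CTD %s...%s -> %s family",
          ctd_start_motif, ctd_end_motif, motif_family))
      } else {
        evidence <- c(evidence, "motif: ambiguous between families")
      }
    }
  }

  if (is.na(motif_family)) {
    family <- identity_family
    evidence <- c(evidence, "call: identity only (no CTD motif signal)")
  } else if (motif_family == identity_family) {
    family <- paste0(identity_family, "_like")
  } else {
    family <- "unresolved"
    evidence <- c(evidence, "call: identity and motif signals conflict")
  }

  if (family == "CtBP1_like" && !is.null(species_context) &&
      nrow(species_context) > 0L) {
    better <- species_context$family %in% "CtBP1_like" &
      species_context$identity_to_ref1 > id1
    if (any(better)) {
      family <- "CtBP1a"
      evidence <- c(evidence,
        "rank: outranked within species by a higher-identity CtBP1-family paralog")
    }
  }

  structure(list(query_id = qid, family = family,
                 identity_to_ref1 = id1, identity_to_ref2 = id2,
                 ctd_start_motif = ctd_start_motif,
                 ctd_end_motif = ctd_end_motif,
                 evidence = evidence),
            class = "paralog_call")
}

#' @export
print.paralog_call <- function(x, ...) {
  cat("Paralog call for '", x$query_id, "': ", x$family, "\n",
      "  identity to ref1/ref2: ",
      sprintf("%.1f%% / %.1f%%", x$identity_to_ref1, x$identity_to_ref2),
      "\n", sep = "")
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Classify every record of a sequence table against two references
#'
#' Applies [classify_paralog()] per record, ranking CtBP1-family calls
#' within each species (highest core identity keeps `CtBP1_like`,
#' subsequent ones become `CtBP1a`). Records are processed in order of
#' decreasing identity within a species, so the result is independent
#' of input row order.
#'
#' @param records Sequence table with `id`, `species`, `residues`.
#' @param ref1,ref2 Reference records or residue strings.
#' @param ... Passed to [classify_paralog()].
#' @return A data.frame of calls, one row per record, in input order,
#'   with `evidence` semicolon-joined.
#' @export
classify_paralogs <- function(records, ref1, ref2, ...) {
  calls <- lapply(seq_len(nrow(records)), function(k)
    classify_paralog(records[k, ], ref1, ref2, ...))
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(query_id = cl$query_id, family = cl$family,
               identity_to_ref1 = cl$identity_to_ref1,
               identity_to_ref2 = cl$identity_to_ref2,
               ctd_start_motif = cl$ctd_start_motif,
               ctd_end_motif = cl$ctd_end_motif,
               evidence = paste(cl$evidence, collapse = "; "),
               stringsAsFactors = FALSE)))
  df$species <- records$species
  # within-species ranking of CtBP1-family paralogs
  for (sp in unique(df$species)) {
    idx <- which(df$species %in% sp & df$family == "CtBP1_like")
    if (length(idx) > 1L) {
      ord <- idx[order(-df$identity_to_ref1[idx], df$query_id[idx])]
      demote <- ord[-1]
      df$family[demote] <- "CtBP1a"
      df$evidence[demote] <- paste(df$evidence[demote],
        "rank: outranked within species by a higher-identity CtBP1-family paralog",
        sep = "; ")
    }
  }
  rownames(df) <- NULL
  df
}

#' Scan for SUMO consensus sites
#'
#' Reports every psi-K-x-(D/E) consensus sumoylation motif: a
#' hydrophobic residue (psi), the acceptor lysine, any residue, then an
#' acidic residue. Overlapping sites are all reported. The psi set
#' defaults to the package's hydrophobic set \{M, I, V, L, F, Y, W\}.
#'
#' @param seq Residue string or record.
#' @param psi_set Residues accepted at the psi position.
#' @return A data.frame with one row per site: `k_position` (1-based
#'   index of the lysine), `context` (the 4-mer), `psi_residue`,
#'   `alpha_residue`. Zero rows when no site is present.
#' @examples
#' scan_sumo_sites("AVKSE")  # K at position 3, context VKSE
#' @export
scan_sumo_sites <- function(seq, psi_set = AA_HYDROPHOBIC) {
  s <- .residues(seq)
  ch <- .chars(s)
  L <- length(ch)
  empty <- data.frame(k_position = integer(0), context = character(0),
                      psi_residue = character(0),
                      alpha_residue = character(0))
  if (L < 4L) return(empty)
  k <- 2:(L - 2L)
  hit <- ch[k] == "K" & ch[k - 1L] %in% psi_set & ch[k + 2L] %in% AA_NEG
  k <- k[hit]
  if (length(k) == 0L) return(empty)
  data.frame(k_position = k,
             context = vapply(k, function(i)
               substr(s, i - 1L, i + 2L), character(1)),
             psi_residue = ch[k - 1L],
             alpha_residue = ch[k + 2L],
             stringsAsFactors = FALSE)
}

#' Default reference-site tables for human CtBP1 and CtBP2
#'
#' Editable site tables in the numbering of the human reference
#' proteins. CtBP1: the HIPK2 phosphorylation site S422 and the SUMO-1
#' acceptor K428. CtBP2: the tetramerization-interface residues S128,
#' A129, R190, G216 and L221, and the phosphorylation sites S365, T414
#' and S428. The reference sequences themselves are user-supplied
#' FASTA, not bundled.
#'
#' @return Named list of data.frames with columns `name`, `position`
#'   (1-based in reference numbering) and `expected` residue.
#' @export
default_reference_sites <- function() {
  list(
    CtBP1 = data.frame(
      name = c("S422_phospho_HIPK2", "K428_sumo"),
      position = c(422L, 428L),
      expected = c("S", "K"),
      stringsAsFactors = FALSE),
    CtBP2 = data.frame(
      name = c("S128_tetramer", "A129_tetramer", "R190_tetramer",
               "G216_tetramer", "L221_tetramer",
               "S365_phospho", "T414_phospho", "S428_phospho"),
      position = c(128L, 129L, 190L, 216L, 221L, 365L, 414L, 428L),
      expected = c("S", "A", "R", "G", "L", "S", "T", "S"),
      stringsAsFactors = FALSE))
}

#' Audit functional reference sites in a query sequence
#'
#' Globally aligns the query to a reference and reports, for each
#' listed reference site (catalytic, tetramerization or PTM position),
#' the query residue occupying the same alignment column; a site is
#' conserved when the query residue equals the expected residue, and a
#' gap is reported as `"-"`.
#'
#' @param query,reference Residue strings or records.
#' @param sites Data.frame with columns `name`, `position` (1-based in
#'   reference numbering) and `expected`; see
#'   [default_reference_sites()].
#' @return A data.frame with one row per site: `name`, `position`,
#'   `expected`, `query_residue`, `conserved`.
#' @export
audit_reference_sites <- function(query, reference, sites) {
  stopifnot(all(c("name", "position", "expected") %in% names(sites)))
  sref <- .residues(reference)
  bad <- sites$position < 1L | sites$position > nchar(sref)
  if (any(bad))
    stop("site position(s) out of reference range: ",
         paste(sites$name[bad], collapse = ", "), call. = FALSE)
  res <- global_align(query, reference)
  cq <- .chars(res$aligned_a)
  cr <- .chars(res$aligned_b)
  rpos <- cumsum(cr != "-")
  cols <- vapply(sites$position, function(p)
    which(rpos == p & cr != "-")[1], integer(1))
  qres <- cq[cols]
  data.frame(name = sites$name, position = sites$position,
             expected = sites$expected, query_residue = qres,
             conserved = qres == sites$expected,
             stringsAsFactors = FALSE)
}

#' Catalog terminal endings across a record set
#'
#' Extracts each record's terminal `k`-mer and labels it with the
#' longest known terminal motif that is a suffix of the sequence
#' (`"novel"` otherwise, with the raw k-mer retained), then aggregates
#' a species-by-ending presence grid.
#'
#' @param records Sequence table with `id`, `species`, `residues`.
#' @param k Length of the terminal k-mer retained for novel endings.
#' @param known Catalog of known terminal motifs.
#' @return A list with `calls` (per-record data.frame: `id`, `species`,
#'   `terminal_kmer`, `label`) and `presence` (logical species x label
#'   incidence matrix).
#' @export
catalog_endings <- function(records, k = 7L,
                            known = default_ending_catalog()) {
  calls <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    s <- records$residues[i]
    kmer <- substr(s, max(1L, nchar(s) - k + 1L), nchar(s))
    data.frame(id = records$id[i],
               species = if ("species" %in% names(records))
                 records$species[i] else NA_character_,
               terminal_kmer = kmer,
               label = .ending_label(s, known),
               stringsAsFactors = FALSE)
  }))
  presence <- table(calls$species, calls$label) > 0
  list(calls = calls, presence = presence)
}
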