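#' Locate an anchor motif by Hamming distance
#'
#' Scans a protein sequence for a short anchor motif. An exact match is
#' returned if present (leftmost); otherwise the best Hamming-distance
#' match within `max_mismatch` is returned, leftmost on ties. Divergent
#' lineages vary anchor residues, so a small mismatch budget (typically
#' 1) keeps the anchors usable family-wide.
#'
#' @param seq Residue string, or a record with a `residues` field.
#' @param motif Anchor motif (length >= 3).
#' @param max_mismatch Maximum Hamming distance allowed (< motif length).
#' @return A list with `motif`, `start`, `end` (1-based, inclusive),
#'   `mismatches`, `found`, and `best_distance` (the smallest distance
#'   seen, informative when `found` is `FALSE`).
#' @examples
#' find_anchor("AAANCVNPP", "NCVN")
#' find_anchor("AAANCINPP", "NCVN", max_mismatch = 1)
#' @export
find_anchor <- function(seq, motif, max_mismatch = 0L) {
  s <- .residues(seq)
  if (nchar(motif) < 3L) stop("motif must be at least 3 residues", call. = FALSE)
  if (max_mismatch >= nchar(motif))
    stop("max_mismatch must be smaller than the motif length", call. = FALSE)
  d <- .hamming_scan(s, motif)
  if (length(d) == 0L || min(d) > max_mismatch) {
    return(list(motif = motif, start = NA_integer_, end = NA_integer_,
                mismatches = NA_integer_, found = FALSE,
                best_distance = if (length(d)) min(d) else Inf))
  }
  i <- which.min(d)  # leftmost among minima
  list(motif = motif, start = i, end = i + nchar(motif) - 1L,
       mismatches = d[i], found = TRUE, best_distance = d[i])
}

# Vector of Hamming distances of `motif` against every offset of `seq`.
.hamming_scan <- function(seq, motif) {
  s <- .chars(seq)
  m <- .chars(motif)
  n <- length(s) - length(m) + 1L
  if (n < 1L) return(integer(0))
  d <- integer(n)
  for (j in seq_along(m)) d <- d + (s[j:(j + n - 1L)] != m[j])
  d
}

#' Segment a CtBP-like protein into NTD, core and CTD
#'
#' The dehydrogenase core is operationalized as the window from the
#' RPLVALL motif through the NCVN motif (both inclusive); the NTD is
#' everything before it and the CTD everything after. The NCVN motif is
#' assigned to the core, so the CTD starts immediately after it and
#' composition statistics downstream cover only the disordered tail.
#' The CTD anchor is searched downstream of the NTD anchor match.
#'
#' @param seq Residue string or record.
#' @param ntd_anchor Motif marking the core start (default `"RPLVALL"`).
#' @param ctd_anchor Motif marking the core end (default `"NCVN"`).
#' @param max_mismatch Hamming tolerance for both anchors.
#' @return A `domain_segmentation` object: list with 1-based inclusive
#'   intervals `ntd`, `core`, `ctd` (each `c(start, end)`; an empty
#'   interval has `end < start`), `flags` (subset of `no_ntd_anchor`,
#'   `no_ctd_anchor`, `tailless`), `length`, and the `anchors` matches.
#'   The intervals tile `[1, length]` contiguously.
#' @examples
#' segment_domains("AAARPLVALLXXXXNCVNPPPP")
#' @export
segment_domains <- function(seq, ntd_anchor = "RPLVALL",
                            ctd_anchor = "NCVN", max_mismatch = 1L) {
  s <- .residues(seq)
  L <- nchar(s)
  a1 <- find_anchor(s, ntd_anchor, max_mismatch)
  from <- if (a1$found) a1$end + 1L else 1L
  a2 <- if (from <= L) {
    m <- find_anchor(substr(s, from, L), ctd_anchor, max_mismatch)
    if (m$found) {
      m$start <- m$start + from - 1L
      m$end <- m$end + from - 1L
    }
    m
  } else {
    list(motif = ctd_anchor, start = NA_integer_, end = NA_integer_,
         mismatches = NA_integer_, found = FALSE, best_distance = Inf)
  }
  if (!a1$found && !a2$found)
    stop("segmentation failed: neither anchor '", ntd_anchor, "' nor '",
         ctd_anchor, "' found within ", max_mismatch, " mismatch(es)",
         call. = FALSE)

  flags <- character(0)
  core_start <- if (a1$found) a1$start else 1L
  if (!a1$found) flags <- c(flags, "no_ntd_anchor")
  if (a2$found) {
    core_end <- a2$end
    if (core_end == L) flags <- c(flags, "tailless")
  } else {
    core_end <- L
    flags <- c(flags, "no_ctd_anchor")
  }

  structure(list(ntd = c(1L, core_start - 1L),
                 core = c(core_start, core_end),
                 ctd = c(core_end + 1L, L),
                 flags = flags, length = L,
                 anchors = list(ntd = a1, ctd = a2)),
            class = "domain_segmentation")
}

#' @export
print.domain_segmentation <- function(x, ...) {
  fmt <- function(iv) if (iv[2] < iv[1]) "empty" else
    paste0("[", iv[1], ", ", iv[2], "] (", iv[2] - iv[1] + 1L, " aa)")
  cat("Domain segmentation of a ", x$length, "-residue protein\n",
      "  NTD:  ", fmt(x$ntd), "\n",
      "  core: ", fmt(x$core), "\n",
      "  CTD:  ", fmt(x$ctd), "\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.interval_length <- function(iv) max(0L, iv[2] - iv[1] + 1L)

#' Extract the NTD, core and CTD subsequences of a segmentation
#'
#' @param seg A `domain_segmentation`.
#' @param seq The residue string (or record) the segmentation came from.
#' @return Named list of strings `ntd`, `core`, `ctd` (empty string for
#'   empty intervals).
#' @export
domain_sequences <- function(seg, seq) {
  s <- .residues(seq)
  stopifnot(inherits(seg, "domain_segmentation"), nchar(s) == seg$length)
  cut <- function(iv) if (iv[2] < iv[1]) "" else substr(s, iv[1], iv[2])
  list(ntd = cut(seg$ntd), core = cut(seg$core), ctd = cut(seg$ctd))
}

#' Segment every record of a sequence table
#'
#' @param records Sequence table (see [read_fasta()]).
#' @inheritParams segment_domains
#' @return A data.frame with one row per record: interval bounds, domain
#'   lengths, the CTD subsequence and semicolon-joined flags. Records
#'   failing segmentation are kept with `ok = FALSE` and the error text
#'   in `flags` (no silent drops).
#' @export
segment_records <- function(records, ntd_anchor = "RPLVALL",
                            ctd_anchor = "NCVN", max_mismatch = 1L) {
  rows <- lapply(seq_len(nrow(records)), function(k) {
    seg <- tryCatch(segment_domains(records$residues[k], ntd_anchor,
                                    ctd_anchor, max_mismatch),
                    error = function(e) e)
    if (inherits(seg, "error")) {
      return(data.frame(id = records$id[k], ok = FALSE,
                        ntd_start = NA, ntd_end = NA, core_start = NA,
                        core_end = NA, ctd_start = NA, ctd_end = NA,
                        ntd_length = NA, ctd_length = NA,
                        ctd = NA_character_,
                        flags = conditionMessage(seg),
                        stringsAsFactors = FALSE))
    }
    ds <- domain_sequences(seg, records$residues[k])
    data.frame(id = records$id[k], ok = TRUE,
               ntd_start = seg$ntd[1], ntd_end = seg$ntd[2],
               core_start = seg$core[1], core_end = seg$core[2],
               ctd_start = seg$ctd[1], ctd_end = seg$ctd[2],
               ntd_length = .interval_length(seg$ntd),
               ctd_length = .interval_length(seg$ctd),
               ctd = ds$ctd,
               flags = paste(seg$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("species" %in% names(records)) out$species <- records$species
  out
}

#' Catalog of known CTD terminal motifs
#'
#' Terminal motifs observed across CtBP long and short isoforms: the
#' ancestral SEVH-type long ending and its PEPSEVH context, the
#' drosophilid ESTEAP ending, dipteran short endings (SNQEK, APECARP,
#' DNTAR, AKK), the hymenopteran RLSSRC short ending, and the
#' paralog-specific vertebrate endings PADQ (CtBP1-like family) and
#' LTEQ (CtBP2-like family).
#'
#' @return Character vector of motifs.
#' @export
default_ending_catalog <- function() {
  c("SEVH", "PEPSEVH", "APECARP", "SNQEK", "ESTEAP", "RLSSRC",
    "DNTAR", "AKK", "PADQ", "LTEQ")
}

#' Type an isoform as long or short and label its ending
#'
#' Short isoforms terminate shortly after the catalytic core with at
#' most a few extra residues, whereas long isoforms carry the ~90
#' residue disordered extension; a 40-residue CTD threshold separates
#' the two regimes with margin. The ending label is the longest catalog
#' motif that is a suffix of the sequence (`"novel"` if none). NTDs of
#' 300+ residues are flagged as RIBEYE-like extensions (observed
#' RIBEYE-like NTDs run 550--620 residues).
#'
#' @param seg A `domain_segmentation` of `seq`.
#' @param seq The corresponding residue string or record.
#' @param endings Catalog of known terminal motifs.
#' @param short_threshold CTD length (aa) below which a form is short.
#' @param ribeye_threshold NTD length (aa) at or above which the NTD is
#'   called a RIBEYE-like extension.
#' @return A list with `form` (`"long"`/`"short"`), `ending_label`,
#'   `ctd_length` and `ntd_extension` (`"none"`/`"ribeye_like"`).
#' @export
classify_isoform <- function(seg, seq, endings = default_ending_catalog(),
                             short_threshold = 40L, ribeye_threshold = 300L) {
  s <- .residues(seq)
  stopifnot(inherits(seg, "domain_segmentation"), nchar(s) == seg$length)
  ctd_length <- .interval_length(seg$ctd)
  list(form = if (ctd_length < short_threshold) "short" else "long",
       ending_label = .ending_label(s, endings),
       ctd_length = ctd_length,
       ntd_extension = if (.interval_length(seg$ntd) >= ribeye_threshold)
         "ribeye_like" else "none")
}

# Longest catalog motif that suffixes the sequence; "novel" if none.
.ending_label <- function(s, endings) {
  hits <- endings[vapply(endings, function(m) {
    nchar(m) <= nchar(s) &&
      substr(s, nchar(s) - nchar(m) + 1L, nchar(s)) == m
  }, logical(1))]
  if (length(hits) == 0L) return("novel")
  hits[which.max(nchar(hits))]
}
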