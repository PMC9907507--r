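#' Global pairwise alignment (Needleman-Wunsch)
#'
#' End-to-end optimal alignment under +1/-1 match/mismatch scores and a
#' linear gap penalty of -2. Traceback ties are broken deterministically
#' (diagonal, then up, then left). Percent identity is computed over the
#' full alignment length with gap columns counted as non-identical,
#' matching the "percentage of completely conserved residues" reading of
#' identity. The simple scheme is used because percent identity, not an
#' alignment score, is the quantity of interest; substitution-matrix
#' scoring can be emulated by passing different `match`/`mismatch`
#' values but is not the default.
#'
#' @param a,b Residue strings or records; both non-empty.
#' @param match,mismatch,gap Scoring parameters.
#' @return An `alignment_result`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings, never gap-over-gap), `score`,
#'   `identity_pct` in \[0, 100\], and `window` (`NULL` for full-length
#'   identity).
#' @examples
#' global_align("NCVN", "NCVN")$identity_pct  # 100
#' global_align("AAAA", "AATA")$identity_pct  # 75
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  sa <- .residues(a)
  sb <- .residues(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  nw <- .nw_align_cpp(sa, sb, match, mismatch, gap)
  ca <- .chars(nw$aligned_a)
  cb <- .chars(nw$aligned_b)
  ident <- ca == cb & ca != "-"
  structure(list(aligned_a = nw$aligned_a, aligned_b = nw$aligned_b,
                 score = nw$score,
                 identity_pct = 100 * sum(ident) / length(ca),
                 window = NULL),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Global alignment: score ", x$score, ", identity ",
      sprintf("%.1f", x$identity_pct), "%",
      if (!is.null(x$window))
        paste0(" over window columns [", x$window[1], ", ", x$window[2], "]"),
      "\n", sep = "")
  invisible(x)
}

#' Percent identity within the anchored core window
#'
#' Aligns two full-length sequences globally, then restricts percent
#' identity to the alignment columns spanned by the first sequence's
#' RPLVALL...NCVN window, both motifs inclusive. This is the
#' dehydrogenase-core identity used to compare CtBP paralogs. Gap
#' columns inside the window (in either row) count as mismatches, and
#' the denominator is the full window span in alignment columns.
#'
#' @param a Reference sequence: both anchors must be locatable in `a`
#'   (Hamming tolerance `max_mismatch`).
#' @param b Subject sequence.
#' @param start_motif,end_motif Window anchors.
#' @param max_mismatch Anchor Hamming tolerance.
#' @inheritParams global_align
#' @return An `alignment_result` whose `identity_pct` is the
#'   within-window identity and whose `window` gives the alignment
#'   column span used.
#' @export
window_identity <- function(a, b, start_motif = "RPLVALL",
                            end_motif = "NCVN", max_mismatch = 1L,
                            match = 1, mismatch = -1, gap = -2) {
  sa <- .residues(a)
  m1 <- find_anchor(sa, start_motif, max_mismatch)
  if (!m1$found)
    stop("start anchor '", start_motif, "' not found in reference sequence",
         call. = FALSE)
  rest_from <- m1$end + 1L
  m2 <- if (rest_from <= nchar(sa))
    find_anchor(substr(sa, rest_from, nchar(sa)), end_motif, max_mismatch)
  else list(found = FALSE)
  if (!m2$found)
    stop("end anchor '", end_motif, "' not found in reference sequence",
         call. = FALSE)
  w1 <- m1$start
  w2 <- m2$end + rest_from - 1L

  res <- global_align(sa, b, match = match, mismatch = mismatch, gap = gap)
  ca <- .chars(res$aligned_a)
  cb <- .chars(res$aligned_b)
  apos <- cumsum(ca != "-")
  in_window <- which(apos >= w1 & apos <= w2 & ca != "-")
  span <- min(in_window):max(in_window)
  ident <- ca[span] == cb[span] & ca[span] != "-"
  res$identity_pct <- 100 * sum(ident) / length(span)
  res$window <- c(span[1], span[length(span)])
  res
}
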