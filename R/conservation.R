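#' Chemical conservation groups
#'
#' Residue groups used for "chemically conserved" alignment columns:
#' hydrophobic aliphatic (M, V, I, L), hydrophobic aromatic (W, Y, F),
#' acidic (D, E), basic (K, R) and hydroxyl-containing (S, T). The
#' groups are disjoint; residues outside them (A, C, G, H, N, P, Q)
#' belong to no group.
#'
#' @return Named list of character vectors.
#' @export
chemical_groups <- function() {
  list(aliphatic = c("M", "V", "I", "L"),
       aromatic = c("W", "Y", "F"),
       acidic = c("D", "E"),
       basic = c("K", "R"),
       hydroxyl = c("S", "T"))
}

#' Annotate alignment columns with conservation classes
#'
#' Per column, among non-gap rows: a residue present in more than 50%
#' of rows makes the column `conserved`; failing that, a chemical group
#' (see [chemical_groups()]) whose pooled frequency exceeds 50% makes it
#' `chemical`; columns with less than 50% occupancy are classed `none`.
#' Independently of the primary class, a distinct second residue with
#' frequency in the closed interval \[25%, 50%\] is recorded as the
#' secondary residue. Denominators exclude gaps throughout. The pooled
#' >50% quota for chemical conservation mirrors the primary threshold;
#' it is a convention of this package, as is treating the secondary
#' bounds as a closed interval.
#'
#' @param msa A `ctd_msa` with at least 2 rows.
#' @return A data.frame with one row per column: `column` (1-based),
#'   `primary_class` (`conserved`/`chemical`/`none`), `primary_residue`
#'   (residue, or group name for chemical columns), `secondary_residue`,
#'   `majority_residue` (most frequent residue regardless of class,
#'   used for block consensus) and `occupancy`.
#' @export
annotate_columns <- function(msa) {
  stopifnot(inherits(msa, "ctd_msa"))
  if (length(msa$ids) < 2L)
    stop("alignment must have at least 2 rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
  groups <- chemical_groups()
  rows <- lapply(seq_len(msa$n_columns), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    occ <- length(res) / length(col)
    primary_class <- "none"
    primary_residue <- NA_character_
    secondary_residue <- NA_character_
    majority_residue <- NA_character_
    if (length(res) > 0L) {
      tab <- table(res)
      tab <- tab[order(-tab, names(tab))]  # frequency, then alphabet
      freq <- as.numeric(tab) / length(res)
      majority_residue <- names(tab)[1]
      if (length(tab) > 1L && freq[2] >= 0.25 && freq[2] <= 0.5)
        secondary_residue <- names(tab)[2]
      if (occ >= 0.5) {
        if (freq[1] > 0.5) {
          primary_class <- "conserved"
          primary_residue <- names(tab)[1]
        } else {
          pooled <- vapply(groups, function(g) mean(res %in% g), numeric(1))
          if (max(pooled) > 0.5) {
            primary_class <- "chemical"
            primary_residue <- names(groups)[which.max(pooled)]
          }
        }
      }
    }
    data.frame(column = j, primary_class = primary_class,
               primary_residue = primary_residue,
               secondary_residue = secondary_residue,
               majority_residue = majority_residue,
               occupancy = occ, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract conserved blocks from column annotations
#'
#' Operationalizes visually identified conserved blocks (central block,
#' terminal block) as maximal runs of conserved/chemical columns,
#' allowing up to `max_break` interrupting columns in total per block,
#' and keeping blocks of at least `min_len` columns. Blocks start and
#' end on conserved columns; the consensus string is the per-column
#' majority residue.
#'
#' @param annotations Output of [annotate_columns()] for one alignment.
#' @param min_len Minimum block length in columns.
#' @param max_break Maximum total interrupting columns inside a block.
#' @return A data.frame of blocks: `start`, `end` (1-based, inclusive),
#'   `length`, `consensus`, `mean_occupancy`.
#' @export
find_conserved_blocks <- function(annotations, min_len = 5L,
                                  max_break = 1L) {
  ok <- annotations$primary_class %in% c("conserved", "chemical")
  if (!any(ok))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), consensus = character(0),
                      mean_occupancy = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, ok = r$values)
  ok_idx <- which(runs$ok)

  blocks <- list()
  i <- 1L
  while (i <= length(ok_idx)) {
    b_start <- runs$start[ok_idx[i]]
    b_end <- runs$end[ok_idx[i]]
    breaks_used <- 0L
    while (i < length(ok_idx)) {
      gap_run <- ok_idx[i] + 1L
      gap_len <- runs$end[gap_run] - runs$start[gap_run] + 1L
      if (ok_idx[i + 1L] == gap_run + 1L &&
          breaks_used + gap_len <= max_break) {
        breaks_used <- breaks_used + gap_len
        i <- i + 1L
        b_end <- runs$end[ok_idx[i]]
      } else break
    }
    blocks[[length(blocks) + 1L]] <- c(b_start, b_end)
    i <- i + 1L
  }

  rows <- lapply(blocks, function(iv) {
    len <- iv[2] - iv[1] + 1L
    if (len < min_len) return(NULL)
    cols <- iv[1]:iv[2]
    cons <- annotations$majority_residue[cols]
    cons[is.na(cons)] <- "-"
    data.frame(start = iv[1], end = iv[2], length = len,
               consensus = paste(cons, collapse = ""),
               mean_occupancy = mean(annotations$occupancy[cols]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), consensus = character(0),
                      mean_occupancy = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove overly gappy alignment columns
#'
#' Light-weight trimming before conservation annotation: columns whose
#' gap fraction exceeds `max_gap_fraction` are removed; row order is
#' preserved.
#'
#' @param msa A `ctd_msa`.
#' @param max_gap_fraction Columns with a gap fraction strictly above
#'   this value are dropped.
#' @return A trimmed `ctd_msa`.
#' @export
drop_gappy_columns <- function(msa, max_gap_fraction = 0.8) {
  stopifnot(inherits(msa, "ctd_msa"))
  mat <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep))
    stop("all columns exceed the gap-fraction threshold", call. = FALSE)
  new_msa(msa$ids,
          apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""))
}
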