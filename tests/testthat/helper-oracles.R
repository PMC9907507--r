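# Independent oracles and fixture builders used across the test files.

# Exhaustive global-alignment score: plain recursion over the three
# possible last columns of a monotone alignment, no DP matrix or
# traceback shared with the implementation.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (substr(a, i, i) == substr(b, j, j)) match
                    else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Single-pass counting oracle for composition fractions.
oracle_composition <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = c(LETTERS)))
  counted <- sum(tab) - tab[["X"]]
  list(length_aa = length(ch),
       frac_pga = (tab[["P"]] + tab[["G"]] + tab[["A"]]) / counted,
       frac_hydrophobic = sum(tab[c("M", "I", "V", "L", "F", "Y", "W")]) /
         counted,
       f_pos = (tab[["K"]] + tab[["R"]]) / counted,
       f_neg = (tab[["D"]] + tab[["E"]]) / counted)
}

# Sliding-window SUMO oracle: checks every 4-mer explicitly.
oracle_sumo_positions <- function(s,
                                  psi = c("M", "I", "V", "L", "F", "Y", "W")) {
  out <- integer(0)
  if (nchar(s) < 4) return(out)
  for (i in 1:(nchar(s) - 3)) {
    w <- strsplit(substr(s, i, i + 3), "")[[1]]
    if (w[1] %in% psi && w[2] == "K" && w[4] %in% c("D", "E"))
      out <- c(out, i + 1L)
  }
  out
}

random_protein <- function(n, alphabet = strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(headers, seqs) {
  tmp <- tempfile(fileext = ".fa")
  writeLines(unlist(Map(function(h, s) c(paste0(">", h), s),
                        headers, seqs)), tmp)
  tmp
}

# Aligned-FASTA fixture for building small test MSAs by hand.
write_temp_msa <- function(ids, rows) {
  write_temp_fasta(ids, rows)
}

# ClustalW dialect of the same alignment (header, two blank lines,
# 60-column blocks).
write_temp_clustal <- function(ids, rows, block = 60L) {
  tmp <- tempfile(fileext = ".aln")
  lines <- c("CLUSTAL W (1.83) multiple sequence alignment", "", "")
  width <- nchar(rows[1])
  for (from in seq(1L, width, by = block)) {
    to <- min(from + block - 1L, width)
    lines <- c(lines,
               paste0(formatC(ids, width = 16, flag = "-"),
                      substr(rows, from, to)),
               "")
  }
  writeLines(lines, tmp)
  tmp
}

# Ancestor-coordinate positions free of block protection (anchors and
# CTD blocks), recomputed from the family layout independently of the
# generator's internal mask. Valid for records without deletions.
unprotected_positions <- function(family) {
  spec <- family$spec
  layout <- family$layout
  L <- layout$end[nrow(layout)]
  protected <- logical(L)
  core_off <- layout$start[layout$segment == "core"] - 1L
  for (anchor in c("RPLVALL", "NCVN")) {
    p <- regexpr(anchor, spec$core_template, fixed = TRUE)[1]
    protected[(core_off + p):(core_off + p + nchar(anchor) - 1L)] <- TRUE
  }
  for (seg in grep("^block", layout$segment)) {
    protected[layout$start[seg]:layout$end[seg]] <- TRUE
  }
  which(!protected)
}
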