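#' Composition profile of a disordered region
#'
#' Computes the CTD property panel for one or more residue strings:
#' length, fraction of the disorder-promoting residues P/G/A, fraction
#' of hydrophobic residues (M, I, V, L, F, Y, W), positive (K/R) and
#' negative (D/E) charged fractions, FCR (fraction of charged residues,
#' `f_pos + f_neg`), NCPR (net charge per residue, stored both signed as
#' `f_pos - f_neg` and as the magnitude used for thresholding), plus the
#' Das-Pappu phase label and the weak-polyampholyte flag (FCR < 0.3 and
#' |NCPR| < 0.25). Histidine is treated as uncharged. Ambiguity code `X`
#' is excluded from numerators and denominators so it cannot dilute the
#' fractions; `length_aa` still counts all residues.
#'
#' @param x Character vector of residue strings (optionally named), or a
#'   sequence table with `id` and `residues` columns.
#' @return A data.frame with one row per sequence: `id`, `length_aa`,
#'   `frac_pga`, `frac_hydrophobic`, `f_pos`, `f_neg`, `fcr`, `ncpr`
#'   (magnitude), `ncpr_signed`, `phase_label`, `weak_polyampholyte`.
#' @examples
#' composition_profile("KKDD")    # fcr 1, ncpr 0
#' composition_profile("PPGGAA")  # frac_pga 1
#' @export
composition_profile <- function(x) {
  if (is.data.frame(x)) {
    ids <- x$id
    seqs <- x$residues
  } else {
    seqs <- x
    ids <- if (!is.null(names(x))) names(x) else
      paste0("seq", seq_along(x))
  }
  if (length(seqs) == 0L)
    stop("no sequences to profile", call. = FALSE)
  rows <- lapply(seq_along(seqs), function(k) {
    s <- seqs[k]
    if (is.na(s) || nchar(s) == 0L)
      stop("empty sequence (", ids[k], "): composition undefined",
           call. = FALSE)
    ch <- .chars(s)
    counted <- ch[ch != "X"]
    n <- length(counted)
    if (n == 0L)
      stop("sequence (", ids[k], ") is all-X: fractions undefined",
           call. = FALSE)
    f_pos <- sum(counted %in% AA_POS) / n
    f_neg <- sum(counted %in% AA_NEG) / n
    data.frame(id = ids[k], length_aa = length(ch),
               frac_pga = sum(counted %in% AA_PGA) / n,
               frac_hydrophobic = sum(counted %in% AA_HYDROPHOBIC) / n,
               f_pos = f_pos, f_neg = f_neg,
               fcr = f_pos + f_neg,
               ncpr = abs(f_pos - f_neg),
               ncpr_signed = f_pos - f_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ph <- phase_classify(out$fcr, out$ncpr_signed)
  out$phase_label <- ph$phase_label
  out$weak_polyampholyte <- ph$weak_polyampholyte
  rownames(out) <- NULL
  out
}

#' Das-Pappu phase classification of an IDR
#'
#' Places a sequence on the Das-Pappu diagram of disordered-region
#' conformational classes using the standard region boundaries:
#' R1 (weak polyampholytes/polyelectrolytes) at FCR < 0.25, the R2
#' boundary region at 0.25 <= FCR <= 0.35, R3 (strong polyampholytes)
#' at FCR > 0.35 with |NCPR| <= 0.35, and R4/R5 (negative/positive
#' polyelectrolytes) at signed NCPR beyond -0.35/+0.35. Independently of
#' the region, a simpler weak-polyampholyte flag is reported for
#' FCR < 0.3 and |NCPR| < 0.25; this coarser cutoff is in common use
#' for CTD-like tails and is deliberately kept separate from the R1/R2
#' boundary at 0.25 rather than merged with it.
#'
#' @param fcr Numeric vector of FCR values.
#' @param ncpr_signed Numeric vector of signed NCPR values
#'   (`f_pos - f_neg`).
#' @return A list of two vectors, `phase_label` and
#'   `weak_polyampholyte`.
#' @examples
#' phase_classify(0.10, 0.05)   # R1_weak, flag TRUE
#' phase_classify(1.0, -1.0)    # R4_negative_polyelectrolyte
#' @export
phase_classify <- function(fcr, ncpr_signed) {
  stopifnot(length(fcr) == length(ncpr_signed))
  ncpr <- abs(ncpr_signed)
  phase <- ifelse(fcr < 0.25, "R1_weak",
           ifelse(fcr <= 0.35, "R2_boundary",
           ifelse(ncpr <= 0.35, "R3_strong_polyampholyte",
           ifelse(ncpr_signed < 0, "R4_negative_polyelectrolyte",
                                   "R5_positive_polyelectrolyte"))))
  list(phase_label = phase,
       weak_polyampholyte = fcr < 0.3 & ncpr < 0.25)
}

#' Per-residue disorder propensity table
#'
#' Proline is the most disorder-promoting residue (propensity 1.0);
#' alanine and glycine score 0.45 and 0.43. Other residues default to 0
#' and can be overridden.
#'
#' @param ... Named overrides, e.g. `S = 0.5`.
#' @return Named numeric vector over the 20 amino acids, values in
#'   \[0, 1\].
#' @export
disorder_propensity <- function(...) {
  tab <- setNames(numeric(length(AA_PROTEIN)), AA_PROTEIN)
  tab["P"] <- 1.0
  tab["A"] <- 0.45
  tab["G"] <- 0.43
  over <- c(...)
  if (length(over)) {
    stopifnot(all(names(over) %in% AA_PROTEIN),
              all(over >= 0 & over <= 1))
    tab[names(over)] <- over
  }
  tab
}

#' Pick one CTD per species (the longest)
#'
#' Species-level property summaries use a single CTD per species: the
#' longest one, breaking ties by the lexicographically smallest record
#' id (logged). Species whose records are all tailless (empty CTD) are
#' excluded with a warning.
#'
#' @param ctd_table Data.frame with columns `species`, `id` and `ctd`
#'   (CTD residue strings; empty or `NA` for tailless records), e.g.
#'   from [segment_records()].
#' @return One row per retained species.
#' @export
select_longest_ctd <- function(ctd_table) {
  stopifnot(all(c("species", "id", "ctd") %in% names(ctd_table)))
  if (anyNA(ctd_table$species))
    stop("species missing for record(s): ",
         paste(ctd_table$id[is.na(ctd_table$species)], collapse = ", "),
         call. = FALSE)
  keep <- !is.na(ctd_table$ctd) & nchar(ctd_table$ctd) > 0L
  dropped <- setdiff(unique(ctd_table$species),
                     unique(ctd_table$species[keep]))
  if (length(dropped))
    warning("excluding species with only tailless records: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  tab <- ctd_table[keep, , drop = FALSE]
  rows <- lapply(split(tab, tab$species), function(g) {
    len <- nchar(g$ctd)
    best <- g[len == max(len), , drop = FALSE]
    if (nrow(best) > 1L) {
      best <- best[order(best$id), , drop = FALSE]
      message("species '", best$species[1], "': CTD length tie, keeping '",
              best$id[1], "'")
    }
    best[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize composition profiles by group
#'
#' Unweighted per-group mean/min/max of every numeric profile field
#' (each species contributes once), mirroring clade-averaged property
#' displays.
#'
#' @param profiles Data.frame with a `species` column plus numeric
#'   profile columns (see [composition_profile()]).
#' @param grouping Data.frame mapping `species` to `group`; every
#'   species in `profiles` must map to exactly one group.
#' @return A data.frame with one row per group: `group`, `n_species`,
#'   then `<field>_mean`, `<field>_min`, `<field>_max` per numeric
#'   field.
#' @export
aggregate_by_group <- function(profiles, grouping) {
  stopifnot("species" %in% names(profiles),
            all(c("species", "group") %in% names(grouping)))
  if (anyDuplicated(grouping$species))
    stop("species mapped to more than one group: ",
         paste(unique(grouping$species[duplicated(grouping$species)]),
               collapse = ", "), call. = FALSE)
  unmapped <- setdiff(profiles$species, grouping$species)
  if (length(unmapped))
    stop("species without a group: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  grp <- grouping$group[match(profiles$species, grouping$species)]
  num_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  rows <- lapply(split(seq_len(nrow(profiles)), grp), function(idx) {
    row <- data.frame(group = grp[idx][1], n_species = length(idx),
                      stringsAsFactors = FALSE)
    for (cn in num_cols) {
      v <- profiles[[cn]][idx]
      row[[paste0(cn, "_mean")]] <- mean(v)
      row[[paste0(cn, "_min")]] <- min(v)
      row[[paste0(cn, "_max")]] <- max(v)
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
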