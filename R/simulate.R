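# Fixed ancestral templates for the synthetic CtBP-like family. The core
# carries the RPLVALL and NCVN anchors exactly once each, with overall
# composition close to a folded dehydrogenase domain (~34% hydrophobic,
# ~20% P/G/A); neither template contains any window within Hamming
# distance 1 of an anchor, so anchors stay unambiguous under mutation.
DEFAULT_NTD_TEMPLATE <- "MDLSHKFDVLNESAGTRLIEKVDASQYPRD"
DEFAULT_CORE_TEMPLATE <- paste0(
  "YYGQPTDAPDIDYVIMHAITNACMLIKNEQRFKPLQLVNSKELHEMNPHSKKERL",
  "RPLVALL",
  "RPAVIPCRTQVGFDVLAVIVDLKILSAKPRTVLLGPLVYYDGIRSSVVKMHRDTLSQRETTLKSQK",
  "ETSDEYHVDNSSYQSFARSALIRDFAMGADGREPRVLAPYTSVTAEGAVDEEIEAFSFRYQGVRRY",
  "FAGVRAALLTARDNTQEAEHIVVTPKLEQTKTNIATHGFGVLVKAGLWFLNTELTLVTIAAIMKVG",
  "TLFATTSDAGMIANVYNAREANKGEIKILVCGAILKLQDGKGLRSALIELGNYKAGGAHILV",
  "NCVN")

#' Default spacer residue sampling weights
#'
#' Tuned to the composition of the P/G/A-rich disordered spacers that
#' separate conserved CTD blocks: expected P+G+A fraction 0.45,
#' expected charged fraction 0.14, expected hydrophobic fraction 0.07.
#'
#' @return Named numeric weight vector over the 20 amino acids.
#' @export
default_spacer_weights <- function() {
  c(P = 0.18, A = 0.15, G = 0.12, S = 0.10, T = 0.08,
    N = 0.05, Q = 0.05, H = 0.04, K = 0.04, D = 0.04,
    R = 0.03, E = 0.03, V = 0.02, L = 0.02, M = 0.01,
    I = 0.01, F = 0.01, Y = 0.01, C = 0.01, W = 0.00)
}

#' Default vertebrate-style paralog families for the generator
#'
#' @return Data.frame with columns `family`, `start_motif`,
#'   `end_motif`: the CtBP1-family KEYL...PADQ and CtBP2-family
#'   KEFF...LTEQ CTD signatures.
#' @export
default_paralog_families <- function() {
  data.frame(family = c("CtBP1_like", "CtBP2_like"),
             start_motif = c("KEYL", "KEFF"),
             end_motif = c("PADQ", "LTEQ"),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic CtBP-like protein family
#'
#' Describes the generative model for [generate_family()]: an ancestor
#' assembled from an NTD, a dehydrogenase-core template carrying the
#' RPLVALL...NCVN anchors, and a CTD of conserved blocks (by default a
#' KEY prefix adjacent to NCVN, the PELNGAIYRY central block, AHSTT,
#' and a PEPSEVH terminal block) separated by disordered spacers
#' sampled from `spacer_weights`; the default spacer lengths give a
#' 95-residue CTD. Species descend from the ancestor by independent
#' per-site substitution with probability `p_sub` (uniform over the 19
#' alternative residues), damped by `block_protection` inside anchors
#' and blocks. Species may additionally emit a short isoform truncated
#' after the core with a sampled short ending, and the family can be
#' duplicated into vertebrate-style paralog families whose CTD
#' start/end motifs are overwritten (and protected) per family.
#'
#' @param n_species Number of species.
#' @param tree `"star"` (each species descends independently from the
#'   family ancestor) or `"balanced"` (perfect binary tree with
#'   per-branch substitution probability `p_sub`).
#' @param p_sub Per-site substitution probability per branch, in
#'   \[0, 1\].
#' @param ntd_template,core_template Ancestral NTD / core residue
#'   strings; the core must contain each anchor exactly once.
#' @param ctd_blocks Ordered conserved CTD block strings.
#' @param spacer_lengths Spacer lengths; must be one fewer than the
#'   number of blocks.
#' @param spacer_weights Residue sampling weights for spacers
#'   (non-negative, not all zero).
#' @param block_protection Multiplier on `p_sub` inside anchors and
#'   blocks (0.1 keeps blocks recognizably conserved).
#' @param short_isoform_prob Probability that a species also emits a
#'   short isoform (per species and family).
#' @param short_endings Short-isoform terminal motifs to sample from.
#' @param paralog_families Optional data.frame (`family`,
#'   `start_motif`, `end_motif`), e.g. [default_paralog_families()];
#'   `NULL` generates a single unduplicated family named `"CtBP"`.
#' @param paralog_divergence Extra per-site substitution probability
#'   applied independently to each paralog-family ancestor.
#' @param indel_prob Per-site deletion probability inside spacers of
#'   descendants (deletions only, so the true alignment stays exact).
#' @param seed Integer seed; the same spec and seed reproduce the
#'   family byte-for-byte.
#' @return A validated `family_spec` object.
#' @export
family_spec <- function(n_species = 20L,
                        tree = c("star", "balanced"),
                        p_sub = 0.05,
                        ntd_template = DEFAULT_NTD_TEMPLATE,
                        core_template = DEFAULT_CORE_TEMPLATE,
                        ctd_blocks = c("KEY", "PELNGAIYRY", "AHSTT",
                                       "PEPSEVH"),
                        spacer_lengths = c(25L, 25L, 20L),
                        spacer_weights = default_spacer_weights(),
                        block_protection = 0.1,
                        short_isoform_prob = 0.25,
                        short_endings = c("SNQEK", "APECARP"),
                        paralog_families = NULL,
                        paralog_divergence = 0.08,
                        indel_prob = 0,
                        seed = 1L) {
  spec <- structure(list(n_species = as.integer(n_species),
                         tree = match.arg(tree), p_sub = p_sub,
                         ntd_template = ntd_template,
                         core_template = core_template,
                         ctd_blocks = ctd_blocks,
                         spacer_lengths = as.integer(spacer_lengths),
                         spacer_weights = spacer_weights,
                         block_protection = block_protection,
                         short_isoform_prob = short_isoform_prob,
                         short_endings = short_endings,
                         paralog_families = paralog_families,
                         paralog_divergence = paralog_divergence,
                         indel_prob = indel_prob,
                         seed = as.integer(seed)),
                    class = "family_spec")
  validate_family_spec(spec)
}

#' @keywords internal
validate_family_spec <- function(spec) {
  with(spec, {
    if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
    if (p_sub < 0 || p_sub > 1) stop("p_sub must be in [0, 1]", call. = FALSE)
    if (block_protection < 0 || block_protection > 1)
      stop("block_protection must be in [0, 1]", call. = FALSE)
    if (short_isoform_prob < 0 || short_isoform_prob > 1)
      stop("short_isoform_prob must be in [0, 1]", call. = FALSE)
    if (any(spacer_weights < 0) || sum(spacer_weights) <= 0)
      stop("spacer weights must be non-negative and not all zero",
           call. = FALSE)
    for (anchor in c("RPLVALL", "NCVN")) {
      hits <- gregexpr(anchor, core_template, fixed = TRUE)[[1]]
      if (length(hits[hits > 0]) != 1L)
        stop("core_template must contain '", anchor, "' exactly once",
             call. = FALSE)
    }
    if (!endsWith(core_template, "NCVN"))
      stop("core_template must end with the NCVN anchor so the CTD ",
           "starts immediately after it", call. = FALSE)
    if (length(spacer_lengths) != length(ctd_blocks) - 1L)
      stop("need exactly one spacer between consecutive CTD blocks ",
           "(length(spacer_lengths) == length(ctd_blocks) - 1)",
           call. = FALSE)
    if (!is.null(paralog_families) &&
        !all(c("family", "start_motif", "end_motif") %in%
             names(paralog_families)))
      stop("paralog_families needs columns family, start_motif, end_motif",
           call. = FALSE)
  })
  spec
}

#' Analytic spacer composition expected under a family spec
#'
#' Closed-form expectation of the composition profile of freshly
#' sampled spacer residues (weight-normalized), used as the oracle for
#' parameter-recovery tests. Substitution during descent pulls realized
#' spacer composition slightly toward uniform; at the default rates the
#' shift is well under 0.02.
#'
#' @param spec A `family_spec`.
#' @return One-row data.frame: `frac_pga`, `frac_hydrophobic`, `f_pos`,
#'   `f_neg`, `fcr`, `ncpr_signed`, `ncpr`.
#' @examples
#' sp <- family_spec()
#' expected_spacer_composition(sp)$frac_pga  # 0.45 under default weights
#' @export
expected_spacer_composition <- function(spec) {
  w <- spec$spacer_weights
  if (sum(w) <= 0) stop("zero total spacer weight", call. = FALSE)
  w <- w / sum(w)
  f_pos <- sum(w[names(w) %in% AA_POS])
  f_neg <- sum(w[names(w) %in% AA_NEG])
  data.frame(frac_pga = sum(w[names(w) %in% AA_PGA]),
             frac_hydrophobic = sum(w[names(w) %in% AA_HYDROPHOBIC]),
             f_pos = f_pos, f_neg = f_neg, fcr = f_pos + f_neg,
             ncpr_signed = f_pos - f_neg, ncpr = abs(f_pos - f_neg))
}

# Substitute characters of `ch` in place with per-site probability
# `rate`; replacements are uniform over the 19 alternative residues.
.mutate_chars <- function(ch, rate) {
  live <- ch != "-"
  hit <- which(live & stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA_PROTEIN, ch[i]), 1L)
  ch
}

#' Generate a synthetic CtBP-like protein family with ground truth
#'
#' Runs the generative model described in [family_spec()] and records
#' every truth needed to validate the pipeline: the gap-aware true
#' alignment of all long isoforms, per-record true domain boundaries
#' (in each record's own coordinates), and true isoform/paralog labels.
#' All randomness derives from `spec$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param spec A `family_spec`.
#' @return A `synthetic_family`: list with `records` (sequence table),
#'   `true_alignment` (`ctd_msa` over long isoforms, in ancestor
#'   coordinates), `true_boundaries`, `true_labels`, `ancestors`
#'   (named list of family-ancestor residue strings), `layout`
#'   (ancestor-coordinate segment table, including spacers) and `spec`.
#' @examples
#' fam <- generate_family(family_spec(n_species = 4, seed = 7))
#' head(fam$records$id)
#' @export
generate_family <- function(spec) {
  validate_family_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  aa <- names(spec$spacer_weights)
  spacers <- lapply(spec$spacer_lengths, function(n)
    paste(sample(aa, n, replace = TRUE, prob = spec$spacer_weights),
          collapse = ""))

  # assemble ancestor and its segment layout (ancestor coordinates)
  pieces <- list(ntd = spec$ntd_template, core = spec$core_template)
  for (i in seq_along(spec$ctd_blocks)) {
    pieces[[paste0("block", i)]] <- spec$ctd_blocks[i]
    if (i < length(spec$ctd_blocks))
      pieces[[paste0("spacer", i)]] <- spacers[[i]]
  }
  lens <- vapply(pieces, nchar, integer(1))
  ends <- cumsum(lens)
  layout <- data.frame(segment = names(pieces),
                       start = ends - lens + 1L, end = ends,
                       stringsAsFactors = FALSE)
  ancestor <- paste(unlist(pieces), collapse = "")
  L <- nchar(ancestor)
  ctd_start <- layout$end[layout$segment == "core"] + 1L

  # protection mask: anchors inside the core plus every CTD block
  protected <- logical(L)
  core_off <- layout$start[layout$segment == "core"] - 1L
  for (anchor in c("RPLVALL", "NCVN")) {
    p <- regexpr(anchor, spec$core_template, fixed = TRUE)[1]
    protected[(core_off + p):(core_off + p + nchar(anchor) - 1L)] <- TRUE
  }
  for (i in seq_along(spec$ctd_blocks)) {
    seg <- layout[layout$segment == paste0("block", i), ]
    protected[seg$start:seg$end] <- TRUE
  }
  spacer_mask <- logical(L)
  for (i in seq_along(spec$spacer_lengths)) {
    seg <- layout[layout$segment == paste0("spacer", i), ]
    spacer_mask[seg$start:seg$end] <- TRUE
  }

  # family ancestors (paralog duplication with motif overwrite)
  fams <- if (is.null(spec$paralog_families))
    data.frame(family = "CtBP", start_motif = NA, end_motif = NA,
               stringsAsFactors = FALSE)
  else spec$paralog_families
  rate_base <- ifelse(protected, spec$p_sub * spec$block_protection,
                      spec$p_sub)
  ancestors <- list()
  fam_protected <- list()
  for (f in seq_len(nrow(fams))) {
    ch <- .chars(ancestor)
    prot_f <- protected
    if (!is.null(spec$paralog_families)) {
      rate_dup <- ifelse(protected,
                         spec$paralog_divergence * spec$block_protection,
                         spec$paralog_divergence)
      ch <- .mutate_chars(ch, rate_dup)
      sm <- .chars(fams$start_motif[f])
      em <- .chars(fams$end_motif[f])
      ch[ctd_start:(ctd_start + length(sm) - 1L)] <- sm
      ch[(L - length(em) + 1L):L] <- em
      prot_f[ctd_start:(ctd_start + length(sm) - 1L)] <- TRUE
      prot_f[(L - length(em) + 1L):L] <- TRUE
    }
    ancestors[[fams$family[f]]] <- paste(ch, collapse = "")
    fam_protected[[fams$family[f]]] <- prot_f
  }

  # descend species from each family ancestor
  species <- sprintf("sp%03d", seq_len(spec$n_species))
  descend <- function(anc_chars, rate) {
    if (spec$tree == "star") {
      lapply(seq_len(spec$n_species), function(i)
        .mutate_chars(anc_chars, rate))
    } else {
      depth <- max(1L, ceiling(log2(spec$n_species)))
      tips <- list(anc_chars)
      for (d in seq_len(depth)) {
        tips <- unlist(lapply(tips, function(node)
          list(.mutate_chars(node, rate), .mutate_chars(node, rate))),
          recursive = FALSE)
      }
      tips[seq_len(spec$n_species)]
    }
  }

  rec_rows <- list()
  aln_ids <- character(0)
  aln_rows <- character(0)
  bound_rows <- list()
  label_rows <- list()
  core_end_anc <- layout$end[layout$segment == "core"]
  # the true core starts at the RPLVALL anchor: any template residues
  # before it belong to the NTD, matching the segmentation definition
  core_start_anc <- core_off +
    regexpr("RPLVALL", spec$core_template, fixed = TRUE)[1]

  for (f in seq_len(nrow(fams))) {
    fam <- fams$family[f]
    rate <- ifelse(fam_protected[[fam]],
                   spec$p_sub * spec$block_protection, spec$p_sub)
    tips <- descend(.chars(ancestors[[fam]]), rate)
    for (i in seq_len(spec$n_species)) {
      ch <- tips[[i]]
      if (spec$indel_prob > 0) {
        del <- spacer_mask & stats::runif(L) < spec$indel_prob
        ch[del] <- "-"
      }
      aligned <- paste(ch, collapse = "")
      residues <- gsub("-", "", aligned, fixed = TRUE)
      # map ancestor coordinates to record coordinates
      live_cum <- cumsum(ch != "-")
      id_long <- paste(species[i], fam, "L", sep = "_")
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        id = id_long, species = species[i],
        description = paste(fam, "long isoform"),
        residues = residues, moltype = "protein",
        stringsAsFactors = FALSE)
      aln_ids <- c(aln_ids, id_long)
      aln_rows <- c(aln_rows, aligned)
      bound_rows[[length(bound_rows) + 1L]] <- data.frame(
        id = id_long,
        ntd_start = 1L, ntd_end = live_cum[core_start_anc - 1L],
        core_start = live_cum[core_start_anc - 1L] + 1L,
        core_end = live_cum[core_end_anc],
        ctd_start = live_cum[core_end_anc] + 1L,
        ctd_end = live_cum[L], length = live_cum[L],
        stringsAsFactors = FALSE)
      end_block <- if (!is.null(spec$paralog_families))
        fams$end_motif[f] else spec$ctd_blocks[length(spec$ctd_blocks)]
      label_rows[[length(label_rows) + 1L]] <- data.frame(
        id = id_long, species = species[i], family = fam,
        form = "long", ending = end_block, stringsAsFactors = FALSE)

      if (stats::runif(1) < spec$short_isoform_prob) {
        ending <- sample(spec$short_endings, 1L)
        short_res <- paste0(substr(residues, 1L, live_cum[core_end_anc]),
                            ending)
        id_short <- paste(species[i], fam, "S", sep = "_")
        rec_rows[[length(rec_rows) + 1L]] <- data.frame(
          id = id_short, species = species[i],
          description = paste(fam, "short isoform"),
          residues = short_res, moltype = "protein",
          stringsAsFactors = FALSE)
        bound_rows[[length(bound_rows) + 1L]] <- data.frame(
          id = id_short,
          ntd_start = 1L, ntd_end = live_cum[core_start_anc - 1L],
          core_start = live_cum[core_start_anc - 1L] + 1L,
          core_end = live_cum[core_end_anc],
          ctd_start = live_cum[core_end_anc] + 1L,
          ctd_end = nchar(short_res), length = nchar(short_res),
          stringsAsFactors = FALSE)
        label_rows[[length(label_rows) + 1L]] <- data.frame(
          id = id_short, species = species[i], family = fam,
          form = "short", ending = ending, stringsAsFactors = FALSE)
      }
    }
  }

  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL
  structure(list(records = records,
                 true_alignment = new_msa(aln_ids, aln_rows),
                 true_boundaries = do.call(rbind, bound_rows),
                 true_labels = do.call(rbind, label_rows),
                 ancestors = ancestors,
                 layout = layout,
                 spec = spec),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("Synthetic CtBP-like family: ", nrow(x$records), " records (",
      x$spec$n_species, " species, ",
      length(x$ancestors), " paralog famil",
      if (length(x$ancestors) == 1) "y" else "ies",
      "), p_sub = ", x$spec$p_sub, ", seed = ", x$spec$seed, "\n",
      sep = "")
  invisible(x)
}

#' True spacer intervals of a synthetic family, per record
#'
#' Maps the generator's ancestor-coordinate spacer segments into each
#' long record's own coordinates (robust to spacer deletions), for
#' parameter-recovery tests on realized spacer composition.
#'
#' @param family A `synthetic_family`.
#' @return Data.frame with columns `id`, `segment`, `start`, `end`
#'   (1-based inclusive, in record coordinates; rows with `end <
#'   start` mean the spacer was fully deleted).
#' @export
true_spacer_intervals <- function(family) {
  stopifnot(inherits(family, "synthetic_family"))
  segs <- family$layout[grepl("^spacer", family$layout$segment), ]
  out <- lapply(seq_along(family$true_alignment$ids), function(k) {
    ch <- .chars(family$true_alignment$seqs[k])
    live_cum <- cumsum(ch != "-")
    data.frame(id = family$true_alignment$ids[k], segment = segs$segment,
               start = ifelse(segs$start == 1L, 1L,
                              live_cum[segs$start - 1L] + 1L),
               end = live_cum[segs$end],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract realized spacer residues of every long record
#'
#' @param family A `synthetic_family`.
#' @return Named character vector: concatenated spacer residues per
#'   long record.
#' @export
spacer_residues <- function(family) {
  iv <- true_spacer_intervals(family)
  recs <- setNames(family$records$residues, family$records$id)
  vapply(split(iv, iv$id), function(g) {
    s <- recs[[g$id[1]]]
    paste(vapply(seq_len(nrow(g)), function(j)
      if (g$end[j] < g$start[j]) "" else substr(s, g$start[j], g$end[j]),
      character(1)), collapse = "")
  }, character(1))
}
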