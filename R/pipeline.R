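#' Build and validate a pipeline run configuration
#'
#' Collects the inputs and thresholds for [run_pipeline()]. All
#' referenced paths must exist at validation time; thresholds must lie
#' in their documented ranges.
#'
#' @param fasta Path to the input protein FASTA.
#' @param out_dir Output directory (created if missing).
#' @param grouping Optional path to a TSV mapping `species` to `group`.
#' @param msa Optional path to an MSA for conservation annotation.
#' @param msa_dialect Dialect of `msa` (see [read_msa()]).
#' @param ref1,ref2 Optional paths to single-record reference FASTAs
#'   (designated CtBP1/CtBP2) enabling paralog classification.
#' @param ntd_anchor,ctd_anchor,max_mismatch Segmentation anchors.
#' @param short_threshold,ribeye_threshold Isoform typing thresholds.
#' @param seed Integer seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(fasta, out_dir, grouping = NULL, msa = NULL,
                            msa_dialect = "aligned_fasta",
                            ref1 = NULL, ref2 = NULL,
                            ntd_anchor = "RPLVALL", ctd_anchor = "NCVN",
                            max_mismatch = 1L, short_threshold = 40L,
                            ribeye_threshold = 300L, seed = 1L) {
  cfg <- list(fasta = fasta, out_dir = out_dir, grouping = grouping,
              msa = msa, msa_dialect = msa_dialect,
              ref1 = ref1, ref2 = ref2,
              ntd_anchor = ntd_anchor, ctd_anchor = ctd_anchor,
              max_mismatch = as.integer(max_mismatch),
              short_threshold = as.integer(short_threshold),
              ribeye_threshold = as.integer(ribeye_threshold),
              seed = as.integer(seed))
  for (p in c("fasta", "grouping", "msa", "ref1", "ref2")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config error: ", p, " path does not exist: ", cfg[[p]],
           call. = FALSE)
  }
  if (cfg$max_mismatch < 0L || cfg$max_mismatch > 3L)
    stop("config error: max_mismatch must be in 0..3", call. = FALSE)
  if (cfg$short_threshold < 1L)
    stop("config error: short_threshold must be positive", call. = FALSE)
  if (xor(is.null(cfg$ref1), is.null(cfg$ref2)))
    stop("config error: ref1 and ref2 must be given together",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Run the full CTD profiling pipeline
#'
#' Chains segmentation, isoform typing, CTD composition profiling
#' (per record and per species via the longest CTD), optional group
#' aggregation, terminal-ending cataloguing, SUMO-consensus scanning of
#' CTDs, optional MSA conservation annotation and optional paralog
#' classification over one dataset. Each stage writes a deterministic
#' TSV/JSON under `out_dir`; a `manifest.json` records the package
#' version, the resolved configuration, input checksums and per-stage
#' row counts. Rerunning with identical inputs reproduces identical
#' outputs. Records that fail a stage are carried through with their
#' failure reason rather than silently dropped.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- character(0)
  emit <- function(obj, name, format = "tsv") {
    path <- file.path(config$out_dir, paste0(name, ".", format))
    write_report(obj, path, format = format)
    outputs[[name]] <<- path
    counts[[name]] <<- if (is.data.frame(obj)) nrow(obj) else length(obj)
  }

  records <- read_fasta(config$fasta)
  # records without a species annotation stand for themselves
  records$species[is.na(records$species)] <-
    records$id[is.na(records$species)]
  counts$input_records <- nrow(records)

  segments <- segment_records(records, config$ntd_anchor,
                              config$ctd_anchor, config$max_mismatch)
  emit(segments, "segments")

  iso_rows <- lapply(which(segments$ok), function(k) {
    seg <- segment_domains(records$residues[k], config$ntd_anchor,
                           config$ctd_anchor, config$max_mismatch)
    iso <- classify_isoform(seg, records$residues[k],
                            short_threshold = config$short_threshold,
                            ribeye_threshold = config$ribeye_threshold)
    data.frame(id = records$id[k], species = records$species[k],
               form = iso$form, ending_label = iso$ending_label,
               ctd_length = iso$ctd_length,
               ntd_extension = iso$ntd_extension,
               stringsAsFactors = FALSE)
  })
  isoforms <- do.call(rbind, iso_rows)
  emit(isoforms, "isoforms")

  with_ctd <- segments[segments$ok & !is.na(segments$ctd) &
                         nchar(segments$ctd) > 0L, ]
  profiles <- cbind(composition_profile(
    setNames(with_ctd$ctd, with_ctd$id)),
    species = with_ctd$species)
  emit(profiles, "ctd_profiles")

  longest <- select_longest_ctd(with_ctd)
  species_profiles <- cbind(composition_profile(
    setNames(longest$ctd, longest$id)),
    species = longest$species)
  emit(species_profiles, "species_profiles")

  if (!is.null(config$grouping)) {
    grouping <- utils::read.delim(config$grouping,
                                  stringsAsFactors = FALSE)
    emit(aggregate_by_group(species_profiles, grouping),
         "group_summary")
  }

  emit(catalog_endings(records)$calls, "endings")

  sumo <- do.call(rbind, lapply(seq_len(nrow(with_ctd)), function(k) {
    hits <- scan_sumo_sites(with_ctd$ctd[k])
    if (nrow(hits) == 0L) return(NULL)
    cbind(id = with_ctd$id[k], hits)
  }))
  if (is.null(sumo))
    sumo <- data.frame(id = character(0), k_position = integer(0),
                       context = character(0), psi_residue = character(0),
                       alpha_residue = character(0))
  emit(sumo, "sumo_sites")

  if (!is.null(config$msa)) {
    msa <- read_msa(config$msa, config$msa_dialect)
    ann <- annotate_columns(msa)
    emit(ann, "column_classes")
    emit(find_conserved_blocks(ann), "conserved_blocks", format = "json")
  }

  if (!is.null(config$ref1)) {
    ref1 <- read_fasta(config$ref1)[1, ]
    ref2 <- read_fasta(config$ref2)[1, ]
    emit(classify_paralogs(records, ref1, ref2), "paralogs")
  }

  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "grouping", "msa", "ref1", "ref2")])
  manifest <- list(
    tool = "ctdprof",
    version = as.character(utils::packageVersion("ctdprof")),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    row_counts = counts,
    outputs = lapply(outputs, normalizePath))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
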