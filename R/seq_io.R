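#' Read protein (or nucleotide) sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a sequence table. Residues are
#' uppercased and line wraps are joined; a terminal `*` (stop codon mark,
#' common in translated cDNA) is stripped with a message. Record ids are
#' the first whitespace-delimited token of the header; the remainder is
#' kept as the description, and a species name is extracted from a
#' trailing NCBI-style `[Genus species]` bracket when present.
#'
#' @param path Path to a FASTA file.
#' @param moltype Either `"protein"` (alphabet ACDEFGHIKLMNPQRSTVWY plus
#'   `X`) or `"nucleotide"` (ACGTU plus `N`).
#' @return A `data.frame` with columns `id`, `species`, `description`,
#'   `residues` and `moltype`, one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo [Homo sapiens]", "NCVN", "KEYL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("not FASTA-formatted: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("format error: no FASTA records in ", path, call. = FALSE)

  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  species <- ifelse(grepl("\\[[^]]+\\]", desc),
                    sub("^.*\\[([^]]+)\\].*$", "\\1", desc),
                    NA_character_)

  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  residues <- toupper(as.character(set))
  stripped <- grepl("\\*$", residues)
  if (any(stripped)) {
    residues <- sub("\\*+$", "", residues)
    message("stripped terminal '*' from ", sum(stripped), " record(s)")
  }

  records <- data.frame(id = ids, species = species, description = desc,
                        residues = unname(residues), moltype = moltype,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  validate_records(records)
  records
}

#' @keywords internal
validate_records <- function(records) {
  alphabet <- list(protein = c(AA_PROTEIN, "X"),
                   nucleotide = c("A", "C", "G", "T", "U", "N"))
  for (k in seq_len(nrow(records))) {
    r <- records$residues[k]
    if (nchar(r) == 0L)
      stop("record '", records$id[k], "' has an empty sequence",
           call. = FALSE)
    ok <- .chars(r) %in% alphabet[[records$moltype[k]]]
    if (!all(ok))
      stop("illegal character '", .chars(r)[which(!ok)[1]],
           "' at position ", which(!ok)[1], " in record '",
           records$id[k], "'", call. = FALSE)
    if (grepl("\\s", records$id[k]))
      stop("record id contains whitespace: '", records$id[k], "'",
           call. = FALSE)
  }
  invisible(records)
}

#' Write a sequence table to FASTA
#'
#' Inverse of [read_fasta()]: ids and residues round-trip exactly.
#' Gapped rows (alignments) are written as-is.
#'
#' @param records Sequence table as returned by [read_fasta()], or any
#'   data.frame with `id` and `residues` columns.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  # keep the species round-trippable via the NCBI-style bracket
  if ("species" %in% names(records)) {
    add <- !is.na(records$species) & !grepl("\\[", desc)
    desc[add] <- trimws(paste0(desc[add], " [", records$species[add], "]"))
  }
  lines <- unlist(lapply(seq_len(nrow(records)), function(k) {
    hdr <- paste0(">", records$id[k],
                  ifelse(nzchar(desc[k]), paste0(" ", desc[k]), ""))
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", records$residues[k])
    c(hdr, strsplit(body, "\n", fixed = TRUE)[[1]])
  }))
  writeLines(lines, path)
  invisible(path)
}

new_msa <- function(ids, seqs) {
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    bad <- ids[widths != widths[1]][1]
    stop("ragged alignment: row '", bad, "' has ", nchar(seqs[ids == bad][1]),
         " columns, expected ", widths[1], call. = FALSE)
  }
  structure(list(ids = ids, seqs = toupper(unname(seqs)),
                 n_columns = unname(widths[1])),
            class = "ctd_msa")
}

#' @export
print.ctd_msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " rows x ",
      x$n_columns, " columns\n", sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads an MSA either as aligned (gapped) FASTA or in the ClustalW
#' block dialect, reassembling ClustalW blocks into full-length rows.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned_fasta"` or `"clustalw"`.
#' @return An object of class `ctd_msa`: a list with `ids`, gapped
#'   `seqs` and `n_columns`. All rows have equal length.
#' @export
read_msa <- function(path, dialect = c("aligned_fasta", "clustalw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "aligned_fasta") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(set) == 0L)
      stop("format error: no records in ", path, call. = FALSE)
    msa <- new_msa(sub("\\s.*$", "", names(set)), as.character(set))
  } else {
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"),
      error = function(e) stop("cannot parse ClustalW file ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    chr <- as.character(aln)
    msa <- new_msa(names(chr), unname(chr))
  }
  # ungapped rows must be valid protein sequences
  validate_records(data.frame(id = msa$ids, species = NA, description = "",
                              residues = gsub("-", "", msa$seqs, fixed = TRUE),
                              moltype = "protein", stringsAsFactors = FALSE))
  msa
}

#' Write an alignment as aligned FASTA
#'
#' @param msa A `ctd_msa` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "ctd_msa"))
  write_fasta(data.frame(id = msa$ids, residues = msa$seqs,
                         stringsAsFactors = FALSE), path)
}

#' Write a tabular report deterministically
#'
#' Writes rows to TSV or JSON with fixed column order and fixed float
#' formatting (4 decimals in TSV), so identical input always produces
#' byte-identical output.
#'
#' @param rows A data.frame, or a list of named lists sharing one key set.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) {
    if (length(rows) > 0L) {
      keys <- lapply(rows, function(r) sort(names(r)))
      if (!all(vapply(keys, identical, logical(1), y = keys[[1]])))
        stop("inconsistent keys across rows", call. = FALSE)
      rows <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)))
    } else {
      stop("cannot infer columns from an empty list; pass a data.frame",
           call. = FALSE)
    }
  }
  if (format == "tsv") {
    out <- rows
    for (j in seq_along(out)) {
      if (is.double(out[[j]]))
        out[[j]] <- formatC(out[[j]], format = "f", digits = 4)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n",
                       na = "NA")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}
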