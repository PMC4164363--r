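#' Sequence quality control for a COI-5P barcode
#'
#' Checks a nucleotide barcode for the hallmarks of a clean protein-coding
#' mitochondrial fragment: a reading frame free of stop codons (vertebrate
#' mitochondrial code: TAA, TAG, AGA, AGG), a length compatible with the
#' 652 bp COI-5P amplicon, no internal gap characters (a proxy for the
#' absence of insertions/deletions), and a tolerable level of ambiguity
#' symbols.
#'
#' The reading frame is chosen as the frame (0, 1 or 2) minimising the stop
#' codon count, ties going to the lowest frame index. A record passes when
#' the minimal stop count is zero, the length lies in \code{[min_len, max_len]},
#' no internal gaps are present and the fraction of non-ACGT symbols is at
#' most 0.5.
#'
#' @param sequence A single nucleotide string (IUPAC symbols; case ignored).
#' @param min_len,max_len Accepted length range; defaults 500--652.
#' @return A list with elements \code{passed}, \code{reading_frame} (0/1/2 or
#'   \code{NA}), \code{stop_codons} (count in the chosen frame),
#'   \code{length_ok}, \code{ambiguity_fraction} and \code{reason} (a short
#'   code, \code{"ok"} when passed).
#' @examples
#' qc_record(paste(rep("ATGGCA", 100), collapse = ""))$passed
#' @export
qc_record <- function(sequence, min_len = 500L, max_len = 652L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  length_ok <- n >= min_len && n <= max_len
  ambiguity <- mean(!(chars %in% .BASES))
  has_gap <- any(chars == "-")

  if (ambiguity > 0.5) {
    return(list(passed = FALSE, reading_frame = NA_integer_,
                stop_codons = NA_integer_, length_ok = length_ok,
                ambiguity_fraction = ambiguity, reason = "excess_ambiguity"))
  }
  stops <- vapply(0:2, function(f) .count_stops(chars, f), integer(1))
  frame <- which.min(stops) - 1L   # which.min takes the first (lowest) tie
  n_stops <- stops[frame + 1L]

  reason <- if (has_gap) "internal_gap"
    else if (n_stops > 0L) "stop_codons"
    else if (!length_ok) "length"
    else "ok"
  list(passed = identical(reason, "ok"), reading_frame = frame,
       stop_codons = n_stops, length_ok = length_ok,
       ambiguity_fraction = ambiguity, reason = reason)
}

.new_barcode_library <- function(records) {
  rownames(records) <- NULL
  structure(records, class = c("barcode_library", "data.frame"))
}

.validate_records <- function(records) {
  .stopifnot_cols(records, c("specimen_id", "sequence", "species", "genus",
                             "family", "order", "region", "role"), "metadata")
  if (any(duplicated(records$specimen_id)))
    stop("duplicate specimen ids: ",
         paste(unique(records$specimen_id[duplicated(records$specimen_id)]),
               collapse = ", "))
  if (any(!nzchar(records$specimen_id))) stop("empty specimen id")
  if (any(!nzchar(records$sequence))) stop("empty sequence")
  bad_role <- setdiff(unique(records$role), c("reference", "query"))
  if (length(bad_role)) stop("role must be 'reference' or 'query', got: ",
                             paste(bad_role, collapse = ", "))
  # Binomials must be prefixed by their genus ("Genus epithet" or placeholders
  # like "Genus sp.").
  has_sp <- grepl(" ", records$species, fixed = TRUE)
  bad <- has_sp & !startsWith(records$species, paste0(records$genus, " "))
  if (any(bad))
    stop("species binomial inconsistent with genus for: ",
         paste(records$specimen_id[bad], collapse = ", "))
  invisible(records)
}

#' Assemble a barcode library from a records table
#'
#' Normalises fields (sequences upper-cased, region coerced to
#' NEA/MED/OTHER, grade to A--E or "ungraded"), validates invariants
#' (unique non-empty ids, genus/species consistency) and computes per-record
#' QC via [qc_record()].
#'
#' @param records Data frame with columns \code{specimen_id}, \code{sequence},
#'   \code{species}, \code{genus}, \code{family}, \code{order}, \code{region},
#'   \code{role} and optionally \code{grade}.
#' @param min_len,max_len QC length bounds, see [qc_record()].
#' @return A \code{barcode_library}: the records data frame with added QC
#'   columns \code{qc_passed}, \code{qc_frame}, \code{qc_stops},
#'   \code{qc_ambiguity}.
#' @export
barcode_library <- function(records, min_len = 500L, max_len = 652L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$sequence <- toupper(records$sequence)
  records$region <- toupper(trimws(records$region))
  records$region[!(records$region %in% c("NEA", "MED"))] <- "OTHER"
  records$role <- tolower(trimws(records$role))
  if (is.null(records$grade)) records$grade <- "ungraded"
  records$grade[is.na(records$grade) | !(records$grade %in% LETTERS[1:5])] <- "ungraded"
  .validate_records(records)
  qc <- lapply(records$sequence, qc_record, min_len = min_len, max_len = max_len)
  records$qc_passed <- vapply(qc, `[[`, logical(1), "passed")
  records$qc_frame <- vapply(qc, `[[`, integer(1), "reading_frame")
  records$qc_stops <- vapply(qc, `[[`, integer(1), "stop_codons")
  records$qc_ambiguity <- vapply(qc, `[[`, numeric(1), "ambiguity_fraction")
  records$qc_reason <- vapply(qc, `[[`, character(1), "reason")
  .new_barcode_library(records)
}

#' Read a barcode library from FASTA + metadata TSV
#'
#' FASTA ids (first whitespace-delimited token of each header) must resolve
#' 1:1 to the \code{specimen_id} column of the tab-separated metadata table.
#' Records present in only one of the two files are rejected and reported in
#' the \code{"rejected"} attribute; duplicated ids are a hard error.
#'
#' @param fasta_path Path to a FASTA file of barcode sequences.
#' @param metadata_path Path to a TSV with header
#'   \code{specimen_id, species, genus, family, order, region, role[, grade]}.
#' @inheritParams barcode_library
#' @return A \code{barcode_library} (see [barcode_library()]); rejected ids,
#'   if any, in \code{attr(x, "rejected")}.
#' @export
read_library <- function(fasta_path, metadata_path, min_len = 500L, max_len = 652L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (any(duplicated(ids)))
    stop("duplicate ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  .stopifnot_cols(meta, c("specimen_id", "species", "genus", "family",
                          "order", "region", "role"), "metadata TSV")
  if (any(duplicated(meta$specimen_id)))
    stop("duplicate specimen_id in metadata: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  no_meta <- setdiff(ids, meta$specimen_id)
  no_seq <- setdiff(meta$specimen_id, ids)
  keep <- intersect(ids, meta$specimen_id)
  if (length(no_meta) || length(no_seq))
    message("rejected ", length(no_meta) + length(no_seq),
            " record(s) without a FASTA/metadata counterpart")
  meta <- meta[match(keep, meta$specimen_id), , drop = FALSE]
  meta$sequence <- as.character(seqs)[match(keep, ids)]
  lib <- barcode_library(meta, min_len = min_len, max_len = max_len)
  attr(lib, "rejected") <- list(missing_metadata = no_meta,
                                missing_sequence = no_seq)
  lib
}

#' Write a barcode library to FASTA + metadata TSV
#'
#' Emits \code{<prefix>.fasta} and \code{<prefix>_metadata.tsv} in
#' \code{out_dir}; the pair round-trips through [read_library()] to an equal
#' record set. Output is byte-deterministic for a given library.
#'
#' @param library A \code{barcode_library}.
#' @param out_dir Output directory (created if absent).
#' @param prefix File name stem, default \code{"library"}.
#' @return Invisibly, the two file paths.
#' @export
write_library <- function(library, out_dir, prefix = "library") {
  stopifnot(inherits(library, "barcode_library"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fasta <- file.path(out_dir, paste0(prefix, ".fasta"))
  tsv <- file.path(out_dir, paste0(prefix, "_metadata.tsv"))
  dss <- Biostrings::DNAStringSet(library$sequence)
  names(dss) <- library$specimen_id
  Biostrings::writeXStringSet(dss, fasta)
  cols <- c("specimen_id", "species", "genus", "family", "order",
            "region", "role", "grade")
  utils::write.table(as.data.frame(library)[, cols], tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Subset a library by role
#'
#' @param library A \code{barcode_library}.
#' @param role \code{"reference"} or \code{"query"}.
#' @param qc_passed_only Drop records failing QC (default TRUE).
#' @return A \code{barcode_library} restricted to the requested role.
#' @export
subset_role <- function(library, role = c("reference", "query"),
                        qc_passed_only = TRUE) {
  role <- match.arg(role)
  keep <- library$role == role
  if (qc_passed_only) keep <- keep & library$qc_passed
  .new_barcode_library(as.data.frame(library)[keep, , drop = FALSE])
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x), "records,",
      length(unique(x$species)), "species;",
      sum(x$role == "reference"), "reference /",
      sum(x$role == "query"), "query;",
      sum(x$qc_passed), "QC-passed\n")
  invisible(x)
}
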