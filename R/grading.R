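#' External concordance table against a snapshot library
#'
#' Compares each reference species against a local snapshot of published
#' barcodes (stand-in for a live identification-engine query, which is not
#' reproducible offline). For every species the best identity hit across its
#' specimens is retained; specimens whose own best-hit species disagrees
#' with the species-level match are counted as outliers.
#'
#' @param library A \code{barcode_library} (the reference records).
#' @param snapshot A \code{barcode_library} or data frame with
#'   \code{species} and \code{sequence} columns (the external candidates).
#' @param min_coverage Minimum compared fraction of the barcode, see
#'   [identity_search()].
#' @return Data frame: \code{species}, \code{matched_species},
#'   \code{identity} (percent), \code{n_specimen_outliers}.
#' @export
external_match_table <- function(library, snapshot, min_coverage = 0.95) {
  recs <- as.data.frame(library)
  out <- lapply(sort(unique(recs$species)), function(sp) {
    rows <- recs[recs$species == sp, , drop = FALSE]
    per_spec <- lapply(rows$sequence, function(s)
      identity_search(s, snapshot, min_coverage = min_coverage)[1, , drop = FALSE])
    best <- do.call(rbind, per_spec)
    top <- which.max(best$identity)
    data.frame(species = sp,
               matched_species = best$species[top],
               identity = best$identity[top],
               n_specimen_outliers = sum(best$species != best$species[top]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Grade reference species A--E
#'
#' Assigns each reference species a reliability grade following the ranking
#' logic of curated fish barcode libraries:
#' \itemize{
#'   \item \strong{E} -- discordant: the external match names a different
#'     species, or the species is para-/polyphyletic on the reference tree.
#'   \item \strong{C} -- intraspecific divergence above \code{grade_threshold}
#'     observed among at least 3 specimens.
#'   \item \strong{A} -- concordant external match at \code{identity_floor}
#'     or better, with intraspecific divergence within the threshold.
#'   \item \strong{B} -- internal concordance among at least 3 specimens,
#'     no external corroboration available.
#'   \item \strong{D} -- 1--2 specimens and no external match (species with
#'     exactly two specimens above the threshold are D with a
#'     \code{deep_divergence_low_n} rationale, since the deep-divergence
#'     clause requires three specimens).
#' }
#' Precedence is E > C > A > B > D; discordance overrides sample size.
#'
#' @param library Reference \code{barcode_library}.
#' @param dm \code{k2p_dist} covering every reference specimen (error
#'   otherwise).
#' @param monophyly Output of [species_monophyly()] on the reference tree,
#'   or \code{NULL} (monophyly then not assessed).
#' @param external_matches Output of [external_match_table()], or \code{NULL}
#'   when no snapshot is available.
#' @param grade_threshold Intraspecific divergence ceiling, default 0.02;
#'   the grading rule uses "<=" (a maximum of 2\% is still concordant).
#' @param identity_floor Identity (percent) required for external
#'   concordance, default 98.
#' @return Data frame of class \code{grade_table}: \code{species},
#'   \code{grade}, \code{n_specimens}, \code{max_intra_pct},
#'   \code{rationale}.
#' @export
grade_library <- function(library, dm, monophyly = NULL,
                          external_matches = NULL,
                          grade_threshold = 0.02, identity_floor = 98) {
  recs <- as.data.frame(library)
  recs <- recs[recs$qc_passed, , drop = FALSE]
  missing <- setdiff(recs$specimen_id, dm$ids)
  if (length(missing))
    stop("specimens absent from distance matrix: ",
         paste(missing, collapse = ", "))
  species <- sort(unique(recs$species))
  rows <- lapply(species, function(sp) {
    ids <- recs$specimen_id[recs$species == sp]
    n <- length(ids)
    max_intra <- .max_within(dm$d, ids)   # 0 for singletons
    ext <- if (!is.null(external_matches))
      external_matches[external_matches$species == sp, , drop = FALSE]
    ext_ok <- !is.null(ext) && nrow(ext) == 1L && ext$identity >= identity_floor
    ext_concordant <- ext_ok && ext$matched_species == sp
    ext_discordant <- ext_ok && ext$matched_species != sp
    mono <- if (!is.null(monophyly)) {
      st <- monophyly$status[monophyly$species == sp]
      if (length(st)) st else "not_evaluable"
    } else "not_evaluable"
    deep <- !is.na(max_intra) && max_intra > grade_threshold

    if (ext_discordant || identical(mono, "non_monophyletic")) {
      g <- "E"
      why <- if (ext_discordant) "external_discordance" else "non_monophyly"
    } else if (deep && n >= 3L) {
      g <- "C"; why <- "deep_divergence"
    } else if (deep) {
      g <- "D"; why <- "deep_divergence_low_n"
    } else if (ext_concordant) {
      g <- "A"; why <- "external_concordance"
    } else if (n >= 3L) {
      g <- "B"; why <- "internal_concordance"
    } else {
      g <- "D"; why <- "low_sampling"
    }
    data.frame(species = sp, grade = g, n_specimens = n,
               max_intra_pct = 100 * max_intra, rationale = why,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grade_table", "data.frame")
  out
}
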