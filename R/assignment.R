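#' Provisional assignment of queries by cluster membership
#'
#' Implements the first stage of the blind protocol: a query is assigned to
#' a reference species iff it sits inside a low-divergence monophyletic
#' cluster (from [extract_clusters()] on the merged reference+query tree)
#' whose reference members all carry that one species name. Clusters without
#' reference members -- including single-entry clusters -- leave the query
#' unassigned (a candidate first-time barcode); clusters whose reference
#' members span several species yield an ambiguous call.
#'
#' @param query_ids Character vector of query specimen ids (must all be in
#'   some cluster, i.e. on the merged tree).
#' @param clusters A \code{barcode_clusters} over the merged tree.
#' @param taxonomy Data frame with \code{specimen_id}, \code{species},
#'   \code{role} for the reference records (query rows may be present with
#'   \code{NA} species; they are ignored as donors).
#' @return Data frame: \code{query_id}, \code{status} in
#'   \code{"assigned"/"ambiguous"/"unassigned"}, \code{assigned_species},
#'   \code{cluster_id}.
#' @export
assign_by_cluster <- function(query_ids, clusters, taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  ref_ids <- taxonomy$specimen_id[taxonomy$role == "reference"]
  by_member <- stats::setNames(
    rep(seq_along(clusters), vapply(clusters, function(cl)
      length(cl$member_ids), integer(1))),
    unlist(lapply(clusters, `[[`, "member_ids")))
  rows <- lapply(query_ids, function(q) {
    k <- by_member[[q]]
    if (is.null(k)) stop("query '", q, "' absent from the cluster partition")
    cl <- clusters[[k]]
    ref_members <- intersect(cl$member_ids, ref_ids)
    if (cl$is_single_entry || !length(ref_members)) {
      status <- "unassigned"; sp <- NA_character_
    } else {
      ref_sp <- unique(taxonomy$species[match(ref_members,
                                              taxonomy$specimen_id)])
      ref_sp <- ref_sp[!is.na(ref_sp)]
      if (length(ref_sp) == 1L) {
        status <- "assigned"; sp <- ref_sp
      } else if (length(ref_sp) == 0L) {
        status <- "unassigned"; sp <- NA_character_
      } else {
        status <- "ambiguous"; sp <- NA_character_
      }
    }
    data.frame(query_id = q, status = status, assigned_species = sp,
               cluster_id = cl$cluster_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Identity search against a candidate library
#'
#' Second-stage fallback: percent identity of the query against every
#' candidate, computed over compared positions (both unambiguous) after an
#' end-gap-free global alignment when lengths differ. Hits are aggregated to
#' the best hit per candidate species and returned sorted by identity
#' (ties by species name, for determinism); hits below the identity or
#' coverage floors are retained but marked as non-passing.
#'
#' @param query A nucleotide string.
#' @param candidates A \code{barcode_library} or data frame with
#'   \code{species} and \code{sequence} columns; must be non-empty.
#' @param min_identity Identity floor in percent, default 98.
#' @param min_coverage Minimum fraction of \code{barcode_len} compared,
#'   default 0.95 ("whole length of the barcode").
#' @param barcode_len Nominal barcode length, default 652.
#' @return Data frame: \code{species}, \code{identity} (percent),
#'   \code{coverage}, \code{passes}.
#' @export
identity_search <- function(query, candidates, min_identity = 98,
                            min_coverage = 0.95, barcode_len = 652L) {
  cand <- as.data.frame(candidates)
  .stopifnot_cols(cand, c("species", "sequence"), "candidate library")
  if (!nrow(cand)) stop("candidate library is empty")
  q <- toupper(query)
  score_one <- function(s) {
    cp <- count_site_patterns(q, s)
    mism <- cp$transitions + cp$transversions
    c(identity = if (cp$n_compared > 0)
        100 * (cp$n_compared - mism) / cp$n_compared else 0,
      coverage = cp$n_compared / barcode_len)
  }
  sc <- t(vapply(cand$sequence, score_one, c(identity = 0, coverage = 0)))
  rownames(sc) <- NULL
  hits <- data.frame(species = cand$species, identity = sc[, "identity"],
                     coverage = sc[, "coverage"], stringsAsFactors = FALSE)
  # best hit per species
  hits <- hits[order(-hits$identity, -hits$coverage, hits$species), ]
  hits <- hits[!duplicated(hits$species), , drop = FALSE]
  hits$passes <- hits$identity >= min_identity & hits$coverage >= min_coverage
  rownames(hits) <- NULL
  hits
}

#' Classify a query's final outcome
#'
#' Combines the cluster-stage provisional call, the fallback identity hits
#' and the (previously hidden) morphology label into one of five outcomes:
#' \code{confirmed} (assignment equals morphology), \code{mismatch}
#' (assignment differs), \code{ambiguous} (mixed-species cluster, or several
#' species exactly tied at the top identity), \code{new_record} (fallback
#' searched, nothing at or above the identity floor: a first-time barcode,
#' morphology retained), \code{no_match} (unassigned and no fallback
#' candidates were available).
#'
#' @param provisional One row of [assign_by_cluster()] output.
#' @param hits [identity_search()] output for this query, or \code{NULL}
#'   when no fallback search was run.
#' @param morphology_species The specimen's morphology-based label.
#' @return One-row data frame: \code{query_id}, \code{outcome},
#'   \code{assigned_species}, \code{morphology_species}, \code{evidence},
#'   \code{best_identity}.
#' @export
classify_outcome <- function(provisional, hits = NULL, morphology_species) {
  q <- provisional$query_id
  finish <- function(outcome, sp, evidence, ident = NA_real_) {
    data.frame(query_id = q, outcome = outcome, assigned_species = sp,
               morphology_species = morphology_species, evidence = evidence,
               best_identity = ident, stringsAsFactors = FALSE)
  }
  if (provisional$status == "assigned") {
    sp <- provisional$assigned_species
    out <- if (identical(sp, morphology_species)) "confirmed" else "mismatch"
    return(finish(out, sp, paste0("cluster:", provisional$cluster_id)))
  }
  if (provisional$status == "ambiguous")
    return(finish("ambiguous", NA_character_,
                  paste0("cluster:", provisional$cluster_id)))
  # unassigned by the cluster rule
  if (is.null(hits) || !nrow(hits))
    return(finish("no_match", NA_character_, "no_candidates"))
  passing <- hits[hits$passes, , drop = FALSE]
  best <- hits[1, ]
  ev <- sprintf("identity:%s(%.1f%%)", best$species, best$identity)
  if (!nrow(passing))
    return(finish("new_record", NA_character_, ev, best$identity))
  top <- passing[passing$identity == passing$identity[1], , drop = FALSE]
  if (length(unique(top$species)) > 1L)
    return(finish("ambiguous", NA_character_, ev, best$identity))
  sp <- top$species[1]
  out <- if (identical(sp, morphology_species)) "confirmed" else "mismatch"
  finish(out, sp, ev, top$identity[1])
}

#' Flag species with deep intraspecific divergence
#'
#' Screens every species with at least two specimens for a maximum
#' intraspecific K2P distance above \code{threshold} (the >2\% rule). For
#' flagged species the number of sub-clusters (the cluster partition
#' restricted to the species' specimens) is reported, together with whether
#' the sub-clusters sort geographically: every sub-cluster pure for one
#' region and not all sub-clusters from the same region. The mean distance
#' between specimens of different sub-clusters is also emitted, so both the
#' maximum-intraspecific and the between-lineage readings of a split are
#' checkable.
#'
#' @param library A \code{barcode_library} (reference, query or merged).
#' @param dm \code{k2p_dist} covering the library's specimens.
#' @param clusters \code{barcode_clusters} over the same specimens.
#' @param threshold Flagging threshold, default 0.02; strict ">".
#' @return Data frame: \code{species}, \code{n}, \code{max_intra_pct},
#'   \code{n_subclusters}, \code{geographic_sorting},
#'   \code{between_subcluster_mean_pct}.
#' @export
flag_deep_divergences <- function(library, dm, clusters, threshold = 0.02) {
  recs <- as.data.frame(library)
  recs <- recs[recs$specimen_id %in% dm$ids, , drop = FALSE]
  by_member <- stats::setNames(
    rep(seq_along(clusters), vapply(clusters, function(cl)
      length(cl$member_ids), integer(1))),
    unlist(lapply(clusters, `[[`, "member_ids")))
  out <- lapply(sort(unique(recs$species)), function(sp) {
    rows <- recs[recs$species == sp, , drop = FALSE]
    if (nrow(rows) < 2L) return(NULL)
    mx <- .max_within(dm$d, rows$specimen_id)
    if (is.na(mx) || mx <= threshold) return(NULL)
    sub <- by_member[rows$specimen_id]
    k <- length(unique(sub))
    pure <- all(vapply(split(rows$region, sub),
                       function(r) length(unique(r)) == 1L, logical(1)))
    sub_regions <- vapply(split(rows$region, sub), `[`, character(1), 1L)
    geo <- pure && length(unique(sub_regions)) > 1L
    between <- {
      d <- dm$d[rows$specimen_id, rows$specimen_id, drop = FALSE]
      cross <- outer(sub, sub, "!=") & upper.tri(d)
      v <- d[cross]
      if (length(v)) mean(v, na.rm = TRUE) * 100 else NA_real_
    }
    data.frame(species = sp, n = nrow(rows), max_intra_pct = 100 * mx,
               n_subclusters = k, geographic_sorting = geo,
               between_subcluster_mean_pct = between,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(species = character(0), n = integer(0),
                      max_intra_pct = numeric(0), n_subclusters = integer(0),
                      geographic_sorting = logical(0),
                      between_subcluster_mean_pct = numeric(0))
  res
}
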