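#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard Saitou--Nei neighbour joining (via \pkg{ape}). The input matrix
#' may not contain undefined entries: callers must prune saturated pairs
#' first (the offending pair is named in the error). Negative branch lengths
#' occasionally produced by NJ are clamped to zero, the deficit being moved
#' onto a sibling branch so that path lengths through the parent node are
#' preserved.
#'
#' @param dm A \code{k2p_dist} from [distance_matrix()], or a symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted \code{phylo} tree whose tips are the matrix ids.
#' @export
build_nj <- function(dm) {
  d <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  if (is.null(rownames(d))) stop("distance matrix must have dimnames")
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("undefined distance between '", rownames(d)[bad[1]], "' and '",
         rownames(d)[bad[2]], "'; prune undefined pairs before NJ")
  }
  if (nrow(d) < 3L) stop("need at least 3 leaves")
  tree <- ape::nj(stats::as.dist(d))
  .clamp_negative_edges(tree)
}

# Clamp negative branch lengths to 0, transferring the deficit to a sibling
# edge (another edge sharing the same parent node) to preserve path lengths.
.clamp_negative_edges <- function(tree) {
  for (iter in seq_len(2L * nrow(tree$edge))) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) tree$edge.length[sib[1]] <-
        tree$edge.length[sib[1]] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for NJ bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate (K2P distances) and reports, for every non-trivial bipartition
#' of the original tree, the percentage of replicates containing it.
#' Deterministic for a fixed \code{seed}. In replicates where a resampled
#' pair becomes K2P-undefined, the entry is capped at twice the largest
#' defined replicate distance so that the tree remains buildable.
#'
#' @param alignment Named character vector of aligned (equal-length)
#'   sequences, or a \code{barcode_library}.
#' @param n_reps Number of bootstrap replicates (>= 1; the field standard is
#'   1000).
#' @param seed Optional integer seed.
#' @param min_overlap Passed to the per-replicate distance computation.
#' @return List with \code{tree} (the original NJ tree, node labels carrying
#'   supports) and \code{support}, a data frame of bipartitions (tip labels,
#'   ";"-separated) and support percentages in [0, 100].
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = NULL,
                              min_overlap = 100) {
  if (inherits(alignment, "barcode_library"))
    alignment <- stats::setNames(alignment$sequence, alignment$specimen_id)
  stopifnot(n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sm <- .seq_char_matrix(alignment)
  if (ncol(sm) < 2L) stop("alignment must have at least 2 columns")
  base_d <- .k2p_from_char_matrix(sm, min_overlap)
  if (anyNA(base_d)) stop("undefined distance in the full alignment")
  tree <- build_nj(base_d)
  splits <- .tree_splits(tree)
  hits <- stats::setNames(numeric(length(splits)), splits)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(sm), ncol(sm), replace = TRUE)
    d <- .k2p_from_char_matrix(sm[, cols, drop = FALSE], min_overlap)
    if (anyNA(d)) {
      cap <- 2 * max(d, na.rm = TRUE)
      d[is.na(d)] <- cap
      diag(d) <- 0
    }
    rep_splits <- .tree_splits(build_nj(d))
    found <- splits %in% rep_splits
    hits[found] <- hits[found] + 1
  }
  support <- 100 * hits / n_reps
  # attach to node labels for Newick export
  labelled <- tree
  labelled$node.label <- rep("", tree$Nnode)
  pp <- ape::prop.part(labelled)
  labs <- attr(pp, "labels")
  for (k in seq_along(pp)) {
    enc <- .canonical_split(labs[pp[[k]]], labs)
    if (enc %in% names(support))
      labelled$node.label[k] <- format(round(support[[enc]]))
  }
  list(tree = labelled,
       support = data.frame(
         bipartition = vapply(strsplit(names(support), "\r", fixed = TRUE),
                              paste, character(1), collapse = ";"),
         support = as.numeric(support),
         stringsAsFactors = FALSE))
}

# K2P matrix straight from a character matrix (internal, used by bootstrap).
.k2p_from_char_matrix <- function(sm, min_overlap = 100) {
  ind <- .base_indicators(sm)
  names(ind) <- .BASES
  valid <- ind$A + ind$C + ind$G + ind$T
  n_comp <- tcrossprod(valid)
  matches <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  tv <- n_comp - matches - ts
  P <- ts / n_comp; Q <- tv / n_comp
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- -0.5 * log(w1 * sqrt(w2))
  d[w1 <= 0 | w2 <= 0 | n_comp < min_overlap] <- NA_real_
  d[!is.na(d) & d < 0] <- 0   # floating round-off; K2P is non-negative
  d <- d + 0                  # normalizes IEEE negative zero
  diag(d) <- 0
  dimnames(d) <- dimnames(tcrossprod(valid))
  rownames(d) <- colnames(d) <- rownames(sm)
  d
}

#' Extract monophyletic low-divergence clusters
#'
#' Partitions the tree's leaves into maximal clades (bipartition sides, plus
#' the full leaf set) whose within-clade maximum pairwise K2P distance is
#' strictly below \code{threshold}. Leaves not absorbed by any qualifying
#' clade become single-entry clusters. Candidate clades are taken in
#' decreasing size (ties broken by the lexicographically smallest member) so
#' that no accepted cluster has a qualifying parent clade.
#'
#' @param tree A \code{phylo} whose tips are a subset of the matrix ids.
#' @param dm A \code{k2p_dist} (or distance matrix) covering the tips.
#' @param threshold Divergence ceiling, default 0.02 (2\%); strict "<".
#' @param taxonomy Optional data frame (\code{specimen_id}, \code{species})
#'   used to fill the species composition of each cluster; specimens with
#'   \code{NA} species (e.g. blinded queries) are counted separately.
#' @return Object of class \code{barcode_clusters}: a list of clusters, each
#'   with \code{cluster_id}, \code{member_ids}, \code{species_composition},
#'   \code{max_within}, \code{is_single_entry}, \code{consensus_species}.
#' @export
extract_clusters <- function(tree, dm, threshold = 0.02, taxonomy = NULL) {
  d <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  labs <- tree$tip.label
  if (!all(labs %in% rownames(d))) stop("tree leaves missing from matrix")
  clades <- .tree_clades(tree)
  n <- length(labs)
  # bipartition sides: every clade and its complement; plus the full set
  sides <- c(clades, lapply(clades, function(s) setdiff(labs, s)))
  sides <- sides[vapply(sides, length, integer(1)) > 0L]
  sides <- unique(lapply(sides, sort))
  mw <- vapply(sides, function(s) .max_within(d, s), numeric(1))
  qual <- !is.na(mw) & (mw < threshold | vapply(sides, length, integer(1)) == 1L)
  sides <- sides[qual]; mw <- mw[qual]
  ord <- order(-vapply(sides, length, integer(1)),
               vapply(sides, `[`, character(1), 1L))
  sides <- sides[ord]; mw <- mw[ord]
  taken <- character(0)
  clusters <- list()
  for (k in seq_along(sides)) {
    s <- sides[[k]]
    if (any(s %in% taken)) next
    clusters[[length(clusters) + 1L]] <- list(member_ids = s, max_within = mw[k])
    taken <- c(taken, s)
  }
  for (leaf in setdiff(labs, taken))
    clusters[[length(clusters) + 1L]] <- list(member_ids = leaf, max_within = 0)
  # stable ordering: by smallest member id
  clusters <- clusters[order(vapply(clusters, function(cl) cl$member_ids[1],
                                    character(1)))]
  out <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    comp <- NULL
    consensus <- NA_character_
    if (!is.null(taxonomy)) {
      sp <- taxonomy$species[match(cl$member_ids, taxonomy$specimen_id)]
      comp <- table(sp, useNA = "ifany")
      known <- unique(sp[!is.na(sp)])
      if (length(known) == 1L && !anyNA(sp)) consensus <- known
    }
    list(cluster_id = sprintf("CL%04d", k), member_ids = cl$member_ids,
         species_composition = comp, max_within = cl$max_within,
         is_single_entry = length(cl$member_ids) == 1L,
         consensus_species = consensus)
  })
  structure(out, class = "barcode_clusters", threshold = threshold)
}

#' @export
print.barcode_clusters <- function(x, ...) {
  cat("barcode_clusters:", length(x), "clusters (<",
      100 * attr(x, "threshold"), "% rule);",
      sum(vapply(x, `[[`, logical(1), "is_single_entry")), "single-entry\n")
  invisible(x)
}

#' Tabulate clusters
#'
#' @param x A \code{barcode_clusters} object.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return Data frame: cluster id, size, members, max within-cluster
#'   distance (percent), single-entry flag, consensus species.
#' @method as.data.frame barcode_clusters
#' @export
as.data.frame.barcode_clusters <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(cl) {
    data.frame(cluster_id = cl$cluster_id, n = length(cl$member_ids),
               members = paste(cl$member_ids, collapse = ";"),
               max_within_pct = 100 * cl$max_within,
               single_entry = cl$is_single_entry,
               consensus_species = cl$consensus_species,
               stringsAsFactors = FALSE)
  }))
}

#' Species monophyly on an unrooted tree
#'
#' A species with at least two specimens on the tree is monophyletic iff its
#' specimen set equals one side of a tree bipartition (trivial sides
#' included). Singletons -- and species whose specimens span the whole tree
#' -- are not informative and are marked accordingly.
#'
#' @param tree A \code{phylo}.
#' @param taxonomy Data frame with \code{specimen_id} and \code{species}.
#' @return Data frame: \code{species}, \code{n_tips}, \code{status} in
#'   \code{"monophyletic"}, \code{"non_monophyletic"}, \code{"not_evaluable"}.
#' @export
species_monophyly <- function(tree, taxonomy) {
  labs <- tree$tip.label
  taxonomy <- as.data.frame(taxonomy)
  sp <- taxonomy$species[match(labs, taxonomy$specimen_id)]
  sides <- unique(vapply(.tree_clades(tree), .canonical_split, character(1),
                         all_labels = labs))
  out <- lapply(sort(unique(sp[!is.na(sp)])), function(s) {
    members <- labs[!is.na(sp) & sp == s]
    status <- if (length(members) < 2L) "not_evaluable"
      else if (length(members) == length(labs)) "monophyletic"
      else if (.canonical_split(members, labs) %in% sides) "monophyletic"
      else "non_monophyletic"
    data.frame(species = s, n_tips = length(members), status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
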