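#' Site-pattern counts between two sequences
#'
#' Counts the sites usable for a Kimura 2-parameter comparison under pairwise
#' deletion: positions where both sequences carry an unambiguous A/C/G/T.
#' Differences are split into transitions (A<->G, C<->T) and transversions
#' (all other changes). Sequences of unequal length are first placed on a
#' common coordinate by an end-gap-free global (overlap) alignment.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param align Align first when lengths differ (default TRUE); with
#'   \code{align = FALSE} unequal lengths are an error.
#' @return List with \code{n_compared}, \code{transitions}, \code{transversions}.
#' @examples
#' count_site_patterns("ACGT", "GCGA")  # 1 transition, 1 transversion
#' @export
count_site_patterns <- function(seq_a, seq_b, align = TRUE) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (nchar(a) != nchar(b)) {
    if (!align) stop("sequences differ in length and align = FALSE")
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b),
                                        type = "overlap")
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% .BASES & cb %in% .BASES
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  purine <- c("A", "G")
  is_ts <- diff & ((ca %in% purine) == (cb %in% purine))
  list(n_compared = sum(ok),
       transitions = sum(is_ts),
       transversions = sum(diff & !is_ts))
}

#' Kimura 2-parameter distance from site-pattern counts
#'
#' Evaluates \eqn{d = -\frac{1}{2}\ln[(1-2P-Q)\sqrt{1-2Q}]} with
#' \eqn{P} the transition and \eqn{Q} the transversion proportion. The
#' distance is undefined -- returned as \code{NA} -- when fewer than
#' \code{min_overlap} sites were compared or when the logarithm's argument is
#' non-positive, i.e. \eqn{1-2P-Q \le 0} or \eqn{1-2Q \le 0} (saturation).
#'
#' @param counts A list as returned by [count_site_patterns()], or a number
#'   of compared sites (then give \code{transitions}/\code{transversions}).
#' @param transitions,transversions Counts, used when \code{counts} is numeric.
#' @param min_overlap Minimum compared sites for a defined distance
#'   (default 100).
#' @return Non-negative distance (substitutions/site), or \code{NA_real_}
#'   when undefined.
#' @examples
#' k2p(count_site_patterns("ACGT", "ACGT"), min_overlap = 1)  # 0
#' @export
k2p <- function(counts, transitions = NULL, transversions = NULL,
                min_overlap = 100) {
  if (is.list(counts)) {
    n <- counts$n_compared; ts <- counts$transitions; tv <- counts$transversions
  } else {
    n <- counts; ts <- transitions; tv <- transversions
  }
  if (is.na(n) || n < min_overlap) return(NA_real_)
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

#' Pairwise K2P distance matrix for a library
#'
#' Computes all unordered pairwise K2P distances among QC-passed records,
#' under pairwise deletion of ambiguous sites. Sequences must share a common
#' coordinate (equal length); undefined pairs (saturated or with fewer than
#' \code{min_overlap} comparable sites) are carried as \code{NA} entries and
#' listed in \code{undefined_pairs}.
#'
#' @param library A \code{barcode_library}, or a named character vector of
#'   aligned sequences.
#' @param min_overlap Passed to [k2p()].
#' @param qc_passed_only For a library input, use QC-passed records only.
#' @return An object of class \code{k2p_dist}: list with \code{ids},
#'   \code{d} (symmetric matrix, proportion scale, \code{NA} = undefined)
#'   and \code{undefined_pairs} (two-column character matrix).
#' @export
distance_matrix <- function(library, min_overlap = 100, qc_passed_only = TRUE) {
  if (inherits(library, "barcode_library")) {
    recs <- as.data.frame(library)
    if (qc_passed_only) recs <- recs[recs$qc_passed, , drop = FALSE]
    seqs <- stats::setNames(recs$sequence, recs$specimen_id)
  } else {
    seqs <- library
    if (is.null(names(seqs))) stop("sequences must be named")
  }
  if (length(seqs) < 2L) stop("need at least 2 QC-passed records")
  sm <- .seq_char_matrix(seqs)
  ind <- .base_indicators(sm)
  names(ind) <- .BASES
  valid <- ind$A + ind$C + ind$G + ind$T
  n_comp <- tcrossprod(valid)
  matches <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  tv <- n_comp - matches - ts
  P <- ts / n_comp
  Q <- tv / n_comp
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- -0.5 * log(w1 * sqrt(w2))
  d[w1 <= 0 | w2 <= 0 | n_comp < min_overlap | !is.finite(n_comp)] <- NA_real_
  d[!is.na(d) & d < 0] <- 0   # floating round-off; K2P is non-negative
  d <- d + 0                  # normalizes IEEE negative zero
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  undefined_pairs <- cbind(names(seqs)[und[, 1]], names(seqs)[und[, 2]])
  structure(list(ids = names(seqs), d = d, undefined_pairs = undefined_pairs),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("k2p_dist over", length(x$ids), "specimens;",
      nrow(x$undefined_pairs), "undefined pair(s)\n")
  invisible(x)
}

.pair_level <- function(taxonomy, ids) {
  tx <- taxonomy[match(ids, taxonomy$specimen_id), , drop = FALSE]
  n <- length(ids)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  same_sp <- tx$species[i] == tx$species[j]
  same_ge <- tx$genus[i] == tx$genus[j]
  same_fa <- tx$family[i] == tx$family[j]
  level <- rep(NA_character_, length(i))
  level[same_fa & !same_ge] <- "confamilial"
  level[same_ge & !same_sp] <- "congeneric"
  level[same_sp] <- "conspecific"
  data.frame(i = i, j = j, level = level, stringsAsFactors = FALSE)
}

#' Distance summaries per taxonomic rank
#'
#' Summarises pairwise K2P distances at the conspecific (same species),
#' congeneric (same genus, different species) and confamilial (same family,
#' different genus) levels, on the percent scale. Undefined pairs are
#' excluded; levels with no pairs are omitted. The standard error is the
#' sample standard deviation of the pair distances divided by the square
#' root of the number of pairs.
#'
#' @param dm A \code{k2p_dist} from [distance_matrix()].
#' @param taxonomy Data frame with \code{specimen_id}, \code{species},
#'   \code{genus}, \code{family} (and \code{grade} when subsetting); a
#'   \code{barcode_library} works directly.
#' @param subset \code{"all"} or \code{"AB"} (restrict to specimens of
#'   grade-A/B species before pairing).
#' @return Data frame with one row per level: \code{level}, \code{n_pairs},
#'   \code{min_pct}, \code{mean_pct}, \code{se_pct}, \code{max_pct}.
#' @export
summarize_ranks <- function(dm, taxonomy, subset = c("all", "AB")) {
  subset <- match.arg(subset)
  taxonomy <- as.data.frame(taxonomy)
  .stopifnot_cols(taxonomy, c("specimen_id", "species", "genus", "family"),
                  "taxonomy")
  ids <- intersect(dm$ids, taxonomy$specimen_id)
  if (subset == "AB") {
    .stopifnot_cols(taxonomy, "grade", "taxonomy (subset = 'AB')")
    ok <- taxonomy$specimen_id[taxonomy$grade %in% c("A", "B")]
    ids <- intersect(ids, ok)
  }
  d <- dm$d[ids, ids, drop = FALSE]
  pl <- .pair_level(taxonomy, ids)
  pl$dist <- d[cbind(pl$i, pl$j)]
  pl <- pl[!is.na(pl$level) & !is.na(pl$dist), , drop = FALSE]
  out <- lapply(c("conspecific", "congeneric", "confamilial"), function(lv) {
    v <- pl$dist[pl$level == lv] * 100
    if (!length(v)) return(NULL)
    data.frame(level = lv, n_pairs = length(v), min_pct = min(v),
               mean_pct = mean(v),
               se_pct = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               max_pct = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-species and per-genus divergence profiles
#'
#' For each species: specimen count, maximum and mean intraspecific K2P
#' distance (percent); species with fewer than two specimens are marked not
#' evaluable. For each genus with congeneric pairs: minimum, mean and
#' maximum congeneric distance.
#'
#' @inheritParams summarize_ranks
#' @return List of two data frames, \code{species} and \code{genus}.
#' @export
species_divergence_profile <- function(dm, taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  ids <- intersect(dm$ids, taxonomy$specimen_id)
  d <- dm$d[ids, ids, drop = FALSE]
  pl <- .pair_level(taxonomy, ids)
  pl$dist <- d[cbind(pl$i, pl$j)]
  tx <- taxonomy[match(ids, taxonomy$specimen_id), ]
  sp_tab <- lapply(sort(unique(tx$species)), function(sp) {
    members <- which(tx$species == sp)
    rows <- pl$level %in% "conspecific" & tx$species[pl$i] == sp
    v <- pl$dist[rows]
    v <- v[!is.na(v)]
    data.frame(species = sp, n = length(members),
               evaluable = length(members) >= 2L,
               max_intra_pct = if (length(v)) max(v) * 100 else NA_real_,
               mean_intra_pct = if (length(v)) mean(v) * 100 else NA_real_,
               stringsAsFactors = FALSE)
  })
  ge_tab <- lapply(sort(unique(tx$genus)), function(g) {
    rows <- pl$level %in% "congeneric" & tx$genus[pl$i] == g
    v <- pl$dist[rows]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(genus = g, n_pairs = length(v), min_pct = min(v) * 100,
               mean_pct = mean(v) * 100, max_pct = max(v) * 100,
               stringsAsFactors = FALSE)
  })
  list(species = do.call(rbind, sp_tab), genus = do.call(rbind, ge_tab))
}
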