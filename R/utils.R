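# Internal helpers shared across modules.

# Stop codons of the vertebrate mitochondrial genetic code.
.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

.BASES <- c("A", "C", "G", "T")

# Split equal-length sequences into an n x L character matrix.
.seq_char_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must have equal length; align them first ",
         "(lengths observed: ", paste(sort(L), collapse = ", "), ")")
  mat <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(mat) <- names(seqs)
  mat
}

# 0/1 indicator matrices (n x L) for each unambiguous base.
.base_indicators <- function(seq_mat) {
  lapply(.BASES, function(b) {
    m <- (seq_mat == b)
    storage.mode(m) <- "double"
    m
  })
}

# Codons of `seq_chars` (character vector of bases) in reading frame `frame`
# (0, 1 or 2); incomplete trailing codon dropped.
.codons <- function(seq_chars, frame = 0L) {
  n <- length(seq_chars)
  start <- frame + 1L
  n_codons <- (n - frame) %/% 3L
  if (n_codons <= 0L) return(character(0))
  idx <- start + 3L * (seq_len(n_codons) - 1L)
  paste0(seq_chars[idx], seq_chars[idx + 1L], seq_chars[idx + 2L])
}

.count_stops <- function(seq_chars, frame = 0L) {
  sum(.codons(seq_chars, frame) %in% .MITO_STOPS)
}

# Canonical encoding of one side of a bipartition over `all_labels`:
# the side not containing the alphabetically first label, members sorted.
.canonical_split <- function(side_labels, all_labels) {
  anchor <- min(all_labels)
  if (anchor %in% side_labels)
    side_labels <- setdiff(all_labels, side_labels)
  paste(sort(side_labels), collapse = "\r")
}

# All clades (tip-label sets of one side of each edge) of an unrooted phylo,
# including singletons; the full tip set is appended as a pseudo-clade so
# that a library whose members all coalesce below threshold forms one cluster.
.tree_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  clades <- lapply(pp, function(i) labs[i])
  singles <- as.list(labs)
  c(clades, singles)
}

# Canonical non-trivial bipartitions of a tree (as encoded strings).
.tree_splits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  clades <- .tree_clades(tree)
  keep <- vapply(clades, function(s) {
    k <- length(s)
    k >= 2L && k <= n - 2L
  }, logical(1))
  unique(vapply(clades[keep], .canonical_split, character(1), all_labels = labs))
}

# Max pairwise distance within a set of ids; NA if any pair undefined.
.max_within <- function(d, ids) {
  if (length(ids) < 2L) return(0)
  sub <- d[ids, ids, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  if (anyNA(vals)) return(NA_real_)
  max(vals)
}

.stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
}
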