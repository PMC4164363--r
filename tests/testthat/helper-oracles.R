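# Independent oracles used across the suite. Deliberately brute-force and
# separate from the package's code paths.

# Per-site loop over two equal-length sequences: usable sites, transitions,
# transversions.
oracle_patterns <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n <- n + 1L
    if (x == y) next
    if (paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT"))
      ts <- ts + 1L
    else tv <- tv + 1L
  }
  list(n = n, ts = ts, tv = tv)
}

# Closed-form K2P; NA outside the domain.
oracle_k2p <- function(n, ts, tv) {
  P <- ts / n; Q <- tv / n
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Random sequence pair with roughly the requested transition/transversion
# pressure, for K2P equivalence sweeps.
random_pair <- function(len = 400, p_ts = 0.05, p_tv = 0.02) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, len, replace = TRUE)
  b <- a
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  u <- runif(len)
  i_ts <- u < p_ts
  i_tv <- u >= p_ts & u < p_ts + p_tv
  b[i_ts] <- ts_map[b[i_ts]]
  b[i_tv] <- vapply(b[i_tv], function(x)
    sample(setdiff(bases, c(x, ts_map[[x]])), 1), character(1))
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# Tip-pair x edge incidence matrix: entry 1 iff the edge lies on the path
# between the two tips (edge side sets computed from the rooted edge table).
edge_incidence <- function(tree) {
  n <- length(tree$tip.label)
  desc <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= n) return(child)
    kids <- child
    repeat {
      more <- tree$edge[tree$edge[, 1] %in% kids, 2]
      if (all(more %in% kids)) break
      kids <- union(kids, more)
    }
    kids[kids <= n]
  })
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    A[p, ] <- vapply(desc, function(s) xor(i %in% s, j %in% s), logical(1))
  }
  list(A = A, pairs = pairs)
}

# Exhaustive-topology least-squares oracle: returns the best-fitting
# unrooted topology (phylo with LS branch lengths) for a distance matrix.
ls_best_tree <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  topos <- lapply(seq_along(topos), function(i) topos[[i]])  # decompress
  best <- NULL; best_rss <- Inf
  for (tr in topos) {
    inc <- edge_incidence(tr)
    dvec <- d[cbind(match(tr$tip.label[inc$pairs[, 1]], rownames(d)),
                    match(tr$tip.label[inc$pairs[, 2]], rownames(d)))]
    fit <- qr.solve(inc$A, dvec)
    rss <- sum((inc$A %*% fit - dvec)^2)
    if (rss < best_rss) {
      tr$edge.length <- as.numeric(fit)
      best <- tr; best_rss <- rss
    }
  }
  list(tree = best, rss = best_rss)
}

# Canonical set of non-trivial splits of a tree, as sorted label strings.
split_set <- function(tree) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  out <- vapply(pp, function(i) {
    s <- attr(pp, "labels")[i]
    if (min(labs) %in% s) s <- setdiff(labs, s)
    paste(sort(s), collapse = "|")
  }, character(1))
  keep <- lengths(pp) >= 2 & lengths(pp) <= length(labs) - 2
  sort(unique(out[keep]))
}

# Random additive distance matrix from a random binary tree with branch
# lengths bounded away from zero.
random_additive <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# A small clean reference/query scenario used by several files.
tiny_sim <- function(seed, ...) {
  simulate_library(simulation_config(seed = seed, ...))
}
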