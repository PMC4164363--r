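test_that("site-pattern counts follow the transition/transversion split", {
  expect_equal(count_site_patterns("ACGT", "ACGT"),
               list(n_compared = 4L, transitions = 0L, transversions = 0L))
  # A->G is a transition, T->A a transversion
  expect_equal(count_site_patterns("ACGT", "GCGA"),
               list(n_compared = 4L, transitions = 1L, transversions = 1L))
  # pairwise deletion drops gap/ambiguity sites
  expect_equal(count_site_patterns("AC-T", "ACGT")$n_compared, 3L)
  expect_equal(count_site_patterns("ACNT", "ACGT")$n_compared, 3L)
})

test_that("k2p evaluates the closed form and flags the domain boundary", {
  expect_equal(k2p(list(n_compared = 200, transitions = 0,
                        transversions = 0)), 0)
  # P = 0.1, Q = 0.05: hand-evaluated closed form
  d <- k2p(list(n_compared = 200, transitions = 20, transversions = 10))
  expect_equal(d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(d, 0.17018, tolerance = 1e-4)
  # P = 0.5, Q = 0: log of zero
  expect_true(is.na(k2p(list(n_compared = 200, transitions = 100,
                             transversions = 0))))
  # too few overlapping sites
  expect_true(is.na(k2p(list(n_compared = 50, transitions = 0,
                             transversions = 0))))
})

test_that("distance_matrix equals a brute-force per-pair oracle", {
  set.seed(101)
  sim <- tiny_sim(101, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 2,
                  misid_rate = 0, cryptic_fraction = 0)
  lib <- sim$library
  dm <- distance_matrix(lib)
  ids <- dm$ids
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    a <- lib$sequence[lib$specimen_id == ids[i]]
    b <- lib$sequence[lib$specimen_id == ids[j]]
    pat <- oracle_patterns(a, b)
    expect_equal(dm$d[i, j], oracle_k2p(pat$n, pat$ts, pat$tv),
                 tolerance = 1e-12)
    expect_equal(dm$d[i, j], dm$d[j, i])
  }
  expect_true(all(diag(dm$d) == 0))
})

test_that("distance_matrix agrees with ape::dist.dna under pairwise deletion", {
  sim <- tiny_sim(77, n_families = 2, genera_per_family = 1,
                  species_per_genus = 3, specimens_per_species = 3,
                  misid_rate = 0, cryptic_fraction = 0)
  lib <- sim$library
  dm <- distance_matrix(lib)
  bin <- ape::as.DNAbin(lapply(
    stats::setNames(strsplit(tolower(lib$sequence), ""), lib$specimen_id),
    identity))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$d[dm$ids, dm$ids], ref[dm$ids, dm$ids], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("K2P dominates the p-distance whenever defined", {
  set.seed(5)
  for (r in 1:50) {
    pr <- random_pair(300, p_ts = runif(1, 0, 0.15), p_tv = runif(1, 0, 0.1))
    cp <- count_site_patterns(pr$a, pr$b)
    d <- k2p(cp)
    if (is.na(d)) next
    p_dist <- (cp$transitions + cp$transversions) / cp$n_compared
    expect_gte(d, p_dist - 1e-12)
  }
})

test_that("rank summaries report the combinatorial pair counts", {
  sim <- tiny_sim(13, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 3,
                  misid_rate = 0, cryptic_fraction = 0)
  lib <- sim$library
  dm <- distance_matrix(lib)
  s <- summarize_ranks(dm, lib)
  # independent combinatorics from the taxonomy table
  tab <- table(lib$species)
  n_con <- sum(choose(tab, 2))
  per_genus <- split(lib$species, lib$genus)
  n_gen <- sum(vapply(per_genus, function(x) {
    t2 <- table(x); (sum(t2)^2 - sum(t2^2)) / 2
  }, numeric(1)))
  per_fam <- split(lib$genus, lib$family)
  n_fam <- sum(vapply(per_fam, function(x) {
    t2 <- table(x); (sum(t2)^2 - sum(t2^2)) / 2
  }, numeric(1)))
  expect_equal(s$n_pairs[s$level == "conspecific"], n_con)
  expect_equal(s$n_pairs[s$level == "congeneric"], n_gen)
  expect_equal(s$n_pairs[s$level == "confamilial"], n_fam)
  expect_true(all(s$min_pct <= s$mean_pct & s$mean_pct <= s$max_pct))
})

test_that("summaries are invariant under record permutation", {
  sim <- tiny_sim(23, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 2,
                  misid_rate = 0)
  lib <- sim$library
  perm <- barcode_library(as.data.frame(lib)[sample(nrow(lib)), ])
  expect_equal(summarize_ranks(distance_matrix(lib), lib),
               summarize_ranks(distance_matrix(perm), perm))
})

test_that("degenerate library: identical conspecifics, 10% between species", {
  base <- strsplit(paste(rep("ATGGCAACCATTGCA", 43), collapse = ""), "")[[1]]
  s1 <- paste(base, collapse = "")
  s2 <- base
  flip <- seq(3, 3 * 60, by = 3)   # mutate third codon positions
  map <- c(A = "G", G = "A", C = "T", T = "C")
  s2[flip] <- map[s2[flip]]
  s2 <- paste(s2, collapse = "")
  lib <- barcode_library(data.frame(
    specimen_id = c("a1", "a2", "b1", "b2"),
    sequence = c(s1, s1, s2, s2),
    species = rep(c("Genus aa", "Genus bb"), each = 2),
    genus = "Genus", family = "Fam", order = "Ord",
    region = "NEA", role = "reference", stringsAsFactors = FALSE))
  s <- summarize_ranks(distance_matrix(lib), lib)
  con <- s[s$level == "conspecific", ]
  gen <- s[s$level == "congeneric", ]
  expect_equal(con$min_pct, 0); expect_equal(con$max_pct, 0)
  expect_equal(gen$min_pct, gen$max_pct)
  expect_equal(gen$min_pct, gen$mean_pct)
})

test_that("species profiles mark singletons not-evaluable, recover splits", {
  sim <- tiny_sim(31, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = c(3, 1),
                  cryptic_fraction = 0.3, cryptic_depth = 0.05,
                  misid_rate = 0)
  lib <- sim$library
  prof <- species_divergence_profile(distance_matrix(lib), lib)
  singles <- sim$truth$species$species[sim$truth$species$n_specimens == 1]
  expect_true(all(!prof$species$evaluable[prof$species$species %in% singles]))
  planted <- sim$truth$species$species[sim$truth$species$cryptic &
                                         sim$truth$species$n_specimens >= 2]
  for (sp in planted) {
    expect_equal(prof$species$max_intra_pct[prof$species$species == sp] / 100,
                 0.05, tolerance = 0.5)
  }
})
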