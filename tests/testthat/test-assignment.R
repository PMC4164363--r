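# Merged-tree scenario builder: returns clusters + taxonomy for assignment.
merged_scenario <- function(sim, threshold = 0.02) {
  lib <- sim$library
  blind <- as.data.frame(lib)
  morph <- stats::setNames(blind$species, blind$specimen_id)
  blind$species[blind$role == "query"] <- NA_character_
  dm <- distance_matrix(barcode_library(
    within(blind, species[is.na(species)] <- genus[is.na(species)])))
  # keep species truly blind in the taxonomy used downstream
  tax <- blind[, c("specimen_id", "species", "role")]
  tree <- build_nj(dm)
  clusters <- extract_clusters(tree, dm, threshold = threshold,
                               taxonomy = tax)
  list(lib = lib, dm = dm, tree = tree, clusters = clusters, tax = tax,
       morphology = morph)
}

test_that("queries inside a pure reference cluster take its species", {
  sim <- tiny_sim(401, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 4,
                  cryptic_fraction = 0, misid_rate = 0)
  sc <- merged_scenario(sim)
  qids <- sc$lib$specimen_id[sc$lib$role == "query"]
  prov <- assign_by_cluster(qids, sc$clusters, sc$tax)
  expect_true(all(prov$status == "assigned"))
  truth <- sim$truth$specimens
  expect_identical(prov$assigned_species,
                   truth$true_species[match(prov$query_id,
                                            truth$specimen_id)])
})

test_that("queries far from all references stay unassigned", {
  sim <- tiny_sim(402, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 3,
                  cryptic_fraction = 0, misid_rate = 0, query_fraction = 0)
  lib <- as.data.frame(sim$library)
  # turn one whole species into queries: no reference conspecifics remain
  drop_sp <- lib$species[1]
  lib$role[lib$species == drop_sp] <- "query"
  sc <- merged_scenario(list(library = barcode_library(lib)))
  qids <- lib$specimen_id[lib$role == "query"]
  prov <- assign_by_cluster(qids, sc$clusters, sc$tax)
  expect_true(all(prov$status == "unassigned"))
})

test_that("assignments are blind to query morphology labels", {
  sim <- tiny_sim(403, n_families = 2, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 4,
                  cryptic_fraction = 0, misid_rate = 0)
  sc <- merged_scenario(sim)
  qids <- sc$lib$specimen_id[sc$lib$role == "query"]
  prov1 <- assign_by_cluster(qids, sc$clusters, sc$tax)
  # scramble every query's reported species; nothing downstream of the
  # cluster stage may change
  scr <- as.data.frame(sim$library)
  qrows <- scr$role == "query"
  scr$species[qrows] <- sample(scr$species[qrows])
  scr$genus[qrows] <- vapply(strsplit(scr$species[qrows], " "), `[[`,
                             character(1), 1)
  sc2 <- merged_scenario(list(library = barcode_library(scr)))
  prov2 <- assign_by_cluster(qids, sc2$clusters, sc2$tax)
  expect_identical(prov1$assigned_species, prov2$assigned_species)
  expect_identical(prov1$status, prov2$status)
})

test_that("identity threshold: 13/652 mismatches pass, 14 fail", {
  base <- paste(rep("ATGGCAACCATTGCAC", 41), collapse = "")  # 656
  base <- substr(base, 1, 652)
  flip <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    map <- c(A = "G", G = "A", C = "T", T = "C")
    idx <- seq(4, by = 9, length.out = k)
    ch[idx] <- map[ch[idx]]
    paste(ch, collapse = "")
  }
  cand <- data.frame(species = c("Genus one", "Genus two"),
                     sequence = c(flip(base, 13), flip(base, 14)),
                     stringsAsFactors = FALSE)
  hits <- identity_search(base, cand, min_identity = 98)
  h13 <- hits[hits$species == "Genus one", ]
  h14 <- hits[hits$species == "Genus two", ]
  expect_equal(h13$identity, 100 * (652 - 13) / 652, tolerance = 1e-12)
  expect_equal(h14$identity, 100 * (652 - 14) / 652, tolerance = 1e-12)
  expect_true(h13$passes)
  expect_false(h14$passes)
  # an identical candidate is a 100% hit
  self <- identity_search(base, data.frame(species = "Genus self",
                                           sequence = base))
  expect_equal(self$identity[1], 100)
})

test_that("outcomes cover confirmed / mismatch / ambiguous / new_record", {
  prov <- data.frame(query_id = "q", status = "assigned",
                     assigned_species = "Sparus aurata",
                     cluster_id = "CL0001", stringsAsFactors = FALSE)
  expect_identical(classify_outcome(prov, NULL, "Sparus aurata")$outcome,
                   "confirmed")
  expect_identical(classify_outcome(prov, NULL, "Sparus pagrus")$outcome,
                   "mismatch")
  un <- within(prov, {status <- "unassigned"; assigned_species <- NA})
  hits <- data.frame(species = c("Genus aa", "Genus bb"),
                     identity = c(100, 100), coverage = 1,
                     passes = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_identical(classify_outcome(un, hits, "Genus aa")$outcome,
                   "ambiguous")   # exact tie across distinct species
  low <- data.frame(species = "Genus cc", identity = 94, coverage = 1,
                    passes = FALSE, stringsAsFactors = FALSE)
  out <- classify_outcome(un, low, "Genus cc")
  expect_identical(out$outcome, "new_record")
  expect_match(out$evidence, "94")
  expect_identical(classify_outcome(un, NULL, "Genus dd")$outcome,
                   "no_match")
  # top-identity rule: single best species above the floor wins
  ranked <- data.frame(species = c("Genus aa", "Genus bb"),
                       identity = c(99.5, 98.3), coverage = 1,
                       passes = c(TRUE, TRUE), stringsAsFactors = FALSE)
  expect_identical(classify_outcome(un, ranked, "Genus aa")$outcome,
                   "confirmed")
  expect_identical(classify_outcome(un, ranked, "Genus bb")$outcome,
                   "mismatch")
})

test_that("a species absent from the snapshot lands below the floor", {
  sim <- tiny_sim(405, n_families = 1, genera_per_family = 1,
                  species_per_genus = 3, specimens_per_species = 2,
                  theta_intra = 0.002, theta_inter = 0.06,
                  theta_family = 0.1, cryptic_fraction = 0, misid_rate = 0,
                  query_fraction = 0)
  lib <- as.data.frame(sim$library)
  target_sp <- lib$species[1]
  query_seq <- lib$sequence[1]
  snap <- lib[lib$species != target_sp, c("species", "sequence")]
  hits <- identity_search(query_seq, snap)
  expect_false(any(hits$passes))
  expect_lt(hits$identity[1], 98)
  expect_gt(hits$identity[1], 85)   # congeners ~6% away
})

test_that("deep-divergence flags recover planted splits and their sorting", {
  sim <- tiny_sim(406, n_families = 2, genera_per_family = 2,
                  species_per_genus = 3, specimens_per_species = 4,
                  cryptic_fraction = 0.15, cryptic_depth = 0.06,
                  region_sorting = TRUE, misid_rate = 0, query_fraction = 0)
  lib <- sim$library
  dm <- distance_matrix(lib)
  tr <- build_nj(dm)
  cl <- extract_clusters(tr, dm, taxonomy = lib)
  fl <- flag_deep_divergences(lib, dm, cl)
  planted <- sim$truth$species$species[sim$truth$species$cryptic]
  expect_setequal(fl$species, planted)
  expect_true(all(fl$max_intra_pct > 2))
  expect_true(all(fl$n_subclusters == 2))
  expect_true(all(fl$geographic_sorting))
  expect_equal(fl$between_subcluster_mean_pct / 100,
               rep(0.06, nrow(fl)), tolerance = 0.35)
})

test_that("species within 0.5% divergence are never flagged", {
  sim <- tiny_sim(407, n_families = 1, genera_per_family = 2,
                  species_per_genus = 2, specimens_per_species = 4,
                  theta_intra = 0.003, cryptic_fraction = 0, misid_rate = 0,
                  query_fraction = 0)
  lib <- sim$library
  dm <- distance_matrix(lib)
  cl <- extract_clusters(build_nj(dm), dm, taxonomy = lib)
  expect_equal(nrow(flag_deep_divergences(lib, dm, cl)), 0)
})
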