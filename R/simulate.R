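#' Configuration for the barcode library simulator
#'
#' Bundles and validates the parameters of the hierarchical generator. The
#' divergence parameters are expected pairwise K2P distances
#' (substitutions/site) between specimens at each taxonomic level and must
#' satisfy \code{0 <= theta_intra < theta_inter < theta_family < theta_deep}.
#'
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape.
#' @param specimens_per_species Integer vector recycled across species (the
#'   default mixes well-sampled species with doubletons and singletons, as
#'   real regional libraries do).
#' @param seq_len Barcode length, default 652.
#' @param theta_intra,theta_inter,theta_family Expected conspecific,
#'   congeneric and confamilial divergence; defaults 0.004 / 0.09 / 0.16.
#' @param theta_deep Expected between-family divergence (keeps distant pairs
#'   clear of K2P saturation), default 0.25.
#' @param kappa Transition/transversion rate ratio, default 4 (typical COI
#'   transition bias).
#' @param cryptic_fraction Fraction of multi-specimen species given a planted
#'   two-lineage split, default 0.1.
#' @param cryptic_depth Expected divergence between the two planted lineages,
#'   default 0.06; must exceed \code{theta_intra}.
#' @param region_sorting If TRUE (default) the two cryptic lineages are
#'   region-pure (NEA vs MED).
#' @param misid_rate Probability that a query specimen's reported species is
#'   swapped for a congener, default 0.02.
#' @param query_fraction Fraction of each species' specimens set aside as
#'   blind queries, default 0.25.
#' @param seed Mandatory integer seed.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_families = 8L, genera_per_family = 2L,
                              species_per_genus = 3L,
                              specimens_per_species = c(5L, 4L, 3L, 3L, 1L, 2L),
                              seq_len = 652L,
                              theta_intra = 0.004, theta_inter = 0.09,
                              theta_family = 0.16, theta_deep = 0.25,
                              kappa = 4, cryptic_fraction = 0.1,
                              cryptic_depth = 0.06, region_sorting = TRUE,
                              misid_rate = 0.02, query_fraction = 0.25,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              specimens_per_species = as.integer(specimens_per_species),
              seq_len = as.integer(seq_len),
              theta_intra = theta_intra, theta_inter = theta_inter,
              theta_family = theta_family, theta_deep = theta_deep,
              kappa = kappa, cryptic_fraction = cryptic_fraction,
              cryptic_depth = cryptic_depth,
              region_sorting = isTRUE(region_sorting),
              misid_rate = misid_rate, query_fraction = query_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (!(theta_intra >= 0 && theta_intra < theta_inter &&
          theta_inter < theta_family && theta_family < theta_deep))
      stop("divergences must satisfy 0 <= theta_intra < theta_inter < ",
           "theta_family < theta_deep")
    if (cryptic_fraction > 0 && cryptic_depth <= theta_intra)
      stop("cryptic_depth must exceed theta_intra")
    if (kappa <= 0 || misid_rate < 0 || misid_rate > 1 ||
        query_fraction < 0 || query_fraction > 1)
      stop("invalid rate parameter")
    if (any(specimens_per_species < 1L)) stop("specimens_per_species >= 1")
  })
  structure(cfg, class = "simulation_config")
}

# K2P substitution probabilities for a branch of expected length d
# (substitutions/site) at transition/transversion ratio kappa.
.k2p_site_probs <- function(d, kappa) {
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta) - 0.5 * exp(-2 * (alpha + beta))
  p_tv <- 0.5 - 0.5 * exp(-4 * beta)
  c(ts = p_ts, tv = p_tv)
}

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
.TV_MAP <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))

.mutate_chars <- function(chars, p_ts, p_tv) {
  L <- length(chars)
  u <- stats::runif(L)
  ts_idx <- which(u < p_ts)
  tv_idx <- which(u >= p_ts & u < p_ts + p_tv)
  if (length(ts_idx)) chars[ts_idx] <- .TS_MAP[chars[ts_idx]]
  if (length(tv_idx)) {
    pick <- 1L + (stats::runif(length(tv_idx)) < 0.5)
    chars[tv_idx] <- mapply(function(b, k) .TV_MAP[[b]][k],
                            chars[tv_idx], pick, USE.NAMES = FALSE)
  }
  chars
}

#' Evolve a sequence under the K2P substitution process
#'
#' Applies, independently per site, the exact Kimura two-parameter
#' substitution probabilities for a branch of expected length
#' \code{branch_length} (substitutions/site) with transition bias
#' \code{kappa}. With \code{avoid_stops = TRUE}, frame-0 codons that would
#' become vertebrate-mitochondrial stops are rejection-resampled from the
#' parent codon, keeping simulated barcodes QC-clean without measurably
#' biasing distances at barcoding divergences. Uses R's global RNG: call
#' \code{set.seed()} for reproducibility.
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param branch_length Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param avoid_stops Keep frame 0 free of stop codons (default TRUE).
#' @return The derived sequence (same length).
#' @export
evolve <- function(seq, branch_length, kappa = 4, avoid_stops = TRUE) {
  stopifnot(branch_length >= 0)
  if (branch_length == 0) return(seq)
  pr <- .k2p_site_probs(branch_length, kappa)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- .mutate_chars(chars, pr["ts"], pr["tv"])
  if (avoid_stops) {
    n_codons <- length(out) %/% 3L
    if (n_codons) {
      for (ci in seq_len(n_codons)) {
        idx <- (3L * ci - 2L):(3L * ci)
        if (!(paste(out[idx], collapse = "") %in% .MITO_STOPS)) next
        fixed <- FALSE
        for (try in 1:50) {
          cand <- .mutate_chars(chars[idx], pr["ts"], pr["tv"])
          if (!(paste(cand, collapse = "") %in% .MITO_STOPS)) {
            out[idx] <- cand; fixed <- TRUE; break
          }
        }
        if (!fixed) out[idx] <- chars[idx]   # parent codon is stop-free
      }
    }
  }
  paste(out, collapse = "")
}

# Random root barcode with a stop-free reading frame 0.
.random_root <- function(seq_len) {
  chars <- sample(.BASES, seq_len, replace = TRUE)
  n_codons <- seq_len %/% 3L
  for (ci in seq_len(n_codons)) {
    idx <- (3L * ci - 2L):(3L * ci)
    while (paste(chars[idx], collapse = "") %in% .MITO_STOPS)
      chars[idx] <- sample(.BASES, 3L, replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' Swap reported species labels to congeners
#'
#' Models morphology-based misidentification: each eligible specimen's
#' reported species is, with probability \code{misid_rate}, replaced by a
#' different species of the same genus (drawn from the library's species
#' pool). Specimens whose genus holds no other species are skipped and
#' logged. Uses the global RNG.
#'
#' @param library A \code{barcode_library}.
#' @param misid_rate Per-specimen swap probability.
#' @param roles Roles eligible for swapping, default both.
#' @return List: \code{library} (labels swapped), \code{swaps} (data frame
#'   \code{specimen_id}, \code{from}, \code{to}), \code{skipped}
#'   (ids drawn for a swap but lacking a congener).
#' @export
inject_errors <- function(library, misid_rate,
                          roles = c("reference", "query")) {
  recs <- as.data.frame(library)
  pool <- unique(recs[, c("species", "genus")])
  eligible <- which(recs$role %in% roles)
  hit <- eligible[stats::runif(length(eligible)) < misid_rate]
  swaps <- list(); skipped <- character(0)
  for (i in hit) {
    congeners <- setdiff(pool$species[pool$genus == recs$genus[i]],
                         recs$species[i])
    if (!length(congeners)) {
      skipped <- c(skipped, recs$specimen_id[i]); next
    }
    to <- sample(sort(congeners), 1L)
    swaps[[length(swaps) + 1L]] <- data.frame(
      specimen_id = recs$specimen_id[i], from = recs$species[i], to = to,
      stringsAsFactors = FALSE)
    recs$species[i] <- to
  }
  swaps <- if (length(swaps)) do.call(rbind, swaps)
    else data.frame(specimen_id = character(0), from = character(0),
                    to = character(0), stringsAsFactors = FALSE)
  list(library = .new_barcode_library(recs), swaps = swaps, skipped = skipped)
}

#' Simulate a barcode library with known truth
#'
#' Hierarchical generation along a fixed genealogy: a single deep ancestor
#' spawns family ancestors, then genus ancestors, species roots and, within
#' each species, a star of specimen haplotypes, with branch lengths chosen
#' so that expected pairwise divergences equal \code{theta_intra},
#' \code{theta_inter} and \code{theta_family} at the three levels. A chosen
#' fraction of multi-specimen species receives a planted two-lineage split
#' of expected depth \code{cryptic_depth}, region-pure (NEA vs MED) when
#' \code{region_sorting}. Specimens are split into reference and query
#' roles per species; query specimens' reported labels are then swapped to
#' congeners at \code{misid_rate}. All sequences pass barcode QC.
#'
#' @param config A [simulation_config()].
#' @return List with \code{library} (a \code{barcode_library}) and
#'   \code{truth}: \code{specimens} (id, true/reported species, lineage,
#'   region, role), \code{species} (taxonomy, sampling, cryptic flag and
#'   planted depth) and \code{swaps} (the misidentification log).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config
  root <- .random_root(cfg$seq_len)
  ev <- function(s, b) evolve(s, b, kappa = cfg$kappa)

  n_species_total <- cfg$n_families * cfg$genera_per_family *
    cfg$species_per_genus
  counts <- rep_len(cfg$specimens_per_species, n_species_total)

  sp_rows <- list(); spec_rows <- list(); seqs <- character(0)
  sp_i <- 0L; g_i <- 0L; spec_i <- 0L
  branch_family <- (cfg$theta_deep - cfg$theta_family) / 2
  branch_genus <- (cfg$theta_family - cfg$theta_inter) / 2
  branch_species <- (cfg$theta_inter - cfg$theta_intra) / 2
  branch_specimen <- cfg$theta_intra / 2
  branch_lineage <- (cfg$cryptic_depth - cfg$theta_intra) / 2

  # which species get a planted split (decided on species indices with >= 2
  # specimens, before sequences are drawn)
  multi <- which(counts >= 2L)
  n_cryptic <- min(length(multi),
                   ceiling(cfg$cryptic_fraction * n_species_total))
  cryptic_idx <- if (n_cryptic) sort(sample(multi, n_cryptic)) else integer(0)

  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("Family%02d", f)
    fam_seq <- ev(root, branch_family)
    for (g in seq_len(cfg$genera_per_family)) {
      g_i <- g_i + 1L
      gen <- sprintf("Genus%03d", g_i)
      gen_seq <- ev(fam_seq, branch_genus)
      for (s in seq_len(cfg$species_per_genus)) {
        sp_i <- sp_i + 1L
        sp <- paste0(gen, " sp", sprintf("%02d", s))
        sp_seq <- ev(gen_seq, branch_species)
        n_spec <- counts[sp_i]
        cryptic <- sp_i %in% cryptic_idx
        lin_seq <- if (cryptic)
          list(ev(sp_seq, branch_lineage), ev(sp_seq, branch_lineage))
        else list(sp_seq)
        n_query <- floor(cfg$query_fraction * n_spec)
        for (k in seq_len(n_spec)) {
          spec_i <- spec_i + 1L
          lineage <- if (cryptic) ((k - 1L) %% 2L) + 1L else 1L
          region <- if (cryptic && cfg$region_sorting)
            c("NEA", "MED")[lineage]
          else c("NEA", "MED")[((k - 1L) %% 2L) + 1L]
          role <- if (k > n_spec - n_query) "query" else "reference"
          spec_rows[[spec_i]] <- data.frame(
            specimen_id = sprintf("SIM%04d", spec_i), species = sp,
            genus = gen, family = fam, order = "Simuliformes",
            region = region, role = role, lineage = lineage,
            stringsAsFactors = FALSE)
          seqs[spec_i] <- ev(lin_seq[[lineage]], branch_specimen)
        }
        sp_rows[[sp_i]] <- data.frame(
          species = sp, genus = gen, family = fam, n_specimens = n_spec,
          cryptic = cryptic,
          planted_depth = if (cryptic) cfg$cryptic_depth else cfg$theta_intra,
          stringsAsFactors = FALSE)
      }
    }
  }
  specimens <- do.call(rbind, spec_rows)
  records <- specimens[, c("specimen_id", "species", "genus", "family",
                           "order", "region", "role")]
  records$sequence <- seqs
  lib <- barcode_library(records)

  swaps <- data.frame(specimen_id = character(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE)
  if (cfg$misid_rate > 0) {
    inj <- inject_errors(lib, cfg$misid_rate, roles = "query")
    lib <- inj$library
    swaps <- inj$swaps
  }
  truth_spec <- data.frame(
    specimen_id = specimens$specimen_id,
    true_species = specimens$species,
    reported_species = lib$species[match(specimens$specimen_id,
                                         lib$specimen_id)],
    lineage = specimens$lineage, region = specimens$region,
    role = specimens$role, stringsAsFactors = FALSE)
  list(library = lib,
       truth = list(specimens = truth_spec,
                    species = do.call(rbind, sp_rows),
                    swaps = swaps))
}
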