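#' Bundled synthetic study fixture
#'
#' Builds a complete synthetic dataset mirroring the study design the
#' package targets: six populations of sizes 5, 7, 5, 16, 15 and 7, 14
#' microsatellite loci with 5-16 alleles per locus (mean 11.71), an
#' F-model divergence calibrated to the 0.03-0.22 pairwise F_ST range,
#' five planted first-generation migrants spanning four population pairs,
#' and a 60 x 60 km landscape whose habitat patches carry the populations.
#' Population abundance counts (source strengths) equal the sample sizes.
#'
#' @param seed Integer seed.
#' @param missing_rate Per-call missing-data probability.
#' @return List with `table`, `freqs` (generating frequencies), `migrants`
#'   (truth tibble), `landscape` (rasters + roads), `coords` (population
#'   centroids), `strengths`, and `seed`.
#' @export
make_fixture <- function(seed = 1, missing_rate = 0.02) {
  pops <- c("MTR", "PTR", "NGWLS", "TATR", "KTR", "NSTR")
  sizes <- c(MTR = 5, PTR = 7, NGWLS = 5, TATR = 16, KTR = 15, NSTR = 7)
  n_alleles <- c(5, 6, 9, 10, 11, 12, 12, 13, 13, 14, 14, 14, 15, 16)
  freqs <- sim_allele_freqs(n_pops = 6, n_loci = 14, n_alleles = n_alleles,
                            fst = 0.12, seed = seed, pop_names = pops)
  sim <- sim_genotypes(freqs, n_per_pop = unname(sizes),
                       missing_rate = missing_rate, seed = seed + 1)
  pairs <- tibble::tibble(from = c("NSTR", "KTR", "MTR", "NGWLS"),
                          to = c("KTR", "PTR", "KTR", "NSTR"),
                          n = c(2, 1, 1, 1))
  planted <- plant_migrants(sim$table, freqs, pairs, seed = seed + 2)
  for (attempt in 0:4) { # population patches must be distinct components
    land <- sim_landscape(grid_dim = c(60, 60), n_patches = 6,
                          seed = seed + 3 + 100000 * attempt)
    coords <- dplyr::mutate(land$truth$patches[, c("x", "y")],
                            pop = pops, .before = 1)
    ok <- tryCatch({
      mask_patch_labels(habitat_resistance(land$landcover)$patches, coords)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
  }
  tab <- planted$table
  tab$x <- coords$x[match(tab$pop, coords$pop)]
  tab$y <- coords$y[match(tab$pop, coords$pop)]
  list(table = tab, freqs = freqs, migrants = planted$truth,
       landscape = land, coords = coords, strengths = sizes, seed = seed)
}

#' Pipeline configuration
#'
#' Collects every threshold of the analysis with the conventional defaults:
#' quality index 0.75, 12-locus minimum, migrant-detection alpha 0.01 with
#' 10000 resampled genotypes, migration priors \{0.01, 0.02, 0.05, 0.1\},
#' >10 km2 habitat patches, night-light urban threshold 20, 30 km study
#' buffer.
#'
#' @param qi_threshold,min_loci,alpha,n_sim,migprior,min_patch_km2,
#'   urban_threshold,buffer_km Analysis thresholds (see description).
#' @param n_perm Mantel permutations.
#' @param seed Master seed.
#' @param genepop Optional path to a Genepop file to analyse instead of the
#'   simulated fixture.
#' @param layer_combos `"all"` (every nonempty subset of the four layers),
#'   `"single"`, or a list of character vectors of layer names from
#'   `c("settlements", "roads", "tree", "habitat")`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(qi_threshold = 0.75, min_loci = 12, alpha = 0.01,
                            n_sim = 10000, migprior = c(0.01, 0.02, 0.05, 0.1),
                            min_patch_km2 = 10, urban_threshold = 20,
                            buffer_km = 30, n_perm = 9999, seed = 1,
                            genepop = NULL, layer_combos = "all") {
  stopifnot(qi_threshold >= 0, qi_threshold <= 1, min_loci >= 1,
            alpha > 0, alpha < 1, n_sim >= 100,
            all(migprior > 0), all(migprior < 1),
            min_patch_km2 >= 0, urban_threshold >= 0, buffer_km > 0)
  structure(as.list(environment()), class = "run_config")
}

layer_subsets <- function(spec, layer_names) {
  if (identical(spec, "all")) {
    combos <- unlist(lapply(seq_along(layer_names), function(k) {
      utils::combn(layer_names, k, simplify = FALSE)
    }), recursive = FALSE)
  } else if (identical(spec, "single")) {
    combos <- as.list(layer_names)
  } else {
    combos <- spec
  }
  stats::setNames(combos, vapply(combos, paste, "", collapse = "+"))
}

#' Run the full landscape-genetics pipeline
#'
#' Orchestrates the stages end to end on a fixture (or supplied Genepop
#' data plus simulated landscape): unique-individual filtering, diversity
#' and differentiation, migrant detection (with resampling null and
#' migrant posteriors across the migration priors), resistance layers,
#' pairwise circuit resistances for every layer combination, and the
#' Mantel tables relating genetic matrices to distance and resistance.
#' Optional stages that fail (e.g. relatedness) are logged, not fatal.
#'
#' @param config A [pipeline_config()].
#' @param fixture Optional pre-built [make_fixture()] output (ignored when
#'   `config$genepop` is set).
#' @return A `run_report` list; see the elements documented in the README.
#' @export
pipeline_run <- function(config = pipeline_config(), fixture = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(...))
    log <<- c(log, msg)
  }
  say("seed = %d", config$seed)
  if (!is.null(config$genepop)) {
    tab <- read_genepop(config$genepop)
    fixture <- list(table = tab, landscape = NULL, coords = NULL,
                    strengths = NULL, migrants = NULL)
    say("read %s", config$genepop)
  } else if (is.null(fixture)) {
    fixture <- make_fixture(seed = config$seed)
    say("simulated fixture")
  }
  tab <- fixture$table

  dedup <- identify_individuals(tab, min_loci = config$min_loci)
  tab <- dedup$table
  say("unique individuals: %d (%d dropped, %d duplicates)",
      nrow(gt_individuals(tab)), nrow(dedup$dropped), nrow(dedup$duplicates))

  freqs <- allele_frequencies(tab)
  divers <- diversity(tab, n_shuffle = min(config$n_sim, 2000),
                      seed = config$seed)
  pid <- pid_sibs(freqs)
  fstm <- fst_matrix(tab)
  dspm <- dsp_matrix(tab)
  say("diversity, F_ST and D_SP done")

  relat <- tryCatch(ml_relatedness(tab), error = function(e) {
    say("relatedness failed: %s", conditionMessage(e)); NULL
  })

  calls <- detect_migrants(tab, alpha = config$alpha, n_sim = config$n_sim,
                           seed = config$seed + 10)
  posteriors <- lapply(config$migprior, function(nu) migrant_posterior(tab, nu))
  names(posteriors) <- paste0("nu_", config$migprior)
  mig_table <- calls[, c("id", "pop", "assigned", "lambda", "p_resident", "flagged")]
  for (nm in names(posteriors)) {
    mig_table[[paste0("migrant_prob_", sub("nu_", "", nm))]] <-
      posteriors[[nm]]$summary$migrant_prob[
        match(mig_table$id, posteriors[[nm]]$summary$id)]
  }
  rates <- migration_matrices(calls, pops = pop_levels(tab))
  say("migrant detection done: %d flagged", sum(calls$flagged))

  report <- list(config = config, log = log, quality = NULL,
                 diversity = divers, pid_sibs = pid,
                 fst = fstm, dsp = dspm, relatedness = relat,
                 migrants = mig_table, posteriors = posteriors,
                 migration = rates, table = tab, truth = fixture$migrants)

  if (!is.null(fixture$landscape)) {
    land <- fixture$landscape
    hab <- habitat_resistance(land$landcover, habitat_classes = 1,
                              min_patch_km2 = config$min_patch_km2)
    setl <- settlement_resistance(land$lights,
                                  urban_threshold = config$urban_threshold)
    road <- road_resistance(land$roads, land$landcover)
    tree <- rescale_1_100(land$tree, invert = TRUE)
    valid <- study_area(hab$patches, setl$urban, buffer_km = config$buffer_km)
    layers <- list(settlements = mask_layer(setl$resistance, valid),
                   roads = mask_layer(road$resistance, valid),
                   tree = mask_layer(tree, valid),
                   habitat = mask_layer(hab$resistance, valid))
    say("layers built; %d valid cells", sum(valid))

    combos <- layer_subsets(config$layer_combos, names(layers))
    # keep only patches that carry populations (in centre order)
    strengths <- fixture$strengths
    resist <- lapply(combos, function(members) {
      layer <- combine_layers(layers[members])
      graph <- build_graph(layer)
      regions <- regions_from_patches(graph, mask_patch_labels(hab$patches,
                                                               fixture$coords))
      names(regions) <- fixture$coords$pop[match(names(regions),
                                                 paste0("P", seq_len(nrow(fixture$coords))))]
      pairwise_resistance(graph, regions,
                          strengths = strengths[names(regions)],
                          current_map = length(members) == length(layers))
    })
    say("circuit solves done for %d surfaces", length(resist))

    ord <- pop_levels(tab)
    rmats <- lapply(resist, function(x) x$r[ord, ord])
    mantel_seed <- config$seed + 20
    tab3 <- list(
      fst = ibd_test(fstm$fst, fixture$coords, config$n_perm, mantel_seed),
      dsp = ibd_test(dspm$dsp, fixture$coords, config$n_perm, mantel_seed),
      immigration = ibd_test(rates$immigration[ord, ord], fixture$coords,
                             config$n_perm, mantel_seed),
      emigration = ibd_test(rates$emigration[ord, ord], fixture$coords,
                            config$n_perm, mantel_seed))
    report$ibd <- purrr::map_dfr(tab3, tidy, .id = "statistic")
    report$mantel_dsp <- mantel_ranking(dspm$dsp, rmats,
                                        n_perm = config$n_perm, seed = mantel_seed)
    report$mantel_emigration <- mantel_ranking(rates$emigration[ord, ord],
                                               rmats, n_perm = config$n_perm,
                                               seed = mantel_seed)
    report$mantel_immigration <- mantel_ranking(rates$immigration[ord, ord],
                                                rmats, n_perm = config$n_perm,
                                                seed = mantel_seed)
    report$layers <- layers
    report$resistance <- resist
    say("Mantel tables done")
  }
  report$log <- log
  structure(report, class = "run_report")
}

# restrict the patch-label raster to the patches nearest the population
# centroids (one patch per population, in coords order)
mask_patch_labels <- function(patches, coords) {
  co <- raster_coords(patches)
  keep <- vapply(seq_len(nrow(coords)), function(i) {
    on <- !is.na(co$value)
    d <- (co$x - coords$x[i])^2 + (co$y - coords$y[i])^2
    co$value[on][which.min(d[on])]
  }, numeric(1))
  if (anyDuplicated(keep)) {
    stop("two population centroids map to the same habitat patch")
  }
  v <- patches$values
  v[!v %in% keep] <- NA
  v <- matrix(match(v, keep), nrow(v), ncol(v))
  raster_grid(v, patches$cell_size, patches$xll, patches$yll)
}

#' @export
print.run_report <- function(x, ...) {
  cat("# run_report\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
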