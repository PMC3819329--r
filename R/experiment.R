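#' End-to-end landscape-driven gene-flow experiment
#'
#' One replicate of the package's full synthetic validation loop: a
#' landscape is generated in which an urban settlement wall (a ring of
#' towns broken by a few forested corridor gaps) encloses a central
#' population, the four resistance surfaces are built, pairwise
#' circuit-theory resistances are computed on each single-layer surface,
#' gene flow follows the settlement surface via
#' `m_ij = m_med * exp(-(R_ij - median R) / tau)` (capped at `m_cap`),
#' allele frequencies evolve under forward migration-drift, genotypes are
#' sampled, and the D_SP matrix is tested against every single-layer
#' resistance matrix (partial Mantel conditioned on inter-population
#' Euclidean distance, the Table-4-style design) and against raw distance
#' (the isolation-by-distance test).
#'
#' Because the generating resistance is the settlement surface, a correct
#' pipeline should rank the settlement layer first by r2 in most
#' replicates while finding no significant isolation by distance.
#'
#' @param seed Integer seed for the replicate.
#' @param n_loci,n_alleles Marker panel of the sampled genotypes.
#' @param n_per_pop Individuals sampled per population.
#' @param n_e,generations Drift parameters of the forward simulation.
#' @param m_med Migration rate assigned to the median-resistance pair.
#' @param m_cap Upper bound on any single pairwise rate.
#' @param tau_quantile Resistance quantile whose excess over the median
#'   sets the exponential decay scale `tau` (divided by 2.5).
#' @param n_perm Mantel permutations (exhaustive enumeration is used at
#'   6 populations regardless).
#' @return List with `ranking` (partial-Mantel table over the four single
#'   layers), `top_surface`, `ibd` (`mantel_result` vs distance),
#'   `fst` (pairwise matrix), `dsp`, `resistance` (per-layer matrices),
#'   `migration` (generating matrix) and `truth` (landscape truth record).
#' @export
connectivity_experiment <- function(seed = 1, n_loci = 28, n_alleles = 10,
                                    n_per_pop = 45, n_e = 100,
                                    generations = 500, m_med = 0.04,
                                    m_cap = 0.08, tau_quantile = 0.8,
                                    n_perm = 999) {
  # rejection-sample the landscape: population patches must stay distinct
  # connected components (rarely, noise merges two patches)
  for (attempt in 0:4) {
    land <- sim_landscape(seed = seed + 100000 * attempt, n_settlements = 10,
                          center_patch = TRUE,
                          barrier = list(type = "ring", patch = 1,
                                         width_km = 6, n_gaps = 3, gap_km = 3))
    hab <- habitat_resistance(land$landcover)
    ctr <- land$truth$patches
    coords <- data.frame(pop = paste0("P", seq_len(nrow(ctr))),
                         x = ctr$x, y = ctr$y)
    pop_patches <- tryCatch(mask_patch_labels(hab$patches, coords),
                            error = function(e) NULL)
    if (!is.null(pop_patches)) break
  }
  if (is.null(pop_patches)) stop("no landscape with 6 distinct population patches")
  setl <- settlement_resistance(land$lights)
  road <- road_resistance(land$roads, land$landcover)
  tree <- rescale_1_100(land$tree, invert = TRUE)
  valid <- study_area(hab$patches, setl$urban)
  layers <- list(settlements = mask_layer(setl$resistance, valid),
                 roads = mask_layer(road$resistance, valid),
                 tree = mask_layer(tree, valid),
                 habitat = mask_layer(hab$resistance, valid))
  rmats <- lapply(layers, function(lay) {
    graph <- build_graph(lay)
    regions <- regions_from_patches(graph, mask_layer(pop_patches, valid))
    pairwise_resistance(graph, regions, current_map = FALSE)$r
  })
  rs <- rmats$settlements
  ut <- upper.tri(rs)
  tau <- (stats::quantile(rs[ut], tau_quantile) - stats::median(rs[ut])) / 2.5
  m <- m_med * exp(-(rs - stats::median(rs[ut])) / tau)
  m[m > m_cap] <- m_cap
  diag(m) <- 0
  f0 <- sim_allele_freqs(n_pops = 6, n_loci = n_loci, n_alleles = n_alleles,
                         fst = 0, seed = seed + 100, pop_names = rownames(rs))
  ff <- sim_geneflow_forward(f0, m, n_e = n_e, generations = generations,
                             seed = seed + 200)
  g <- sim_genotypes(ff, n_per_pop = n_per_pop, seed = seed + 300)
  dspm <- dsp_matrix(g$table)$dsp
  dmat <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  dimnames(dmat) <- dimnames(dspm)
  ranking <- mantel_ranking(dspm, rmats, z = dmat, n_perm = n_perm,
                            seed = seed + 400)
  ibd <- ibd_test(dspm, coords, n_perm = n_perm, seed = seed + 400)
  list(ranking = ranking, top_surface = ranking$surface[1], ibd = ibd,
       fst = fst_matrix(g$table)$fst, dsp = dspm, resistance = rmats,
       migration = m, coords = coords, truth = land$truth)
}
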