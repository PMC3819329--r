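test_that("the F-model collapses at F = 0, rejects F >= 1, and is deterministic", {
  f0 <- sim_allele_freqs(n_pops = 4, n_loci = 3, n_alleles = 5, fst = 0, seed = 1)
  wide <- tidyr::pivot_wider(f0, names_from = "pop", values_from = "freq")
  expect_equal(wide$P1, wide$P2)
  expect_equal(wide$P1, wide$P4)
  expect_error(sim_allele_freqs(fst = 1), "fst")
  a <- sim_allele_freqs(n_pops = 3, n_loci = 4, n_alleles = 6, fst = 0.2, seed = 9)
  b <- sim_allele_freqs(n_pops = 3, n_loci = 4, n_alleles = 6, fst = 0.2, seed = 9)
  expect_identical(a, b)
  c2 <- sim_allele_freqs(n_pops = 3, n_loci = 4, n_alleles = 6, fst = 0.2, seed = 10)
  expect_false(identical(a, c2))
})

test_that("every simulated frequency vector sums to one", {
  for (f in c(0, 0.05, 0.3)) {
    fr <- sim_allele_freqs(n_pops = 3, n_loci = 5, n_alleles = c(2, 4, 8, 12, 16),
                           fst = f, seed = 3)
    sums <- dplyr::summarise(dplyr::group_by(fr, pop, locus),
                             s = sum(freq), .groups = "drop")$s
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("genotype simulation respects fixation, missingness and heterozygosity", {
  fixed <- tibble::tibble(pop = rep(c("P1", "P2"), each = 1), locus = "L1",
                          allele = 1L, freq = 1, n = NA_real_)
  g <- sim_genotypes(corridorgen:::new_allele_freqs(fixed), n_per_pop = 10, seed = 2)
  expect_true(all(g$table$a1 == 1 & g$table$a2 == 1))

  f0 <- sim_allele_freqs(n_pops = 1, n_loci = 6, n_alleles = 4, fst = 0, seed = 4)
  g0 <- sim_genotypes(f0, n_per_pop = 25, missing_rate = 0, seed = 5)
  expect_equal(sum(is.na(g0$table$a1)), 0)

  # binomial bound on observed heterozygosity at p = (0.5, 0.5)
  half <- corridorgen:::new_allele_freqs(
    tibble::tibble(pop = "P1", locus = "L1", allele = 1:2,
                   freq = 0.5, n = NA_real_))
  gh <- sim_genotypes(half, n_per_pop = 200, seed = 6)
  ho <- mean(gh$table$a1 != gh$table$a2)
  expect_lt(abs(ho - 0.5), 0.07)
})

test_that("planted migrants carry source genotypes under destination labels", {
  freqs <- sim_allele_freqs(n_pops = 3, n_loci = 14, n_alleles = 8,
                            fst = 0.15, seed = 7)
  sim <- sim_genotypes(freqs, n_per_pop = 10, seed = 8)
  none <- plant_migrants(sim$table, freqs,
                         tibble::tibble(from = "P1", to = "P2", n = 0), seed = 9)
  srt <- function(x) dplyr::arrange(tibble::as_tibble(x), id, locus)
  expect_equal(srt(none$table), srt(sim$table))
  expect_equal(nrow(none$truth), 0)

  two <- plant_migrants(sim$table, freqs,
                        tibble::tibble(from = "P1", to = "P2", n = 2), seed = 9)
  expect_equal(nrow(two$truth), 2)
  expect_equal(unique(two$truth$source), "P1")
  expect_equal(unique(two$truth$labelled), "P2")
  # labels unchanged: migrants still listed under the destination population
  ind <- gt_individuals(two$table)
  expect_equal(ind$pop[match(two$truth$id, ind$id)], c("P2", "P2"))
  expect_error(plant_migrants(sim$table, freqs,
                              tibble::tibble(from = "P1", to = "P2", n = 99)),
               "only")
})

test_that("replicate simulation reproduces the error model edge cases", {
  freqs <- sim_allele_freqs(n_pops = 1, n_loci = 5, n_alleles = 6, fst = 0, seed = 10)
  sim <- sim_genotypes(freqs, n_per_pop = 15, seed = 11)
  clean <- sim_replicates(sim$table, 0, 0, n_reps = 4, seed = 12)
  cons <- consensus_genotype(clean)
  expect_true(all(cons$quality$qi == 1))
  merged <- dplyr::left_join(clean, tibble::as_tibble(sim$table),
                             by = c("id", "locus"), suffix = c("", "_true"))
  expect_equal(merged$a1, merged$a1_true)

  # full dropout: every heterozygote call becomes homozygous in every replicate
  drop <- sim_replicates(sim$table, dropout_rate = 1, n_reps = 3, seed = 13)
  het_true <- sim$table$a1 != sim$table$a2
  drop_het <- dplyr::semi_join(drop, tibble::as_tibble(sim$table)[het_true, ],
                               by = c("id", "locus"))
  expect_true(all(drop_het$a1 == drop_het$a2, na.rm = TRUE))
  expect_error(sim_replicates(sim$table, dropout_rate = 2), "dropout")
})

test_that("forward migration-drift has the right fixed points", {
  freqs <- sim_allele_freqs(n_pops = 2, n_loci = 3, n_alleles = 4,
                            fst = 0.3, seed = 14)
  # no migration, drift disabled: identity
  m0 <- matrix(0, 2, 2)
  same <- sim_geneflow_forward(freqs, m0, n_e = Inf, generations = 50, seed = 15)
  expect_equal(same$freq, freqs$freq, tolerance = 1e-12)
  # symmetric full mixing, no drift: equal frequencies after one generation
  m5 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  mixed <- sim_geneflow_forward(freqs, m5, n_e = Inf, generations = 1, seed = 16)
  w <- tidyr::pivot_wider(mixed, names_from = "pop", values_from = "freq")
  expect_equal(w$P1, w$P2, tolerance = 1e-12)
  freqs3 <- sim_allele_freqs(n_pops = 3, n_loci = 2, n_alleles = 3,
                             fst = 0.1, seed = 20)
  expect_error(sim_geneflow_forward(freqs3, matrix(0.6, 3, 3), n_e = 100),
               "sum to <= 1")
  expect_error(sim_geneflow_forward(freqs, m0, n_e = 5), "n_e")
})

test_that("landscape rasters obey their value contracts and determinism", {
  land <- sim_landscape(grid_dim = c(40, 40), n_settlements = 8, seed = 17)
  expect_true(all(land$tree$values >= 0 & land$tree$values <= 67))
  expect_true(all(land$landcover$values %in% c(0, 1)))
  expect_true(any(land$lights$values > 20)) # some urban centres exist
  expect_equal(dim(land$tree), dim(land$lights))
  dark <- sim_landscape(grid_dim = c(30, 30), n_settlements = 0,
                        n_roads = 2, seed = 18)
  expect_true(all(dark$lights$values == 0))
  again <- sim_landscape(grid_dim = c(40, 40), n_settlements = 8, seed = 17)
  expect_identical(land$lights$values, again$lights$values)
  expect_identical(land$roads, again$roads)
})

test_that("a ring settlement barrier raises the walled pair's effective resistance", {
  land <- sim_landscape(seed = 19, n_settlements = 8, center_patch = TRUE,
                        barrier = list(type = "ring", patch = 1, width_km = 6,
                                       n_gaps = 3, gap_km = 3))
  hab <- habitat_resistance(land$landcover)
  setl <- settlement_resistance(land$lights)
  valid <- study_area(hab$patches, setl$urban)
  graph <- build_graph(mask_layer(setl$resistance, valid))
  ctr <- land$truth$patches
  co <- raster_coords(hab$patches)
  on <- !is.na(co$value)
  keep <- vapply(seq_len(nrow(ctr)), function(i) {
    d <- (co$x - ctr$x[i])^2 + (co$y - ctr$y[i])^2
    co$value[on][which.min(d[on])]
  }, numeric(1))
  pv <- hab$patches
  pv$values[!pv$values %in% keep] <- NA
  pv$values <- matrix(match(pv$values, keep), nrow(pv$values))
  regions <- regions_from_patches(graph, mask_layer(pv, valid))
  R <- pairwise_resistance(graph, regions, current_map = FALSE)$r
  # walled (centre) population costs more to reach than unwalled neighbours
  expect_gt(R[1, 2], R[2, 3])
  expect_gt(mean(R[1, -1]), mean(R[-1, -1][upper.tri(R[-1, -1])]))
})
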