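test_that("allele frequencies are counts over typed gene copies", {
  tab <- gt_from_calls(list(P1 = list(
    s1 = list(c(1, 1)), s2 = list(c(1, 1)), s3 = list(c(1, 1)),
    s4 = list(c(1, 1)), s5 = list(c(1, 1)),
    s6 = list(c(2, 2)), s7 = list(c(2, 2)), s8 = list(c(2, 2)),
    s9 = list(c(2, 2)), s10 = list(c(2, 2)))), loci = "L1")
  af <- allele_frequencies(tab)
  expect_equal(af$n, c(20, 20))
  expect_equal(af$freq[af$allele == 1], 0.5)
})

test_that("diversity gives He with the small-sample correction and exact HWE behaviour", {
  # (AA, Aa, aa) = (25, 50, 25): exact Hardy-Weinberg proportions
  hw <- gt_from_calls(list(P1 = c(
    lapply(1:25, function(i) list(c(1, 1))),
    lapply(1:50, function(i) list(c(1, 2))),
    lapply(1:25, function(i) list(c(2, 2))))), loci = "L1")
  d <- diversity(hw, n_shuffle = 2000, seed = 5)
  expect_equal(d$al, 2)
  expect_equal(d$ho, 0.5)
  expect_equal(d$he, 200 / 199 * 0.5)
  expect_gt(d$hwe_p, 0.5)

  # (0, 50, 0): extreme heterozygote excess
  hx <- gt_from_calls(list(P1 = lapply(1:50, function(i) list(c(1, 2)))),
                      loci = "L1")
  dx <- diversity(hx, n_shuffle = 2000, seed = 5)
  expect_lt(dx$hwe_p, 0.001)

  # monomorphic locus
  mono <- gt_from_calls(list(P1 = lapply(1:10, function(i) list(c(3, 3)))),
                        loci = "L1")
  dm <- diversity(mono)
  expect_equal(dm$he, 0)
  expect_equal(dm$hwe_p, 1)
})

test_that("HWE Monte-Carlo p-values are roughly uniform under Hardy-Weinberg", {
  freqs <- sim_allele_freqs(n_pops = 1, n_loci = 200, n_alleles = 4,
                            fst = 0, seed = 31)
  sim <- sim_genotypes(freqs, n_per_pop = 50, seed = 32)
  d <- diversity(sim$table, n_shuffle = 500, seed = 33)
  ks <- suppressWarnings(stats::ks.test(d$hwe_p, "punif"))
  expect_gt(ks$p.value, 0.05)
  expect_gt(mean(d$hwe_p < 0.5), 0.3) # not degenerate either
})

test_that("P_ID-sibs matches the closed form and multiplies across loci", {
  f2 <- tibble::tibble(pop = "P1", locus = "L1", allele = 1:2,
                       freq = c(0.5, 0.5), n = NA_real_)
  expect_equal(pid_sibs(f2)$overall, 0.59375)
  mono <- tibble::tibble(pop = "P1", locus = "L1", allele = 1,
                         freq = 1, n = NA_real_)
  expect_equal(pid_sibs(mono)$overall, 1)
  two <- rbind(f2, transform(f2, locus = "L2"))
  expect_equal(pid_sibs(two)$overall, 0.59375^2)
  expect_equal(pid_sibs(two)$overall, 0.3525390625)
  expect_error(pid_sibs(f2, loci = character(0)), "empty")
})

test_that("P_ID-sibs per locus lies in (0, 1] and is non-increasing as loci accrue", {
  freqs <- sim_allele_freqs(n_pops = 1, n_loci = 14, n_alleles = 10,
                            fst = 0, seed = 44)
  res <- pid_sibs(freqs)
  expect_true(all(res$per_locus$pid_sibs > 0 & res$per_locus$pid_sibs <= 1))
  run <- cumprod(res$per_locus$pid_sibs)
  expect_true(all(diff(run) <= 0))
  expect_equal(res$overall, run[length(run)])
})

test_that("Weir-Cockerham theta matches the variance-component oracle", {
  # two pops fixed for different alleles -> theta 1
  fixed <- gt_from_calls(list(
    P1 = lapply(1:8, function(i) list(c(1, 1), c(1, 1))),
    P2 = lapply(1:8, function(i) list(c(2, 2), c(2, 2)))),
    loci = c("L1", "L2"))
  expect_equal(fst_wc(fixed)$theta, 1)

  # pop1 = 10 AA, pop2 = 5 AA + 5 aa at one locus: hand-computed components
  # a = 2 * 0.1111..., b = 2 * 0.138888..., c = 0 -> theta = 4/9
  mixed <- gt_from_calls(list(
    P1 = lapply(1:10, function(i) list(c(1, 1))),
    P2 = c(lapply(1:5, function(i) list(c(1, 1))),
           lapply(1:5, function(i) list(c(2, 2))))), loci = "L1")
  expect_equal(fst_wc(mixed)$theta, 4 / 9, tolerance = 1e-12)

  # identical source frequencies -> theta near zero
  freqs <- sim_allele_freqs(n_pops = 2, n_loci = 14, n_alleles = 10,
                            fst = 0, seed = 51)
  sim <- sim_genotypes(freqs, n_per_pop = 100, seed = 52)
  expect_lt(abs(fst_wc(sim$table)$theta), 0.02)
})

test_that("theta is symmetric in population order and invariant to relabelling", {
  freqs <- sim_allele_freqs(n_pops = 3, n_loci = 10, n_alleles = 6,
                            fst = 0.1, seed = 61)
  sim <- sim_genotypes(freqs, n_per_pop = 12, seed = 62)
  t12 <- fst_wc(sim$table, pops = c("P1", "P2"))$theta
  t21 <- fst_wc(sim$table, pops = c("P2", "P1"))$theta
  expect_equal(t12, t21)
  relab <- sim$table
  relab$a1 <- 100 - relab$a1 # strictly decreasing code map
  relab$a2 <- 100 - relab$a2
  relab <- genotype_table(tibble::as_tibble(relab))
  expect_equal(fst_wc(relab, pops = c("P1", "P2"))$theta, t12)
})

test_that("theta recovers the generating divergence and permutation p works", {
  # F-model recovery at one F (full grid in the acceptance suite)
  th <- vapply(1:6, function(s) {
    freqs <- sim_allele_freqs(n_pops = 6, n_loci = 14, n_alleles = 10,
                              fst = 0.10, seed = 100 + s)
    sim <- sim_genotypes(freqs, n_per_pop = 50, seed = 200 + s)
    fst_wc(sim$table)$theta
  }, numeric(1))
  expect_lt(abs(mean(th) - 0.10), 0.03)

  freqs <- sim_allele_freqs(n_pops = 2, n_loci = 10, n_alleles = 8,
                            fst = 0.15, seed = 71)
  sim <- sim_genotypes(freqs, n_per_pop = 15, seed = 72)
  est <- fst_wc(sim$table, n_perm = 199, seed = 73)
  expect_lt(est$p, 0.05) # strongly diverged pair should be significant
  expect_gt(est$se, 0)
})

test_that("allele-sharing distance counts shared alleles correctly", {
  # AB vs AC at one locus: shared proportion 0.5 -> one_minus variant 0.5
  ab_ac <- gt_from_calls(list(P1 = list(s1 = list(c(1, 2))),
                              P2 = list(s2 = list(c(1, 3)))), loci = "L1")
  est <- dsp(ab_ac, "P1", "P2", variant = "one_minus")
  expect_equal(est$ps, 0.5)
  expect_equal(est$value, 0.5)

  # identical tables -> ps 1, D_SP 0
  same <- gt_from_calls(list(P1 = list(s1 = list(c(1, 2), c(3, 3))),
                             P2 = list(s2 = list(c(1, 2), c(3, 3)))),
                        loci = c("L1", "L2"))
  expect_equal(dsp(same, "P1", "P2")$value, 0)

  # disjoint allele sets -> one_minus = 1, minus_ln = Inf with flag
  disj <- gt_from_calls(list(P1 = list(s1 = list(c(1, 1))),
                             P2 = list(s2 = list(c(2, 2)))), loci = "L1")
  expect_equal(dsp(disj, "P1", "P2", variant = "one_minus")$value, 1)
  ml <- dsp(disj, "P1", "P2")
  expect_true(is.infinite(ml$value) && ml$infinite)
})

test_that("D_SP (-ln variant) is nonnegative, zero iff sharing is complete, and monotone in divergence", {
  ds <- vapply(c(0.02, 0.1, 0.3), function(f) {
    freqs <- sim_allele_freqs(n_pops = 2, n_loci = 14, n_alleles = 8,
                              fst = f, seed = 81)
    sim <- sim_genotypes(freqs, n_per_pop = 20, seed = 82)
    dsp(sim$table, "P1", "P2")$value
  }, numeric(1))
  expect_true(all(ds > 0))
  expect_true(all(diff(ds) > 0))
})

test_that("ML relatedness recovers extremes and categories", {
  # identical multilocus genotypes at rare-allele loci -> k2 ~ 1, r ~ 1
  loci <- sprintf("L%02d", 1:14)
  rare <- genotype_table(rbind(
    data.frame(id = "a", pop = "P1", locus = loci, a1 = 1, a2 = 2),
    data.frame(id = "b", pop = "P1", locus = loci, a1 = 1, a2 = 2)))
  # reference frequencies: alleles 1 and 2 rare, allele 3 common
  freqs <- new_freqs <- tibble::tibble(
    pop = "ALL", locus = rep(loci, each = 3), allele = rep(1:3, 14),
    freq = rep(c(0.05, 0.05, 0.9), 14), n = NA_real_)
  est <- ml_relatedness(rare, pairs = data.frame(id1 = "a", id2 = "b"),
                        freqs = freqs)
  expect_gt(est$k2, 0.95)
  expect_gt(est$r, 0.95)

  # unrelated pairs: mean r near zero (upward-bounded boundary bias)
  f0 <- sim_allele_freqs(n_pops = 1, n_loci = 30, n_alleles = 2,
                         fst = 0, seed = 91)
  sim <- sim_genotypes(f0, n_per_pop = 40, seed = 92)
  ids <- gt_individuals(sim$table)$id
  prs <- data.frame(id1 = ids[seq(1, 39, by = 2)], id2 = ids[seq(2, 40, by = 2)])
  est0 <- ml_relatedness(sim$table, pairs = prs)
  expect_lt(abs(mean(est0$r)), 0.15)
  expect_true(all(abs(est0$k0 + est0$k1 + est0$k2 - 1) < 1e-9))
})

test_that("parent-offspring pairs are classified PO in the majority of cases", {
  f0 <- sim_allele_freqs(n_pops = 1, n_loci = 14, n_alleles = 10,
                         fst = 0, seed = 95)
  fa <- corridorgen:::freq_arrays(f0)
  loci <- names(fa)
  withr::with_seed(96, {
    rows <- list()
    for (i in 1:40) {
      for (l in loci) {
        p <- fa[[l]]$freq[1, ]
        codes <- fa[[l]]$codes
        par <- sample(codes, 2, replace = TRUE, prob = p)
        kid <- c(sample(par, 1), sample(codes, 1, prob = p))
        rows[[length(rows) + 1]] <- data.frame(
          id = c(sprintf("par%02d", i), sprintf("kid%02d", i)), pop = "P1",
          locus = l, a1 = c(min(par), min(kid)), a2 = c(max(par), max(kid)))
      }
    }
  })
  tab <- genotype_table(do.call(rbind, rows))
  prs <- data.frame(id1 = sprintf("par%02d", 1:40),
                    id2 = sprintf("kid%02d", 1:40))
  est <- ml_relatedness(tab, pairs = prs)
  expect_gt(mean(est$category == "PO"), 0.5)
  expect_gt(mean(est$r), 0.35) # true r = 0.5
})
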