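# Per-locus reference-count arrays for assignment likelihoods:
# for each locus, the pop x allele gene-copy count matrix over ALL
# populations, total copies per pop, and k = alleles observed at the locus
# across all populations (the Dirichlet prior is 1/k per allele).
assign_arrays <- function(arr) {
  pops <- arr$pop_levels
  lapply(seq_along(arr$loci), function(l) {
    copies <- c(arr$a1[, l], arr$a2[, l])
    codes <- sort(unique(stats::na.omit(copies)))
    cnt <- matrix(0, length(pops), length(codes),
                  dimnames = list(pops, as.character(codes)))
    for (p in seq_along(pops)) {
      cp <- c(arr$a1[arr$pops == pops[p], l], arr$a2[arr$pops == pops[p], l])
      tb <- table(factor(cp, levels = codes))
      cnt[p, ] <- as.numeric(tb)
    }
    list(codes = codes, cnt = cnt, n = rowSums(cnt), k = length(codes))
  })
}

# log10 posterior-predictive probability of diploid genotypes under the
# Rannala-Mountain criterion, vectorised over individuals for one
# population. a_idx/b_idx: per-locus allele indices (lists over loci),
# NA = untyped. `la` = assign_arrays() element list; `adjust` optionally
# subtracts an individual's own gene copies (leave-one-out).
rm_loglik10_pop <- function(la, a_idx, b_idx, pop, own = NULL) {
  n_ind <- length(a_idx[[1]])
  ll <- numeric(n_ind)
  for (l in seq_along(la)) {
    ai <- a_idx[[l]]; bi <- b_idx[[l]]
    ok <- !is.na(ai)
    if (!any(ok)) next
    cnt <- la[[l]]$cnt[pop, ]
    n <- la[[l]]$n[pop]
    k <- la[[l]]$k
    na <- cnt[ai[ok]]
    nb <- cnt[bi[ok]]
    nn <- rep(n, sum(ok))
    if (!is.null(own)) { # remove the individual's own two copies
      w <- which(ok)
      na <- na - (own[[l]]$a[w])
      nb <- nb - (own[[l]]$b[w])
      nn <- nn - own[[l]]$two[w]
    }
    het <- ai[ok] != bi[ok]
    term <- log10((na + 1 / k) / (nn + 1)) +
      log10((nb + 1 / k + !het) / (nn + 2)) +
      het * log10(2)
    ll[ok] <- ll[ok] + term
  }
  ll
}

#' Rannala-Mountain assignment likelihood
#'
#' log10 posterior-predictive probability of a diploid multilocus genotype
#' in a reference population: alleles are drawn sequentially from a
#' Dirichlet(1/k per allele) posterior on the population's observed
#' gene-copy counts, where k is the number of alleles observed at the locus
#' across all populations — first allele `(n_a + 1/k) / (n + 1)`, second
#' `(n_b + 1/k + delta_ab) / (n + 2)`, doubled for heterozygotes. Missing
#' loci are skipped. An allele unseen in the reference population keeps
#' finite likelihood through the prior mass `1/k`.
#'
#' @param table A [genotype_table()] supplying the reference counts (all
#'   populations; k is taken across all of them).
#' @param genotype Data frame (`locus`, `a1`, `a2`) for one individual.
#' @param pop Reference population label.
#' @return log10 likelihood (scalar).
#' @export
rm_likelihood <- function(table, genotype, pop) {
  arr <- gt_array(table)
  la <- assign_arrays(arr)
  pi <- match(pop, arr$pop_levels)
  stopifnot(!is.na(pi))
  a_idx <- b_idx <- vector("list", length(arr$loci))
  for (l in seq_along(arr$loci)) {
    row <- genotype[genotype$locus == arr$loci[l], ]
    if (nrow(row) == 1 && !is.na(row$a1)) {
      a_idx[[l]] <- match(as.character(row$a1), names(la[[l]]$cnt[pi, ]))
      b_idx[[l]] <- match(as.character(row$a2), names(la[[l]]$cnt[pi, ]))
      if (is.na(a_idx[[l]]) || is.na(b_idx[[l]])) {
        stop("genotype carries an allele unseen at locus ", arr$loci[l],
             " in the reference table")
      }
    } else {
      a_idx[[l]] <- NA_integer_; b_idx[[l]] <- NA_integer_
    }
  }
  rm_loglik10_pop(la, a_idx, b_idx, pi)
}

# allele-index matrices (ind x loci) into each locus's code set
geno_indices <- function(arr, la) {
  L <- length(arr$loci)
  a_idx <- b_idx <- vector("list", L)
  for (l in seq_len(L)) {
    a_idx[[l]] <- match(arr$a1[, l], la[[l]]$codes)
    b_idx[[l]] <- match(arr$a2[, l], la[[l]]$codes)
  }
  list(a = a_idx, b = b_idx)
}

# log10 likelihood matrix (individuals x populations); rows' home pops get
# leave-one-out counts.
assignment_loglik <- function(arr, la, loo = TRUE) {
  gi <- geno_indices(arr, la)
  pops <- arr$pop_levels
  n_ind <- length(arr$ids)
  L <- length(arr$loci)
  ll <- matrix(0, n_ind, length(pops), dimnames = list(arr$ids, pops))
  for (p in seq_along(pops)) {
    own <- NULL
    if (loo) {
      # rows whose home is p lose their own gene copies: a homozygote
      # carries 2 copies of its allele, a heterozygote 1 of each.
      own <- lapply(seq_len(L), function(l) {
        home <- arr$pops == pops[p] & !is.na(gi$a[[l]])
        hom <- home & gi$a[[l]] == gi$b[[l]]
        het <- home & !hom
        list(a = 2 * hom + het, b = 2 * hom + het, two = 2 * home)
      })
    }
    ll[, p] <- rm_loglik10_pop(la, gi$a, gi$b, p, own = own)
  }
  ll
}

#' First-generation migrant detection with a resampling null
#'
#' For every individual the statistic is
#' `Lambda = max_j log10 L_j - log10 L_home` (zero when the genotype is
#' likeliest at home), where likelihoods follow [rm_likelihood()] and the
#' home likelihood removes the individual's own gene copies (leave-one-out).
#' The null distribution of Lambda for each home population is built from
#' `n_sim` genotypes simulated by drawing alleles with replacement from that
#' population's observed allele frequencies (Monte-Carlo resampling);
#' `p_resident` is the fraction of null Lambda at least as large as the
#' observed one (ties counted, conservative), and an individual is flagged
#' as a first-generation migrant when `p_resident < alpha`.
#'
#' @param table A [genotype_table()] (at least 2 populations).
#' @param alpha Flagging threshold on `p_resident`.
#' @param n_sim Simulated genotypes per home population.
#' @param seed Integer seed.
#' @return Tibble with `id`, `pop`, `assigned`, `lambda`, `p_resident`,
#'   `flagged`, plus per-population log10 likelihood columns `ll_<pop>`.
#' @export
detect_migrants <- function(table, alpha = 0.01, n_sim = 10000, seed = 1) {
  arr <- gt_array(table)
  stopifnot(length(arr$pop_levels) >= 2)
  small <- table(arr$pops)
  if (any(small < 3)) {
    warning("populations with fewer than 3 individuals: ",
            paste(names(small)[small < 3], collapse = ", "),
            " (resampling null poorly calibrated)")
  }
  la <- assign_arrays(arr)
  ll <- assignment_loglik(arr, la, loo = TRUE)
  home_idx <- match(arr$pops, arr$pop_levels)
  l_home <- ll[cbind(seq_along(arr$ids), home_idx)]
  l_max <- apply(ll, 1, max)
  lambda <- l_max - l_home
  assigned <- arr$pop_levels[max.col(ll, ties.method = "first")]

  null_lambda <- withr::with_seed(seed, {
    lapply(seq_along(arr$pop_levels), function(p) {
      sim <- simulate_genotype_indices(la, p, n_sim)
      lls <- vapply(seq_along(arr$pop_levels), function(q) {
        rm_loglik10_pop(la, sim$a, sim$b, q)
      }, numeric(n_sim))
      apply(lls, 1, max) - lls[, p]
    })
  })
  p_res <- vapply(seq_along(arr$ids), function(i) {
    mean(null_lambda[[home_idx[i]]] >= lambda[i] - 1e-12)
  }, numeric(1))
  out <- tibble::tibble(id = arr$ids, pop = arr$pops, assigned = assigned,
                        lambda = lambda, p_resident = p_res,
                        flagged = p_res < alpha)
  dplyr::bind_cols(out, tibble::as_tibble(ll, .name_repair = ~ paste0("ll_", .x)))
}

# draw n_sim multilocus genotypes from pop p's observed frequencies
simulate_genotype_indices <- function(la, p, n_sim) {
  L <- length(la)
  a <- b <- vector("list", L)
  for (l in seq_len(L)) {
    cnt <- la[[l]]$cnt[p, ]
    if (sum(cnt) == 0) { # locus untyped in this population
      a[[l]] <- rep(NA_integer_, n_sim)
      b[[l]] <- rep(NA_integer_, n_sim)
      next
    }
    a[[l]] <- sample.int(length(cnt), n_sim, replace = TRUE, prob = cnt)
    b[[l]] <- sample.int(length(cnt), n_sim, replace = TRUE, prob = cnt)
    sw <- a[[l]] > b[[l]] # canonical order, irrelevant to the likelihood
    tmp <- a[[l]][sw]; a[[l]][sw] <- b[[l]][sw]; b[[l]][sw] <- tmp
  }
  list(a = a, b = b)
}

#' Migrant posterior under a migration prior
#'
#' Competing hypotheses for each individual: resident (prior `1 - nu`),
#' first-generation (F0) migrant from each other population (total prior
#' `nu/2`, split equally), and F1 offspring of one migrant parent from each
#' other population (total prior `nu/2`, split equally). Resident and F0
#' likelihoods follow [rm_likelihood()] (leave-one-out counts for the home
#' population); the F1 likelihood draws one allele from the home posterior
#' and one from the source posterior, summed over phase. Posteriors are
#' prior times likelihood, normalised per individual.
#'
#' @param table A [genotype_table()].
#' @param nu Prior migrant probability in `[0, 1)`; `nu = 0` forces
#'   resident posteriors of 1.
#' @return List with `summary` (tibble `id`, `pop`, `p_resident`,
#'   `migrant_prob`, `best_source`, `flagged_0.9`) and `posterior` (long
#'   tibble `id`, `pop`, `hypothesis`, `source`, `prior`, `posterior`).
#' @export
migrant_posterior <- function(table, nu = 0.05) {
  if (nu < 0 || nu >= 1) stop("nu must be in [0, 1)")
  arr <- gt_array(table)
  pops <- arr$pop_levels
  K <- length(pops)
  la <- assign_arrays(arr)
  ll <- assignment_loglik(arr, la, loo = TRUE)    # resident/F0 table
  gi <- geno_indices(arr, la)
  home_idx <- match(arr$pops, pops)

  rows <- list()
  for (i in seq_along(arr$ids)) {
    h <- home_idx[i]
    hyp <- tibble::tibble(hypothesis = "resident", source = pops[h],
                          prior = 1 - nu, ll10 = ll[i, h])
    others <- setdiff(seq_len(K), h)
    if (nu > 0 && length(others) > 0) {
      pr_each <- nu / 2 / length(others)
      f0 <- tibble::tibble(hypothesis = "F0", source = pops[others],
                           prior = pr_each, ll10 = ll[i, others])
      f1ll <- vapply(others, function(j) f1_loglik10(arr, la, gi, i, h, j),
                     numeric(1))
      f1 <- tibble::tibble(hypothesis = "F1", source = pops[others],
                           prior = pr_each, ll10 = f1ll)
      hyp <- dplyr::bind_rows(hyp, f0, f1)
    }
    lw <- log(hyp$prior) + hyp$ll10 * log(10)
    lw <- lw - max(lw)
    hyp$posterior <- exp(lw) / sum(exp(lw))
    hyp$id <- arr$ids[i]
    hyp$pop <- arr$pops[i]
    rows[[i]] <- hyp
  }
  post <- dplyr::bind_rows(rows) |>
    dplyr::select("id", "pop", "hypothesis", "source", "prior", "posterior")
  summary <- post |>
    dplyr::group_by(.data$id, .data$pop) |>
    dplyr::summarise(
      p_resident = sum(.data$posterior[.data$hypothesis == "resident"]),
      migrant_prob = 1 - .data$p_resident,
      best_source = {
        mig <- dplyr::filter(dplyr::pick(dplyr::everything()),
                             .data$hypothesis != "resident")
        if (nrow(mig) == 0) NA_character_ else
          mig$source[which.max(mig$posterior)]
      },
      .groups = "drop") |>
    dplyr::mutate(flagged_0.9 = .data$migrant_prob > 0.9)
  list(summary = summary, posterior = post)
}

# F1 hypothesis: one gene copy from home (leave-one-out), one from source j,
# summed over phase; log10 over typed loci.
f1_loglik10 <- function(arr, la, gi, i, h, j) {
  total <- 0
  for (l in seq_along(la)) {
    ai <- gi$a[[l]][i]; bi <- gi$b[[l]][i]
    if (is.na(ai)) next
    k <- la[[l]]$k
    hom <- ai == bi
    # home counts leave-one-out
    cnt_h <- la[[l]]$cnt[h, ]
    n_h <- la[[l]]$n[h] - 2
    cnt_h[ai] <- cnt_h[ai] - 1
    cnt_h[bi] <- cnt_h[bi] - 1
    p_h <- function(x) (cnt_h[x] + 1 / k) / (n_h + 1)
    cnt_j <- la[[l]]$cnt[j, ]
    n_j <- la[[l]]$n[j]
    p_j <- function(x) (cnt_j[x] + 1 / k) / (n_j + 1)
    pr <- if (hom) p_h(ai) * p_j(ai) else p_h(ai) * p_j(bi) + p_h(bi) * p_j(ai)
    total <- total + log10(pr)
  }
  total
}

#' Assignment-derived migration-rate matrices
#'
#' Builds a row-stochastic matrix `m` with `m[i, j]` the fraction of
#' individuals sampled in population i attributed to source j — from
#' migrant-detection calls (an unflagged individual counts as resident;
#' a flagged one counts toward its assigned population) or from migrant
#' posteriors (posterior mass on each source). The immigration matrix is
#' `m` with the diagonal zeroed (rates into the sampled population) and the
#' emigration matrix its transpose; the vectors are their row means over
#' sources.
#'
#' @param calls Tibble from [detect_migrants()], or the `posterior` element
#'   of [migrant_posterior()].
#' @param pops Population labels defining matrix order.
#' @return List with `m`, `immigration`, `emigration` (matrices) and
#'   `immigration_rate`, `emigration_rate` (named vectors).
#' @export
migration_matrices <- function(calls, pops = NULL) {
  if ("posterior" %in% names(calls)) { # long posterior tibble
    if (is.null(pops)) pops <- unique(calls$pop)
    K <- length(pops)
    m <- matrix(0, K, K, dimnames = list(pops, pops))
    n_i <- table(factor(unique(calls[, c("id", "pop")])$pop, levels = pops))
    for (r in seq_len(nrow(calls))) {
      i <- match(calls$pop[r], pops)
      j <- match(calls$source[r], pops)
      m[i, j] <- m[i, j] + calls$posterior[r]
    }
    m <- sweep(m, 1, as.numeric(n_i), "/")
  } else {
    if (is.null(pops)) pops <- unique(calls$pop)
    K <- length(pops)
    m <- matrix(0, K, K, dimnames = list(pops, pops))
    src <- ifelse(calls$flagged, calls$assigned, calls$pop)
    for (r in seq_len(nrow(calls))) {
      m[match(calls$pop[r], pops), match(src[r], pops)] <-
        m[match(calls$pop[r], pops), match(src[r], pops)] + 1
    }
    m <- m / rowSums(m)
  }
  if (any(is.nan(m))) warning("empty population: undefined migration row")
  imm <- m; diag(imm) <- 0
  emi <- t(imm)
  list(m = m, immigration = imm, emigration = emi,
       immigration_rate = rowSums(imm) ,
       emigration_rate = rowSums(emi))
}
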