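#' Observed allele frequencies per population and locus
#'
#' Frequencies are allele counts over typed gene copies, per population per
#' locus. A locus untyped in a population contributes no rows there.
#'
#' @param table A [genotype_table()].
#' @return Allele-frequency tibble with columns `pop`, `locus`, `allele`,
#'   `count` (gene copies of that allele), `freq`, and `n` (total typed gene
#'   copies at that population x locus).
#' @export
allele_frequencies <- function(table) {
  stopifnot(nrow(table) > 0)
  out <- table |>
    dplyr::filter(!is.na(.data$a1)) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::count(.data$pop, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::select("pop", "locus", "allele", "count", "freq", "n")
  new_allele_freqs(out)
}

#' Per-locus genetic diversity and Hardy-Weinberg tests
#'
#' Computes, per locus over all individuals pooled: number of alleles (Al),
#' unbiased expected heterozygosity `He = n/(n-1) * (1 - sum p^2)` (n = gene
#' copies), observed heterozygosity Ho, and a Hardy-Weinberg exact test
#' p-value by Monte-Carlo shuffling of gene copies within the locus
#' (two-sided on the conditional probability of the genotype configuration).
#'
#' @param table A [genotype_table()].
#' @param n_shuffle Monte-Carlo shuffles for the HWE test.
#' @param seed Integer seed for the shuffles.
#' @return Tibble with columns `locus`, `al`, `n_typed`, `he`, `ho`,
#'   `hwe_p`.
#' @export
diversity <- function(table, n_shuffle = 10000, seed = 1) {
  arr <- gt_array(table)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(arr$loci), function(l) {
      a1 <- arr$a1[, l]; a2 <- arr$a2[, l]
      ok <- !is.na(a1)
      a1 <- a1[ok]; a2 <- a2[ok]
      n_ind <- length(a1)
      copies <- c(a1, a2)
      p <- as.numeric(table(copies)) / length(copies)
      he <- if (length(copies) > 1) {
        length(copies) / (length(copies) - 1) * (1 - sum(p^2))
      } else 0
      tibble::tibble(
        locus = arr$loci[l],
        al = length(unique(copies)),
        n_typed = n_ind,
        he = he,
        ho = mean(a1 != a2),
        hwe_p = hwe_exact_mc(a1, a2, n_shuffle))
    })
  })
}

# Monte-Carlo HWE exact test. Statistic: conditional probability of the
# genotype configuration given allele counts; since allele counts are fixed
# under gene-copy shuffles this reduces to sum(-lfactorial(genotype counts))
# + n_het * log 2. p = Pr(stat_perm <= stat_obs), +1-corrected.
hwe_exact_mc <- function(a1, a2, n_shuffle) {
  if (length(unique(c(a1, a2))) < 2) return(1)
  stat <- function(x1, x2) {
    key <- paste(pmin(x1, x2), pmax(x1, x2))
    cnt <- table(key)
    sum(x1 != x2) * log(2) - sum(lfactorial(cnt))
  }
  obs <- stat(a1, a2)
  copies <- c(a1, a2)
  n <- length(a1)
  hits <- 0L
  for (b in seq_len(n_shuffle)) {
    perm <- sample(copies)
    if (stat(perm[seq_len(n)], perm[n + seq_len(n)]) <= obs + 1e-9) hits <- hits + 1L
  }
  (hits + 1) / (n_shuffle + 1)
}

#' Probability of identity among siblings
#'
#' Per-locus `PIDsib = 0.25 + 0.5*sum(p^2) + 0.5*(sum(p^2))^2 -
#' 0.25*sum(p^4)`; the overall value is the product across loci — the
#' probability that two full siblings share an identical multilocus
#' genotype, the conservative bound used when declaring two samples the
#' same individual.
#'
#' @param freqs Allele-frequency tibble. If several populations are present
#'   their frequencies are pooled, weighted by gene-copy counts when
#'   available.
#' @param loci Loci to use (default: all loci in `freqs`).
#' @return List with `per_locus` (tibble `locus`, `pid_sibs`) and `overall`.
#' @export
pid_sibs <- function(freqs, loci = NULL) {
  if (is.null(loci)) loci <- unique(freqs$locus)
  if (length(loci) == 0) stop("empty locus list")
  pooled <- freqs |>
    dplyr::filter(.data$locus %in% loci) |>
    dplyr::mutate(w = ifelse(is.na(.data$n), 1, .data$n)) |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::summarise(freq = sum(.data$freq * .data$w), .groups = "drop_last") |>
    dplyr::mutate(freq = .data$freq / sum(.data$freq)) |>
    dplyr::ungroup()
  per_locus <- pooled |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      pid_sibs = 0.25 + 0.5 * sum(.data$freq^2) +
        0.5 * sum(.data$freq^2)^2 - 0.25 * sum(.data$freq^4),
      .groups = "drop")
  list(per_locus = per_locus, overall = prod(per_locus$pid_sibs))
}

# Weir-Cockerham (1984) variance components for one locus over r pops.
# Input: list per pop of (a1, a2) integer vectors (typed individuals only).
# Returns c(a, b, c) summed over alleles, or NULL if < 2 pops typed.
wc_components <- function(geno_by_pop) {
  geno_by_pop <- geno_by_pop[vapply(geno_by_pop, function(g) length(g$a1) > 0, logical(1))]
  r <- length(geno_by_pop)
  if (r < 2) return(NULL)
  n_i <- vapply(geno_by_pop, function(g) length(g$a1), numeric(1))
  alleles <- sort(unique(unlist(lapply(geno_by_pop, function(g) c(g$a1, g$a2)))))
  n_bar <- mean(n_i)
  n_tot <- sum(n_i)
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  out <- c(a = 0, b = 0, c = 0)
  for (A in alleles) {
    p_i <- vapply(geno_by_pop, function(g) mean(c(g$a1, g$a2) == A), numeric(1))
    h_i <- vapply(geno_by_pop,
                  function(g) mean((g$a1 == A) != (g$a2 == A)), numeric(1))
    p_bar <- sum(n_i * p_i) / n_tot
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / n_tot
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    out <- out + c(a, b, cc)
  }
  out
}

#' Weir-Cockerham theta (F_ST)
#'
#' Multilocus theta is the ratio of summed variance components
#' `sum(a) / sum(a + b + c)` over loci; the standard error is a
#' leave-one-locus-out jackknife and significance (optional) comes from
#' permuting individuals among populations.
#'
#' @param table A [genotype_table()].
#' @param pops Populations to include (default: all; give two for a
#'   pairwise estimate).
#' @param n_perm Label permutations for a p-value (0 = skip).
#' @param seed Integer seed for permutations.
#' @return List with `theta`, `se`, `p` (`NA` if not permuted), and
#'   `per_locus` tibble of variance components.
#' @export
fst_wc <- function(table, pops = NULL, n_perm = 0, seed = 1) {
  arr <- gt_array(table)
  if (is.null(pops)) pops <- arr$pop_levels
  sel <- arr$pops %in% pops
  a1 <- arr$a1[sel, , drop = FALSE]
  a2 <- arr$a2[sel, , drop = FALSE]
  labels <- arr$pops[sel]

  theta_of <- function(labels, keep_parts = FALSE) {
    parts <- matrix(NA_real_, length(arr$loci), 3,
                    dimnames = list(arr$loci, c("a", "b", "c")))
    for (l in seq_along(arr$loci)) {
      by_pop <- lapply(pops, function(p) {
        rows <- labels == p & !is.na(a1[, l])
        list(a1 = a1[rows, l], a2 = a2[rows, l])
      })
      comp <- wc_components(by_pop)
      if (!is.null(comp)) parts[l, ] <- comp
    }
    tot <- colSums(parts, na.rm = TRUE)
    denom <- sum(tot)
    th <- if (abs(denom) < 1e-300) NA_real_ else tot[["a"]] / denom
    if (keep_parts) list(theta = th, parts = parts) else th
  }

  obs <- theta_of(labels, keep_parts = TRUE)
  parts <- obs$parts
  ok <- which(!is.na(parts[, 1]))
  # leave-one-locus-out jackknife
  se <- NA_real_
  if (length(ok) > 1) {
    jk <- vapply(ok, function(l) {
      tot <- colSums(parts[setdiff(ok, l), , drop = FALSE])
      tot[["a"]] / sum(tot)
    }, numeric(1))
    se <- sqrt((length(ok) - 1) / length(ok) * sum((jk - mean(jk))^2))
  }
  p <- NA_real_
  if (n_perm > 0 && !is.na(obs$theta)) {
    withr::with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        th <- theta_of(sample(labels))
        if (!is.na(th) && th >= obs$theta - 1e-12) hits <- hits + 1L
      }
      p <- (hits + 1) / (n_perm + 1)
    })
  }
  list(theta = unname(obs$theta), se = se, p = p,
       per_locus = tibble::as_tibble(parts, rownames = "locus"))
}

#' Pairwise F_ST matrix over all populations
#'
#' @inheritParams fst_wc
#' @return List of matrices `fst`, `se`, `p` (population x population;
#'   `p` all `NA` unless `n_perm > 0`).
#' @export
fst_matrix <- function(table, n_perm = 0, seed = 1) {
  pops <- pop_levels(table)
  k <- length(pops)
  f <- s <- p <- matrix(0, k, k, dimnames = list(pops, pops))
  p[] <- NA_real_
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      est <- fst_wc(table, pops = c(pops[i], pops[j]), n_perm = n_perm,
                    seed = seed + 1000 * i + j)
      f[i, j] <- f[j, i] <- est$theta
      s[i, j] <- s[j, i] <- est$se
      p[i, j] <- p[j, i] <- est$p
    }
  }
  list(fst = f, se = s, p = p)
}

#' Allele-sharing genetic distance D_SP between two populations
#'
#' For every inter-population pair of individuals the proportion of shared
#' alleles at each co-typed locus is `sum_alleles min(count1, count2) / 2`;
#' per-pair sharing is the mean over loci and `ps` the mean over pairs.
#' `D_SP = -ln(ps)` (default) or `1 - ps`. The standard error is a
#' leave-one-locus-out jackknife.
#'
#' @param table A [genotype_table()].
#' @param pop_a,pop_b Population labels.
#' @param variant `"minus_ln"` or `"one_minus"`.
#' @return List with `value`, `se`, `ps` and `variant`. If `ps = 0` the
#'   `minus_ln` value is `Inf` (flagged via `infinite = TRUE`).
#' @export
dsp <- function(table, pop_a, pop_b, variant = c("minus_ln", "one_minus")) {
  variant <- match.arg(variant)
  arr <- gt_array(table)
  ia <- which(arr$pops == pop_a)
  ib <- which(arr$pops == pop_b)
  stopifnot(length(ia) > 0, length(ib) > 0)
  L <- length(arr$loci)
  share <- matrix(NA_real_, length(ia) * length(ib), L)
  pair <- 0
  for (i in ia) {
    for (j in ib) {
      pair <- pair + 1
      for (l in seq_len(L)) {
        if (is.na(arr$a1[i, l]) || is.na(arr$a1[j, l])) next
        share[pair, l] <- shared_alleles(arr$a1[i, l], arr$a2[i, l],
                                         arr$a1[j, l], arr$a2[j, l])
      }
    }
  }
  d_of <- function(cols) {
    pm <- rowMeans(share[, cols, drop = FALSE], na.rm = TRUE)
    ps <- mean(pm, na.rm = TRUE)
    if (variant == "minus_ln") -log(ps) else 1 - ps
  }
  value <- d_of(seq_len(L))
  typed <- which(colSums(!is.na(share)) > 0)
  se <- NA_real_
  if (length(typed) > 1 && is.finite(value)) {
    jk <- vapply(typed, function(l) d_of(setdiff(typed, l)), numeric(1))
    se <- sqrt((length(typed) - 1) / length(typed) * sum((jk - mean(jk))^2))
  }
  ps <- if (variant == "minus_ln") exp(-value) else 1 - value
  list(value = value, se = se, ps = ps, variant = variant,
       infinite = !is.finite(value))
}

# proportion of alleles shared by two diploid calls: 0, 0.5 or 1
shared_alleles <- function(x1, x2, y1, y2) {
  (min(sum(c(x1, x2) == y1), sum(c(y1, y2) == y1)) +
     if (y2 != y1) min(sum(c(x1, x2) == y2), sum(c(y1, y2) == y2)) else 0) / 2
}

#' @rdname dsp
#' @return `dsp_matrix()`: list of matrices `dsp` and `se`.
#' @export
dsp_matrix <- function(table, variant = c("minus_ln", "one_minus")) {
  variant <- match.arg(variant)
  pops <- pop_levels(table)
  k <- length(pops)
  d <- s <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      est <- dsp(table, pops[i], pops[j], variant = variant)
      d[i, j] <- d[j, i] <- est$value
      s[i, j] <- s[j, i] <- est$se
    }
  }
  list(dsp = d, se = s)
}

# Per-locus joint probabilities of an unordered genotype pair given 0/1/2
# IBD alleles (Thompson 1975 / Milligan 2003 table). p = named freq vector.
ibd_pair_probs <- function(g1, g2, p) {
  pi_ <- function(a) max(unname(p[as.character(a)]), 1e-10)
  i <- g1[1]; j <- g1[2]; k <- g2[1]; l <- g2[2]
  hom1 <- i == j; hom2 <- k == l
  if (hom1 && hom2) {
    if (i == k) {            # ii,ii
      c(pi_(i)^4, pi_(i)^3, pi_(i)^2)
    } else {                 # ii,jj
      c(pi_(i)^2 * pi_(k)^2, 0, 0)
    }
  } else if (hom1 && !hom2) {
    if (i == k || i == l) {  # ii,ij
      o <- if (i == k) l else k
      c(2 * pi_(i)^3 * pi_(o), pi_(i)^2 * pi_(o), 0)
    } else {                 # ii,jk
      c(2 * pi_(i)^2 * pi_(k) * pi_(l), 0, 0)
    }
  } else if (!hom1 && hom2) {
    Recall(g2, g1, p)
  } else {
    same <- (i == k && j == l)
    shared <- intersect(c(i, j), c(k, l))
    if (same) {              # ij,ij
      c(4 * pi_(i)^2 * pi_(j)^2, pi_(i) * pi_(j) * (pi_(i) + pi_(j)),
        2 * pi_(i) * pi_(j))
    } else if (length(shared) == 1) { # ij,ik
      s <- shared
      o1 <- setdiff(c(i, j), s); o2 <- setdiff(c(k, l), s)
      c(4 * pi_(s)^2 * pi_(o1) * pi_(o2), pi_(s) * pi_(o1) * pi_(o2), 0)
    } else {                 # ij,kl
      c(4 * pi_(i) * pi_(j) * pi_(k) * pi_(l), 0, 0)
    }
  }
}

#' Maximum-likelihood pairwise relatedness
#'
#' The likelihood of a pair of multilocus genotypes is a mixture over
#' sharing 0, 1 or 2 alleles identical by descent, with standard
#' conditional genotype-pair probabilities. `(k0, k1, k2)` is maximised
#' over the simplex by a coarse grid (step 0.01) with local refinement;
#' relatedness is `r = k2 + k1/2` and the best relationship category is the
#' likelihood argmax among U (1,0,0), HS (0.5,0.5,0), FS (0.25,0.5,0.25)
#' and PO (0,1,0).
#'
#' @param table A [genotype_table()].
#' @param pairs Two-column data frame (`id1`, `id2`); default all pairs.
#' @param freqs Reference allele frequencies; default pooled frequencies of
#'   `table` (set `by_pop = TRUE` to use each individual pair's sampled
#'   populations separately is not supported; pass per-population `freqs`
#'   filtered to one population instead).
#' @return Tibble with `id1`, `id2`, `k0`, `k1`, `k2`, `r`, `category`,
#'   `loglik`, `n_loci`.
#' @export
ml_relatedness <- function(table, pairs = NULL, freqs = NULL) {
  arr <- gt_array(table)
  if (is.null(pairs)) {
    idx <- utils::combn(arr$ids, 2)
    pairs <- tibble::tibble(id1 = idx[1, ], id2 = idx[2, ])
  }
  if (is.null(freqs)) {
    pooled <- table
    pooled$pop <- "ALL"
    freqs <- allele_frequencies(genotype_table(pooled))
  }
  p_by_locus <- lapply(split(freqs, factor(freqs$locus, unique(freqs$locus))),
                       function(d) stats::setNames(d$freq / sum(d$freq),
                                                   as.character(d$allele)))
  grid <- k_simplex_grid(0.01)
  cats <- rbind(U = c(1, 0, 0), HS = c(0.5, 0.5, 0),
                FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
  purrr::map2_dfr(pairs$id1, pairs$id2, function(u, v) {
    i <- match(u, arr$ids); j <- match(v, arr$ids)
    probs <- list()
    for (l in seq_along(arr$loci)) {
      if (is.na(arr$a1[i, l]) || is.na(arr$a1[j, l])) next
      loc <- arr$loci[l]
      if (!loc %in% names(p_by_locus)) next
      probs[[length(probs) + 1]] <-
        ibd_pair_probs(c(arr$a1[i, l], arr$a2[i, l]),
                       c(arr$a1[j, l], arr$a2[j, l]), p_by_locus[[loc]])
    }
    if (length(probs) == 0) {
      return(tibble::tibble(id1 = u, id2 = v, k0 = NA_real_, k1 = NA_real_,
                            k2 = NA_real_, r = NA_real_,
                            category = NA_character_, loglik = NA_real_,
                            n_loci = 0L))
    }
    A <- do.call(rbind, probs) # loci x 3
    ll_of <- function(K) rowSums(log(pmax(K %*% t(A), 1e-300)))
    ll <- ll_of(grid)
    best <- grid[which.max(ll), ]
    fine <- k_simplex_refine(best, step = 0.001, halfwidth = 0.01)
    llf <- ll_of(fine)
    best <- fine[which.max(llf), ]
    cat_ll <- ll_of(cats)
    tibble::tibble(id1 = u, id2 = v,
                   k0 = best[1], k1 = best[2], k2 = best[3],
                   r = best[3] + best[2] / 2,
                   category = rownames(cats)[which.max(cat_ll)],
                   loglik = max(llf), n_loci = nrow(A))
  })
}

k_simplex_grid <- function(step) {
  k0 <- seq(0, 1, by = step)
  g <- expand.grid(k0 = k0, k1 = k0)
  g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
  as.matrix(cbind(g$k0, g$k1, pmax(0, 1 - g$k0 - g$k1)))
}

k_simplex_refine <- function(center, step, halfwidth) {
  k0 <- seq(max(0, center[1] - halfwidth), min(1, center[1] + halfwidth), by = step)
  k1 <- seq(max(0, center[2] - halfwidth), min(1, center[2] + halfwidth), by = step)
  g <- expand.grid(k0 = k0, k1 = k1)
  g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
  as.matrix(cbind(g$k0, g$k1, pmax(0, 1 - g$k0 - g$k1)))
}
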