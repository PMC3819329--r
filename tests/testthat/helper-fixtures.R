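# Small constructed genotype tables used across tests.

# n individuals per pop, all given the same diploid call per locus
gt_constant <- function(pops, loci, a1, a2) {
  rows <- do.call(rbind, lapply(names(pops), function(p) {
    do.call(rbind, lapply(seq_len(pops[[p]]), function(i) {
      data.frame(id = sprintf("%s_%02d", p, i), pop = p, locus = loci,
                 a1 = a1, a2 = a2)
    }))
  }))
  genotype_table(rows)
}

# genotype table from an explicit list: list(pop = list(id = list(c(a,b), ...)))
# unnamed individuals get ids s1, s2, ...
gt_from_calls <- function(calls, loci) {
  rows <- list()
  for (p in names(calls)) {
    if (is.null(names(calls[[p]]))) {
      names(calls[[p]]) <- sprintf("%s_s%03d", p, seq_along(calls[[p]]))
    }
    for (id in names(calls[[p]])) {
      g <- calls[[p]][[id]]
      rows[[length(rows) + 1]] <- data.frame(
        id = id, pop = p, locus = loci,
        a1 = vapply(g, `[`, 0, 1), a2 = vapply(g, `[`, 0, 2))
    }
  }
  genotype_table(do.call(rbind, rows))
}

# dense-oracle effective resistance via Laplacian pseudo-inverse (base R)
reff_pinv <- function(graph, region_a, region_b) {
  ct <- corridorgen:::contract_nodes(graph, list(region_a, region_b))
  n <- ct$n_groups
  L <- matrix(0, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- ct$group[graph$edges[e, "i"]]
    j <- ct$group[graph$edges[e, "j"]]
    if (i == j) next
    g <- graph$edges[e, "g"]
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
  }
  Lp <- MASS::ginv(L)
  a <- ct$region_groups[1]; b <- ct$region_groups[2]
  e <- numeric(n); e[a] <- 1; e[b] <- -1
  drop(t(e) %*% Lp %*% e)
}
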