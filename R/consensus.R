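#' Consensus genotypes and quality index from replicate calls
#'
#' Builds a consensus genotype per sample per locus from repeated
#' amplifications, following the multiple-tubes convention: the consensus is
#' the modal diploid call, and a heterozygote is accepted only if observed
#' in at least two replicates (otherwise the best-supported homozygote is
#' taken). Per-locus quality is the fraction of non-missing replicates
#' matching the consensus; the sample quality index (QI) is the mean over
#' loci with data. Samples are retained when `QI >= qi_threshold` (field
#' protocols use 0.75).
#'
#' @param replicates Tibble of replicate calls (`id`, `locus`, `rep`,
#'   `a1`, `a2`), at least 2 replicates per sample x locus.
#' @param qi_threshold Minimum quality index for retention.
#' @param pops Optional named character vector mapping sample id to
#'   population label (otherwise all samples get population "ALL").
#' @return List with `table` (consensus [genotype_table()], retained samples
#'   only) and `quality`, a tibble (`id`, `qi`, `n_typed`, `retained`).
#' @export
consensus_genotype <- function(replicates, qi_threshold = 0.75, pops = NULL) {
  stopifnot(all(c("id", "locus", "rep", "a1", "a2") %in% names(replicates)))
  per_locus <- replicates |>
    dplyr::group_by(.data$id, .data$locus) |>
    dplyr::summarise(consensus_call(.data$a1, .data$a2), .groups = "drop")

  quality <- per_locus |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(qi = mean(.data$quality[!is.na(.data$a1)]),
                     n_typed = sum(!is.na(.data$a1)), .groups = "drop") |>
    dplyr::mutate(qi = ifelse(is.nan(.data$qi), 0, .data$qi),
                  retained = .data$qi >= qi_threshold)

  keep <- quality$id[quality$retained]
  calls <- per_locus |>
    dplyr::filter(.data$id %in% keep) |>
    dplyr::mutate(pop = if (is.null(pops)) "ALL" else unname(pops[.data$id])) |>
    dplyr::select("id", "pop", "locus", "a1", "a2")
  list(table = genotype_table(calls), quality = quality)
}

# Modal diploid call among replicates; heterozygote needs >=2 concordant
# replicates. Returns one-row tibble (a1, a2, quality).
consensus_call <- function(a1, a2) {
  ok <- !is.na(a1)
  if (!any(ok)) {
    return(tibble::tibble(a1 = NA_integer_, a2 = NA_integer_, quality = NA_real_))
  }
  a1 <- a1[ok]; a2 <- a2[ok]
  key <- paste(pmin(a1, a2), pmax(a1, a2))
  counts <- sort(table(key), decreasing = TRUE)
  het <- vapply(strsplit(names(counts), " "),
                function(p) p[1] != p[2], logical(1))
  eligible <- counts >= 2 | !het
  pick <- if (any(eligible)) names(counts)[which(eligible)[1]] else names(counts)[1]
  g <- as.integer(strsplit(pick, " ")[[1]])
  tibble::tibble(a1 = g[1], a2 = g[2],
                 quality = sum(key == pick) / length(key))
}

#' Identify unique individuals from multilocus genotypes
#'
#' Samples typed at fewer than `min_loci` loci are dropped. Remaining pairs
#' are compared at their overlapping typed loci; a pair is merged when the
#' overlap covers at least `min_loci` loci and the genotypes disagree at no
#' more than `max_mismatch` of them. Merging is closed transitively and the
#' representative of each individual is the lexicographically smallest
#' sample id, so the result is independent of input order.
#'
#' @param table A [genotype_table()].
#' @param min_loci Minimum typed loci for a sample to enter, and minimum
#'   overlap for a pair to be comparable.
#' @param max_mismatch Maximum mismatching loci tolerated within a match.
#' @return List with `table` (unique individuals, one representative each),
#'   `duplicates` (tibble `id`, `representative`), and `dropped` (tibble
#'   `id`, `n_typed`, `reason`).
#' @export
identify_individuals <- function(table, min_loci = 12, max_mismatch = 0) {
  arr <- gt_array(table)
  n_typed <- rowSums(!is.na(arr$a1))
  dropped <- tibble::tibble(id = arr$ids[n_typed < min_loci],
                            n_typed = n_typed[n_typed < min_loci],
                            reason = sprintf("typed at fewer than %d loci", min_loci))
  keep <- which(n_typed >= min_loci)
  ids <- arr$ids[keep]
  n <- length(ids)
  edges <- integer(0)
  if (n > 1) {
    a1 <- arr$a1[keep, , drop = FALSE]
    a2 <- arr$a2[keep, , drop = FALSE]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- !is.na(a1[i, ]) & !is.na(a1[j, ])
        if (sum(both) < min_loci) next
        mism <- sum(a1[i, both] != a1[j, both] | a2[i, both] != a2[j, both])
        if (mism <= max_mismatch) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  rep_of <- vapply(split(ids, comp), function(s) min(s), character(1))
  representative <- unname(rep_of[as.character(comp)])
  duplicates <- tibble::tibble(id = ids, representative = representative) |>
    dplyr::filter(.data$id != .data$representative)
  list(table = gt_filter_ids(table, unname(rep_of)),
       duplicates = duplicates, dropped = dropped)
}
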