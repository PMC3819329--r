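#' Genotype tables
#'
#' A genotype table holds diploid microsatellite calls in long (tidy) form:
#' one row per sample per locus, with columns `id`, `pop`, `locus`, `a1`,
#' `a2` and optional per-sample coordinates `x`, `y` (km). Allele codes are
#' positive integers; a missing call has `NA` in both allele columns. Allele
#' pairs are unordered and stored sorted ascending so that comparisons are
#' canonical.
#'
#' @param calls A data frame with columns `id`, `pop`, `locus`, `a1`, `a2`
#'   and optionally `x`, `y`.
#' @param pop_levels Declared population labels in display order. Defaults to
#'   order of first appearance.
#' @return A tibble of class `genotype_tbl`.
#' @export
genotype_table <- function(calls, pop_levels = NULL) {
  stopifnot(all(c("id", "pop", "locus", "a1", "a2") %in% names(calls)))
  calls <- tibble::as_tibble(calls)
  calls$id <- as.character(calls$id)
  calls$pop <- as.character(calls$pop)
  calls$locus <- as.character(calls$locus)
  calls$a1 <- as.integer(calls$a1)
  calls$a2 <- as.integer(calls$a2)
  half <- xor(is.na(calls$a1), is.na(calls$a2))
  if (any(half)) stop("half-missing diploid calls: both alleles or neither must be NA")
  lo <- pmin(calls$a1, calls$a2)
  hi <- pmax(calls$a1, calls$a2)
  calls$a1 <- lo
  calls$a2 <- hi
  if (!"x" %in% names(calls)) calls$x <- NA_real_
  if (!"y" %in% names(calls)) calls$y <- NA_real_
  if (is.null(pop_levels)) pop_levels <- unique(calls$pop)
  if (!all(calls$pop %in% pop_levels)) stop("population label outside declared set")
  structure(calls, pop_levels = pop_levels,
            class = c("genotype_tbl", class(tibble::tibble())))
}

#' @rdname genotype_table
#' @param x A `genotype_tbl`.
#' @export
pop_levels <- function(x) attr(x, "pop_levels")

#' One row per sampled individual
#'
#' @param x A `genotype_tbl`.
#' @return Tibble with `id`, `pop`, `x`, `y` and `n_typed` (loci with data).
#' @export
gt_individuals <- function(x) {
  dplyr::summarise(dplyr::group_by(x, .data$id, .data$pop),
                   x = dplyr::first(.data$x), y = dplyr::first(.data$y),
                   n_typed = sum(!is.na(.data$a1)), .groups = "drop")
}

#' @rdname gt_individuals
#' @export
gt_loci <- function(x) unique(x$locus)

# Dense array view used by the likelihood/statistics hot paths.
# Returns matrices a1, a2 (individuals x loci, allele codes, NA = missing),
# plus ids, pops per individual, locus names and population levels.
gt_array <- function(x) {
  loci <- gt_loci(x)
  ind <- gt_individuals(x)
  li <- match(x$locus, loci)
  ii <- match(x$id, ind$id)
  a1 <- a2 <- matrix(NA_integer_, nrow(ind), length(loci),
                     dimnames = list(ind$id, loci))
  a1[cbind(ii, li)] <- x$a1
  a2[cbind(ii, li)] <- x$a2
  list(a1 = a1, a2 = a2, ids = ind$id, pops = ind$pop,
       x = ind$x, y = ind$y, loci = loci, pop_levels = pop_levels(x))
}

# Inverse of gt_array(); coords optional vectors aligned with arr$ids.
gt_from_array <- function(arr) {
  n <- length(arr$ids); L <- length(arr$loci)
  genotype_table(tibble::tibble(
    id = rep(arr$ids, each = L),
    pop = rep(arr$pops, each = L),
    locus = rep(arr$loci, times = n),
    a1 = as.integer(t(arr$a1)),
    a2 = as.integer(t(arr$a2)),
    x = rep(if (is.null(arr$x)) NA_real_ else arr$x, each = L),
    y = rep(if (is.null(arr$y)) NA_real_ else arr$y, each = L)
  ), pop_levels = arr$pop_levels)
}

#' Subset a genotype table to selected individuals
#'
#' @param x A `genotype_tbl`.
#' @param ids Character vector of sample ids to keep.
#' @export
gt_filter_ids <- function(x, ids) {
  genotype_table(dplyr::filter(x, .data$id %in% ids), pop_levels = pop_levels(x))
}

#' @export
print.genotype_tbl <- function(x, ...) {
  ind <- gt_individuals(x)
  cat(sprintf("# genotype_tbl: %d individuals, %d loci, %d populations\n",
              nrow(ind), length(gt_loci(x)), length(pop_levels(x))))
  NextMethod()
}
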