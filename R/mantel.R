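#' Mantel test between two distance matrices
#'
#' Pearson correlation between the vectorised entries of two co-labelled
#' matrices — the upper off-diagonal triangle when both are symmetric, all
#' `n(n-1)` off-diagonal entries otherwise (asymmetric rate matrices) —
#' with significance from joint row-and-column permutations of `Y`. The
#' permutation p-value is two-tailed and +1-corrected:
#' `p = (#{|r_perm| >= |r_obs|} + 1) / (n_perm + 1)`; when `n <= 7` labels
#' the full `n!` enumeration is used instead and the p-value is exact.
#'
#' @param x,y Square numeric matrices with identical dimnames order.
#' @param n_perm Number of permutations (ignored when enumerating).
#' @param seed Integer seed.
#' @param exhaustive `NULL` (auto: enumerate when `n <= 7`), `TRUE` or
#'   `FALSE`.
#' @return A `mantel_result` list: `r`, `r2`, `p`, `n_perm`, `exhaustive`,
#'   `partial`, `n`, `seed`, `labels`.
#' @export
mantel <- function(x, y, n_perm = 9999, seed = 1, exhaustive = NULL) {
  check_mantel_input(x, y)
  n <- nrow(x)
  sym <- is_symmetric(x) && is_symmetric(y)
  vec <- function(m, perm = seq_len(n)) {
    mp <- m[perm, perm]
    if (sym) mp[upper.tri(mp)] else mp[row(mp) != col(mp)]
  }
  vx <- vec(x)
  if (stats::sd(vx) == 0 || stats::sd(vec(y)) == 0) {
    stop("constant matrix: Mantel r undefined")
  }
  r_obs <- stats::cor(vx, vec(y))
  if (is.null(exhaustive)) exhaustive <- n <= 7
  if (exhaustive) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) stats::cor(vx, vec(y, p)), numeric(1))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    withr::with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (abs(stats::cor(vx, vec(y, sample.int(n)))) >= abs(r_obs) - 1e-12) {
          hits <- hits + 1L
        }
      }
      p <- (hits + 1) / (n_perm + 1)
    })
  }
  structure(list(r = r_obs, r2 = r_obs^2, p = p, n_perm = n_perm,
                 exhaustive = exhaustive, partial = FALSE, n = n,
                 seed = seed, labels = rownames(x) %||% as.character(seq_len(n))),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between the entrywise residuals of `x ~ z` and `y ~ z`,
#' with significance by permuting the residualised `y` rows and columns
#' jointly (Smouse-Long-Sokal). A constant `z` reduces to the simple
#' Mantel test with a warning.
#'
#' @inheritParams mantel
#' @param z Conditioning matrix.
#' @export
partial_mantel <- function(x, y, z, n_perm = 9999, seed = 1, exhaustive = NULL) {
  check_mantel_input(x, y)
  check_mantel_input(x, z)
  n <- nrow(x)
  sym <- is_symmetric(x) && is_symmetric(y) && is_symmetric(z)
  vec0 <- function(m) if (sym) m[upper.tri(m)] else m[row(m) != col(m)]
  vz <- vec0(z)
  if (stats::sd(vz) == 0) {
    warning("conditioning matrix constant: reduces to simple Mantel")
    out <- mantel(x, y, n_perm = n_perm, seed = seed, exhaustive = exhaustive)
    out$partial <- TRUE
    return(out)
  }
  resid_of <- function(v) stats::resid(stats::lm(v ~ vz))
  rx <- resid_of(vec0(x))
  ry_mat <- matrix(0, n, n, dimnames = dimnames(y))
  ry_v <- resid_of(vec0(y))
  if (sym) {
    ry_mat[upper.tri(ry_mat)] <- ry_v
    ry_mat <- ry_mat + t(ry_mat)
  } else {
    ry_mat[row(ry_mat) != col(ry_mat)] <- ry_v
  }
  vec <- function(m, perm = seq_len(n)) {
    mp <- m[perm, perm]
    if (sym) mp[upper.tri(mp)] else mp[row(mp) != col(mp)]
  }
  # degenerate residuals (e.g. x identical to z): partial correlation is 0
  if (stats::sd(rx) < 1e-10 * (stats::sd(vec0(x)) + 1e-300) ||
      stats::sd(ry_v) < 1e-10 * (stats::sd(vec0(y)) + 1e-300)) {
    return(structure(list(r = 0, r2 = 0, p = 1, n_perm = 0,
                          exhaustive = FALSE, partial = TRUE, n = n,
                          seed = seed,
                          labels = rownames(x) %||% as.character(seq_len(n))),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(rx, vec(ry_mat))
  if (is.null(exhaustive)) exhaustive <- n <= 7
  if (exhaustive) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) stats::cor(rx, vec(ry_mat, p)), numeric(1))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_perm <- length(perms)
  } else {
    withr::with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (abs(stats::cor(rx, vec(ry_mat, sample.int(n)))) >= abs(r_obs) - 1e-12) {
          hits <- hits + 1L
        }
      }
      p <- (hits + 1) / (n_perm + 1)
    })
  }
  structure(list(r = r_obs, r2 = r_obs^2, p = p, n_perm = n_perm,
                 exhaustive = exhaustive, partial = TRUE, n = n,
                 seed = seed, labels = rownames(x) %||% as.character(seq_len(n))),
            class = "mantel_result")
}

#' Isolation-by-distance test
#'
#' Euclidean distance matrix (km) between population centroids, correlated
#' with a genetic distance matrix by [mantel()].
#'
#' @param genetic Square genetic distance/rate matrix.
#' @param coords Data frame with `pop`, `x`, `y` (one row per population,
#'   matching the matrix labels).
#' @inheritParams mantel
#' @return A `mantel_result`; the geographic matrix is attached as
#'   `attr(, "distance")`.
#' @export
ibd_test <- function(genetic, coords, n_perm = 9999, seed = 1) {
  ord <- match(rownames(genetic), coords$pop)
  stopifnot(!anyNA(ord))
  d <- as.matrix(stats::dist(cbind(coords$x[ord], coords$y[ord])))
  dimnames(d) <- dimnames(genetic)
  out <- mantel(genetic, d, n_perm = n_perm, seed = seed)
  attr(out, "distance") <- d
  out
}

check_mantel_input <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == ncol(x),
            all(dim(x) == dim(y)))
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    stop("matrix labels differ or are ordered differently")
  }
}

is_symmetric <- function(m) isTRUE(all.equal(m, t(m), tolerance = 1e-12,
                                             check.attributes = FALSE))

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(s, n, after = pos - 1)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel: r = %.4f (r2 = %.4f), p = %.4g [%s, n = %d, %d perms]\n",
              if (x$partial) "Partial" else "Simple", x$r, x$r2, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n, x$n_perm))
  invisible(x)
}

#' Rank layer combinations by Mantel r2
#'
#' Runs a (partial) Mantel test of one genetic matrix against each supplied
#' resistance matrix and returns the table sorted by r2 — the layout used
#' to compare candidate landscape-resistance surfaces.
#'
#' @param genetic Genetic distance/rate matrix.
#' @param resistances Named list of resistance matrices.
#' @param z Optional conditioning matrix (partial Mantel when given).
#' @inheritParams mantel
#' @return Tibble with `surface`, `r`, `r2`, `p`, `significant`, sorted by
#'   decreasing r2.
#' @export
mantel_ranking <- function(genetic, resistances, z = NULL, n_perm = 9999,
                           seed = 1) {
  purrr::imap_dfr(resistances, function(m, nm) {
    res <- if (is.null(z)) {
      mantel(genetic, m, n_perm = n_perm, seed = seed)
    } else {
      partial_mantel(genetic, m, z, n_perm = n_perm, seed = seed)
    }
    tibble::tibble(surface = nm, r = res$r, r2 = res$r2, p = res$p)
  }) |>
    dplyr::mutate(significant = .data$p <= 0.05) |>
    dplyr::arrange(dplyr::desc(.data$r2))
}
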