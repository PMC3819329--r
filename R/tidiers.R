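#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Mantel result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return One-row tibble with `r`, `r2`, `p`, `n`, `n_perm`,
#'   `exhaustive`, `partial`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, r2 = x$r2, p = x$p, n = x$n, n_perm = x$n_perm,
                 exhaustive = x$exhaustive, partial = x$partial)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' Tidy pairwise matrices
#'
#' Converts a labelled square matrix to a long tibble of unordered (or
#' ordered, if asymmetric) pairs.
#'
#' @param m Square labelled matrix.
#' @param value Name of the value column.
#' @param upper_only Keep only the upper triangle.
#' @return Tibble `pop_a`, `pop_b`, value.
#' @export
pairwise_tbl <- function(m, value = "value", upper_only = TRUE) {
  idx <- if (upper_only) which(upper.tri(m), arr.ind = TRUE) else
    which(row(m) != col(m), arr.ind = TRUE)
  out <- tibble::tibble(pop_a = rownames(m)[idx[, 1]],
                        pop_b = colnames(m)[idx[, 2]],
                        v = m[idx])
  names(out)[3] <- value
  out
}

#' Tidy a pairwise resistance result
#'
#' @param x A `resistance_result` from [pairwise_resistance()].
#' @param ... Unused.
#' @return Tibble `pop_a`, `pop_b`, `resistance`, `resistance_scaled`,
#'   `disconnected`.
#' @export
tidy.resistance_result <- function(x, ...) {
  dplyr::bind_cols(
    pairwise_tbl(x$r, "resistance"),
    pairwise_tbl(x$r_scaled, "resistance_scaled")["resistance_scaled"],
    pairwise_tbl(x$disconnected * 1, "disconnected")["disconnected"]) |>
    dplyr::mutate(disconnected = .data$disconnected > 0)
}

#' @export
autoplot.resistance_result <- function(object, ...) {
  if (is.null(object$current)) stop("no current map was accumulated")
  autoplot(object$current) +
    ggplot2::labs(fill = "current", title = "Cumulative current map")
}

#' Differentiation matrix in the two-triangle report layout
#'
#' F_ST in the upper triangle and D_SP (with its jackknife SE in
#' parentheses) in the lower triangle — the standard compact layout for
#' reporting both differentiation measures at once.
#'
#' @param fst Symmetric F_ST matrix.
#' @param dsp Symmetric D_SP matrix.
#' @param dsp_se Optional D_SP standard-error matrix.
#' @return Character matrix with population dimnames.
#' @export
render_differentiation <- function(fst, dsp, dsp_se = NULL) {
  k <- nrow(fst)
  out <- matrix("", k, k, dimnames = dimnames(fst))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) out[i, j] <- sprintf("%.4f", fst[i, j])
      if (i > j) {
        out[i, j] <- if (is.null(dsp_se)) sprintf("%.3f", dsp[i, j]) else
          sprintf("%.3f (%.2f)", dsp[i, j], dsp_se[i, j])
      }
    }
  }
  out
}
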