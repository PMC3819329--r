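#' Build the conductance graph of a resistance raster
#'
#' Valid (non-nodata) cells become nodes; 4- or 8-neighbour cell pairs get
#' an edge with conductance `1 / (d * (r_i + r_j) / 2)` where `d` is 1 for
#' cardinal and `sqrt(2)` for diagonal neighbours (the averaged-resistance
#' convention; `conductance = "mean_conductance"` averages the cell
#' conductances instead).
#'
#' @param layer A [raster_grid()] resistance layer (values >= 1, NA = cell
#'   absent from the graph).
#' @param neighbourhood 4 or 8.
#' @param conductance Edge-conductance convention.
#' @return A `node_graph` list: `n` nodes, `edges` (matrix with columns
#'   `i`, `j`, `g`), `cell_of_node` (linear cell index of each node),
#'   `node_of_cell` (matrix of node ids, NA where invalid), `dim`,
#'   `cell_size`.
#' @export
build_graph <- function(layer, neighbourhood = 8,
                        conductance = c("mean_resistance", "mean_conductance")) {
  conductance <- match.arg(conductance)
  stopifnot(neighbourhood %in% c(4, 8))
  v <- layer$values
  valid <- !is.na(v)
  if (sum(valid) < 2) stop("fewer than 2 valid cells")
  nr <- nrow(v); nc <- ncol(v)
  node <- matrix(NA_integer_, nr, nc)
  node[valid] <- seq_len(sum(valid))
  shifts <- rbind(c(0, 1, 1), c(1, 0, 1))
  if (neighbourhood == 8) shifts <- rbind(shifts, c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  edges <- NULL
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts[s, 1]; dc <- shifts[s, 2]; df <- shifts[s, 3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    i1 <- as.matrix(expand.grid(r = r1, c = c1))
    i2 <- cbind(i1[, 1] + dr, i1[, 2] + dc)
    ok <- valid[i1] & valid[i2]
    if (!any(ok)) next
    ri <- v[i1[ok, , drop = FALSE]]
    rj <- v[i2[ok, , drop = FALSE]]
    g <- if (conductance == "mean_resistance") {
      1 / (df * (ri + rj) / 2)
    } else {
      (1 / ri + 1 / rj) / 2 / df
    }
    edges <- rbind(edges, cbind(i = node[i1[ok, , drop = FALSE]],
                                j = node[i2[ok, , drop = FALSE]], g = g))
  }
  if (is.null(edges)) {
    edges <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "g")))
  }
  structure(list(n = sum(valid), edges = edges,
                 cell_of_node = which(valid), node_of_cell = node,
                 dim = c(nr, nc), cell_size = layer$cell_size,
                 xll = layer$xll, yll = layer$yll),
            class = "node_graph")
}

#' @export
print.node_graph <- function(x, ...) {
  cat(sprintf("# node_graph: %d nodes, %d edges on a %dx%d grid\n",
              x$n, nrow(x$edges), x$dim[1], x$dim[2]))
  invisible(x)
}

# contract node sets into supernodes (infinite internal conductance).
# regions: list of integer node-id vectors. Returns group id per node and
# the group ids of the regions.
contract_nodes <- function(graph, regions) {
  group <- seq_len(graph$n)
  for (k in seq_along(regions)) {
    m <- regions[[k]]
    stopifnot(length(m) > 0)
    group[m] <- graph$n + k
  }
  relab <- match(group, sort(unique(group)))
  list(group = relab,
       region_groups = vapply(regions, function(m) relab[m[1]], integer(1)),
       n_groups = max(relab))
}

# sparse Laplacian of the contracted graph
contracted_laplacian <- function(graph, group, n_groups) {
  gi <- group[graph$edges[, "i"]]
  gj <- group[graph$edges[, "j"]]
  keep <- gi != gj
  W <- Matrix::sparseMatrix(i = c(gi[keep], gj[keep]),
                            j = c(gj[keep], gi[keep]),
                            x = rep(graph$edges[keep, "g"], 2),
                            dims = c(n_groups, n_groups))
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Effective resistance between two node regions
#'
#' Region cells are merged into supernodes; unit current is injected at A
#' and extracted at B, the Laplacian system is solved by sparse direct
#' factorisation, and the effective resistance is the potential difference
#' between the supernodes. Disconnected regions give `Inf`.
#'
#' @param graph A `node_graph` from [build_graph()].
#' @param region_a,region_b Integer vectors of node ids (disjoint,
#'   nonempty).
#' @return Scalar effective resistance.
#' @export
effective_resistance <- function(graph, region_a, region_b) {
  stopifnot(length(intersect(region_a, region_b)) == 0)
  ct <- contract_nodes(graph, list(region_a, region_b))
  L <- contracted_laplacian(graph, ct$group, ct$n_groups)
  a <- ct$region_groups[1]; b <- ct$region_groups[2]
  ig <- igraph::graph_from_edgelist(
    unique(cbind(ct$group[graph$edges[, "i"]], ct$group[graph$edges[, "j"]])),
    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, ct$n_groups - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  if (comp[a] != comp[b]) return(Inf)
  solve_pair_resistance(L, a, b)$r
}

# solve grounded system for one pair; returns resistance and potentials
solve_pair_resistance <- function(L, a, b, keep = NULL) {
  n <- nrow(L)
  if (is.null(keep)) keep <- setdiff(seq_len(n), b)
  G <- L[keep, keep, drop = FALSE]
  rhs <- numeric(length(keep))
  rhs[match(a, keep)] <- 1
  x <- as.numeric(Matrix::solve(G, rhs))
  resid <- max(abs(as.numeric(G %*% x) - rhs))
  if (resid > 1e-8) warning("Laplacian solve residual ", signif(resid, 3))
  v <- numeric(n)
  v[keep] <- x
  list(r = v[a], v = v)
}

#' Pairwise effective resistances and cumulative current map
#'
#' All regions are short-circuited into supernodes (polygon semantics) and
#' every unordered pair is solved. The cumulative current raster sums each
#' pair's per-cell absolute current weighted by
#' `s_i * s_j / mean(s_i * s_j)` where `s` are the source strengths
#' (population abundance counts); effective resistance itself is invariant
#' to injected current, so strengths also enter through the explicitly
#' labelled strength-normalised variant `r_scaled = R_ij / (s_i * s_j)`.
#'
#' @param graph A `node_graph`.
#' @param regions Named list of node-id vectors (>= 2 regions, disjoint).
#' @param strengths Named numeric source strengths (default all 1).
#' @param current_map Accumulate the cumulative current raster.
#' @return A `resistance_result` list: `r` (pairwise effective resistance
#'   matrix), `r_scaled`, `current` ([raster_grid()] or NULL),
#'   `disconnected` (logical matrix flag).
#' @export
pairwise_resistance <- function(graph, regions, strengths = NULL,
                                current_map = TRUE) {
  K <- length(regions)
  stopifnot(K >= 2)
  labs <- names(regions) %||% paste0("R", seq_len(K))
  if (is.null(strengths)) strengths <- stats::setNames(rep(1, K), labs)
  strengths <- strengths[labs]
  ct <- contract_nodes(graph, regions)
  L <- contracted_laplacian(graph, ct$group, ct$n_groups)
  eg <- cbind(ct$group[graph$edges[, "i"]], ct$group[graph$edges[, "j"]])
  ig <- igraph::graph_from_edgelist(unique(eg[eg[, 1] != eg[, 2], , drop = FALSE]),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, ct$n_groups - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  R <- matrix(0, K, K, dimnames = list(labs, labs))
  disconnected <- matrix(FALSE, K, K, dimnames = list(labs, labs))
  cur <- matrix(0, graph$dim[1], graph$dim[2])
  sw <- outer(strengths, strengths)
  mean_sw <- mean(sw[upper.tri(sw)])
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      a <- ct$region_groups[i]; b <- ct$region_groups[j]
      if (comp[a] != comp[b]) {
        R[i, j] <- R[j, i] <- Inf
        disconnected[i, j] <- disconnected[j, i] <- TRUE
        next
      }
      keep <- which(comp == comp[a])
      keep <- setdiff(keep, b)
      sol <- solve_pair_resistance(L, a, b, keep = keep)
      R[i, j] <- R[j, i] <- sol$r
      if (current_map) {
        vi <- sol$v[ct$group[graph$edges[, "i"]]]
        vj <- sol$v[ct$group[graph$edges[, "j"]]]
        I_edge <- abs(graph$edges[, "g"] * (vi - vj))
        node_cur <- numeric(graph$n)
        for (e in c("i", "j")) {
          node_cur <- node_cur +
            as.numeric(tapply_sum(graph$edges[, e], I_edge, graph$n))
        }
        node_cur <- node_cur / 2
        w <- sw[i, j] / mean_sw
        cells <- graph$cell_of_node
        cur[cells] <- cur[cells] + w * node_cur
      }
    }
  }
  if (any(disconnected)) warning("disconnected region pairs: resistance Inf")
  current <- NULL
  if (current_map) {
    cm <- matrix(NA_real_, graph$dim[1], graph$dim[2])
    cm[graph$cell_of_node] <- cur[graph$cell_of_node]
    in_region <- unlist(regions)
    cm[graph$cell_of_node[in_region]] <- NA # short-circuited interiors
    current <- raster_grid(cm, graph$cell_size, graph$xll, graph$yll)
  }
  structure(list(r = R, r_scaled = R / sw, current = current,
                 disconnected = disconnected, strengths = strengths),
            class = "resistance_result")
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Map raster patch labels to graph node regions
#'
#' @param graph A `node_graph`.
#' @param patches Patch-label [raster_grid()] (NA off-patch).
#' @return Named list of node-id vectors, one per patch label present in
#'   the graph.
#' @export
regions_from_patches <- function(graph, patches) {
  lab <- patches$values[graph$cell_of_node]
  nodes <- seq_len(graph$n)
  out <- split(nodes, lab)
  stats::setNames(out, paste0("P", names(out)))
}
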