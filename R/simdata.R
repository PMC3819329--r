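#' Simulate population allele frequencies under the F-model
#'
#' Ancestral frequencies at each locus are drawn from a flat Dirichlet;
#' each population's frequencies are then drawn from
#' `Dirichlet(p_ancestral * (1 - F) / F)`, so that the expected
#' among-population variance at an allele with ancestral frequency `p` is
#' `F * p * (1 - p)` — i.e. `fst` is the expected Weir-Cockerham theta of
#' the simulated populations. `fst = 0` returns the ancestral frequencies in
#' every population (no divergence).
#'
#' @param n_pops Number of populations.
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus; scalar or vector of length `n_loci`.
#' @param fst Divergence parameter `F` in `[0, 1)`.
#' @param seed Integer seed; every simulation function uses its own seeded
#'   generator and leaves the caller's RNG untouched.
#' @param pop_names Population labels; default `P1..Pk`.
#' @return An allele-frequency tibble (class `allele_freq_tbl`): one row per
#'   population x locus x allele with columns `pop`, `locus`, `allele`,
#'   `freq`, `n` (gene copies backing the estimate; `NA` for theoretical
#'   frequencies).
#' @export
sim_allele_freqs <- function(n_pops = 6, n_loci = 14, n_alleles = 12,
                             fst = 0.10, seed = 1,
                             pop_names = paste0("P", seq_len(n_pops))) {
  stopifnot(fst >= 0, fst < 1, n_pops >= 1, n_loci >= 1, all(n_alleles >= 2))
  n_alleles <- rep_len(n_alleles, n_loci)
  loci <- sprintf("L%02d", seq_len(n_loci))
  withr::with_seed(seed, {
    out <- purrr::map2_dfr(loci, n_alleles, function(loc, k) {
      p_anc <- rdirichlet(1, rep(1, k))[1, ]
      pops <- if (fst == 0) {
        matrix(p_anc, n_pops, k, byrow = TRUE)
      } else {
        rdirichlet(n_pops, p_anc * (1 - fst) / fst)
      }
      tibble::tibble(
        pop = rep(pop_names, each = k),
        locus = loc,
        allele = rep(seq_len(k), times = n_pops),
        freq = as.vector(t(pops)),
        n = NA_real_)
    })
    new_allele_freqs(out)
  })
}

new_allele_freqs <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("allele_freq_tbl", class(tibble::tibble())))
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0 # numerically possible at tiny alpha
  if (any(zero)) x[zero, ] <- t(stats::rmultinom(sum(zero), 1, rep(1, length(alpha))))
  x / rowSums(x)
}

# freqs tibble -> list [[locus]] = matrix pops x alleles (freqs), plus codes
freq_arrays <- function(freqs) {
  pops <- unique(freqs$pop)
  lapply(split(freqs, factor(freqs$locus, unique(freqs$locus))), function(d) {
    codes <- sort(unique(d$allele))
    m <- matrix(0, length(pops), length(codes),
                dimnames = list(pops, as.character(codes)))
    m[cbind(match(d$pop, pops), match(d$allele, codes))] <- d$freq
    list(freq = m, codes = codes)
  })
}

#' Simulate diploid genotypes under Hardy-Weinberg proportions
#'
#' Each individual's two gene copies at each locus are drawn independently
#' from its population's allele frequencies; calls are then masked at
#' `missing_rate` per individual per locus.
#'
#' @param freqs Allele-frequency tibble (see [sim_allele_freqs()]).
#' @param n_per_pop Individuals per population; scalar or vector (one entry
#'   per population, in the order populations appear in `freqs`).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param seed Integer seed.
#' @return A list with `table` (a [genotype_table()]) and `truth` (the
#'   generating configuration, including the seed).
#' @export
sim_genotypes <- function(freqs, n_per_pop = 15, missing_rate = 0, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  fa <- freq_arrays(freqs)
  pops <- rownames(fa[[1]]$freq)
  n_per_pop <- rep_len(n_per_pop, length(pops))
  loci <- names(fa)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_along(pops), function(pi) {
      n <- n_per_pop[pi]
      ids <- sprintf("%s_%02d", pops[pi], seq_len(n))
      purrr::map_dfr(loci, function(loc) {
        p <- fa[[loc]]$freq[pi, ]
        codes <- fa[[loc]]$codes
        a1 <- sample(codes, n, replace = TRUE, prob = p)
        a2 <- sample(codes, n, replace = TRUE, prob = p)
        miss <- stats::runif(n) < missing_rate
        a1[miss] <- NA_integer_
        a2[miss] <- NA_integer_
        tibble::tibble(id = ids, pop = pops[pi], locus = loc, a1 = a1, a2 = a2)
      })
    })
    list(table = genotype_table(rows, pop_levels = pops),
         truth = list(seed = seed, n_per_pop = stats::setNames(n_per_pop, pops),
                      missing_rate = missing_rate))
  })
}

#' Plant first-generation migrants with known ground truth
#'
#' For each requested source-to-destination pair, randomly chosen resident
#' individuals of the destination population have their multilocus genotype
#' redrawn from the SOURCE population's allele frequencies while keeping
#' their destination population label — an F0 migrant by construction.
#'
#' @param table A [genotype_table()].
#' @param freqs The generating allele frequencies.
#' @param pairs Data frame with columns `from`, `to`, `n`.
#' @param seed Integer seed.
#' @return List with the modified `table` and `truth`, a tibble
#'   (`id`, `source`, `labelled`) naming every planted migrant.
#' @export
plant_migrants <- function(table, freqs, pairs, seed = 1) {
  fa <- freq_arrays(freqs)
  arr <- gt_array(table)
  stopifnot(all(pairs$from %in% arr$pop_levels), all(pairs$to %in% arr$pop_levels),
            all(pairs$from != pairs$to))
  withr::with_seed(seed, {
    truth <- list()
    taken <- character(0)
    for (r in seq_len(nrow(pairs))) {
      from <- pairs$from[r]; to <- pairs$to[r]; n <- pairs$n[r]
      cand <- setdiff(arr$ids[arr$pops == to], taken)
      if (n > length(cand)) {
        stop("cannot plant ", n, " migrants into ", to, ": only ",
             length(cand), " unreplaced residents")
      }
      chosen <- sample(cand, n)
      taken <- c(taken, chosen)
      pi <- match(from, rownames(fa[[1]]$freq))
      for (id in chosen) {
        i <- match(id, arr$ids)
        for (loc in arr$loci) {
          p <- fa[[loc]]$freq[pi, ]
          g <- sort(sample(fa[[loc]]$codes, 2, replace = TRUE, prob = p))
          arr$a1[i, loc] <- g[1]
          arr$a2[i, loc] <- g[2]
        }
      }
      truth[[r]] <- tibble::tibble(id = chosen, source = from, labelled = to)
    }
    list(table = gt_from_array(arr), truth = dplyr::bind_rows(truth))
  })
}

#' Simulate replicate genotype calls with dropout and false alleles
#'
#' Emulates repeated amplification of each sample at each locus: in each
#' replicate a heterozygous call loses one allele (allelic dropout, becoming
#' an apparent homozygote) with probability `dropout_rate`, and each
#' surviving allele copy is replaced by a random different allele of the
#' locus with probability `false_allele_rate`.
#'
#' @param table A [genotype_table()] holding the true genotypes.
#' @param dropout_rate,false_allele_rate Error probabilities in `[0, 1]`.
#' @param n_reps Replicates per sample (at least 2; field protocols use 4).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `locus`, `rep`, `a1`, `a2`.
#' @export
sim_replicates <- function(table, dropout_rate = 0, false_allele_rate = 0,
                           n_reps = 4, seed = 1) {
  stopifnot(n_reps >= 2, dropout_rate >= 0, dropout_rate <= 1,
            false_allele_rate >= 0, false_allele_rate <= 1)
  allele_sets <- lapply(split(table, table$locus),
                        function(d) sort(unique(stats::na.omit(c(d$a1, d$a2)))))
  withr::with_seed(seed, {
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      d <- tibble::tibble(id = table$id, locus = table$locus, rep = r,
                          a1 = table$a1, a2 = table$a2)
      het <- !is.na(d$a1) & d$a1 != d$a2
      drop <- het & stats::runif(nrow(d)) < dropout_rate
      keep_first <- stats::runif(nrow(d)) < 0.5
      d$a1[drop & !keep_first] <- d$a2[drop & !keep_first]
      d$a2[drop & keep_first] <- d$a1[drop & keep_first]
      for (col in c("a1", "a2")) {
        flip <- !is.na(d[[col]]) & stats::runif(nrow(d)) < false_allele_rate
        for (i in which(flip)) {
          others <- setdiff(allele_sets[[d$locus[i]]], d[[col]][i])
          if (length(others)) d[[col]][i] <- sample(others, 1)
        }
      }
      lo <- pmin(d$a1, d$a2); hi <- pmax(d$a1, d$a2)
      d$a1 <- lo; d$a2 <- hi
      d
    })
    dplyr::arrange(reps, .data$id, .data$locus, .data$rep)
  })
}

#' Simulate a synthetic study landscape
#'
#' Generates co-registered rasters emulating the inputs of a
#' resistance-surface analysis: a land-cover grid with forest habitat
#' patches (class 1), percent tree cover in `[0, 67]`, night-light radiance
#' with settlement kernels (some cells above the urban threshold of 20),
#' and a set of road polylines. Patch centres sit on a jittered ring so
#' that inter-patch Euclidean distances are roughly even. An optional
#' barrier places a band of moderately lit settlement cells (light 10,
#' below the urban threshold so the band contributes resistance without
#' being masked out of the landscape) either as a ring around one patch or
#' as a wall between two patches.
#'
#' @param grid_dim `c(nrows, ncols)` of the grid (at least 10 x 10).
#' @param cell_size Cell edge (km).
#' @param n_patches Number of habitat patches (>10 km2 each by construction).
#' @param n_small_patches Decoy patches below the 10 km2 filter.
#' @param n_extra_patches Additional retained (>10 km2) forest patches that
#'   carry no sampled population.
#' @param n_settlements Number of settlement light kernels.
#' @param n_roads Number of road polylines crossing the landscape.
#' @param barrier `NULL`, or `list(type = "ring", patch = i)` /
#'   `list(type = "wall", between = c(i, j))`; optional elements `width_km`
#'   (default 3) and `light` (default 10).
#' @param seed Integer seed.
#' @return List with rasters `landcover`, `tree`, `lights` (all
#'   [raster_grid()]), `roads` (tibble `road`, `x`, `y` of polyline
#'   vertices) and `truth` (patch centres/radii, settlement cells, barrier
#'   cells, seed).
#' @export
sim_landscape <- function(grid_dim = c(60, 60), cell_size = 1,
                          n_patches = 6, n_small_patches = 3,
                          n_extra_patches = 3, n_settlements = 25, n_roads = 6,
                          barrier = NULL, center_patch = FALSE, seed = 1) {
  stopifnot(all(grid_dim >= 10), cell_size > 0)
  nr <- grid_dim[1]; nc <- grid_dim[2]
  withr::with_seed(seed, {
    cx <- nc / 2; cy <- nr / 2
    ring_r <- 0.36 * min(nr, nc)
    n_ring <- if (center_patch) n_patches - 1 else n_patches
    ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring +
      stats::runif(n_ring, -0.15, 0.15)
    centers <- tibble::tibble(
      patch = seq_len(n_patches),
      x = c(if (center_patch) cx else NULL, cx + ring_r * cos(ang)) * cell_size,
      y = c(if (center_patch) cy else NULL, cy + ring_r * sin(ang)) * cell_size,
      r = stats::runif(n_patches, 3.2, 4.8))
    small <- tibble::tibble(
      patch = n_patches + seq_len(n_small_patches),
      x = stats::runif(n_small_patches, 0.2, 0.8) * nc * cell_size,
      y = stats::runif(n_small_patches, 0.2, 0.8) * nr * cell_size,
      r = stats::runif(n_small_patches, 0.4, 0.9))
    # additional retained (>10 km2) forest patches that carry no sampled
    # population; placed clear of the main patches
    extra <- NULL
    if (n_extra_patches > 0) {
      ex <- ey <- er <- numeric(0)
      tries <- 0
      while (length(ex) < n_extra_patches && tries < 500) {
        tries <- tries + 1
        x0 <- stats::runif(1, 0.12, 0.88) * nc * cell_size
        y0 <- stats::runif(1, 0.12, 0.88) * nr * cell_size
        r0 <- stats::runif(1, 2.2, 3.2)
        d <- sqrt((centers$x - x0)^2 + (centers$y - y0)^2)
        if (all(d > centers$r + r0 + 6) &&
            (!length(ex) || all(sqrt((ex - x0)^2 + (ey - y0)^2) > er + r0 + 3))) {
          ex <- c(ex, x0); ey <- c(ey, y0); er <- c(er, r0)
        }
      }
      extra <- tibble::tibble(patch = n_patches + n_small_patches + seq_along(ex),
                              x = ex, y = ey, r = er)
    }
    co <- raster_coords(raster_grid(matrix(0, nr, nc), cell_size))
    all_centers <- dplyr::bind_rows(centers, small, extra)
    field <- rep(-Inf, nrow(co))
    for (k in seq_len(nrow(all_centers))) {
      pc <- all_centers[k, ]
      d <- sqrt((co$x - pc$x)^2 + (co$y - pc$y)^2)
      field <- pmax(field, pc$r - d)
    }
    noise <- smooth_noise(nr, nc, sigma = 2)
    habitat <- matrix(0, nr, nc)
    habitat[cbind(co$row, co$col)] <- as.numeric(field + 0.8 * noise[cbind(co$row, co$col)] > 0)

    tn <- smooth_noise(nr, nc, sigma = 3)
    tn <- (tn - min(tn)) / (max(tn) - min(tn))
    tree <- 27 * habitat + 40 * tn
    tree[tree < 0] <- 0
    tree[tree > 67] <- 67
    gap_cells <- NULL # forested corridor cells through a ring barrier

    lights <- matrix(0, nr, nc)
    sx <- stats::runif(n_settlements, 0, nc * cell_size)
    sy <- stats::runif(n_settlements, 0, nr * cell_size)
    peak <- stats::runif(n_settlements, 5, 55)
    for (s in seq_len(n_settlements)) {
      d2 <- (co$x - sx[s])^2 + (co$y - sy[s])^2
      lights[cbind(co$row, co$col)] <- lights[cbind(co$row, co$col)] +
        peak[s] * exp(-d2 / (2 * 1.2^2))
    }
    lights[lights < 0.5] <- 0 # radiance floor: unlit background is dark
    barrier_cells <- integer(0)
    if (!is.null(barrier)) {
      width <- barrier$width_km %||% 3
      level <- barrier$light %||% if (identical(barrier$type, "ring")) 30 else 10
      if (barrier$type == "ring") {
        n_gaps <- barrier$n_gaps %||% 3
        gap_km <- barrier$gap_km %||% 4
        gap_light <- barrier$gap_light %||% 10
        inband <- rep(FALSE, nrow(co))
        ingap <- rep(FALSE, nrow(co))
        for (pk in barrier$patch) {
          pc <- centers[pk, ]
          d <- sqrt((co$x - pc$x)^2 + (co$y - pc$y)^2)
          theta <- atan2(co$y - pc$y, co$x - pc$x)
          band <- d >= pc$r + 1.5 & d <= pc$r + 1.5 + width
          inband <- inband | band
          if (n_gaps > 0) {
            gap_centers <- stats::runif(1, 0, 2 * pi) +
              2 * pi * (seq_len(n_gaps) - 1) / n_gaps
            half_arc <- gap_km / (2 * (pc$r + 1.5 + width / 2))
            for (gc in gap_centers) {
              dd <- abs(((theta - gc + pi) %% (2 * pi)) - pi)
              ingap <- ingap | (band & dd <= half_arc)
            }
          }
        }
      } else if (barrier$type == "wall") {
        p1 <- centers[barrier$between[1], ]; p2 <- centers[barrier$between[2], ]
        mx <- (p1$x + p2$x) / 2; my <- (p1$y + p2$y) / 2
        ux <- p2$x - p1$x; uy <- p2$y - p1$y
        len <- sqrt(ux^2 + uy^2); ux <- ux / len; uy <- uy / len
        along <- (co$x - mx) * ux + (co$y - my) * uy   # toward p2
        across <- -(co$x - mx) * uy + (co$y - my) * ux # along the wall
        inband <- abs(along) <= width / 2 & abs(across) <= 0.8 * len
      } else stop("unknown barrier type: ", barrier$type)
      idx <- cbind(co$row[inband], co$col[inband])
      lights[idx] <- pmax(lights[idx], level)
      if (barrier$type == "ring" && any(ingap)) {
        gdx <- cbind(co$row[ingap], co$col[ingap])
        lights[gdx] <- gap_light
        tree[gdx] <- 67 # corridor gaps carry full forest cover
        gap_cells <- which(ingap)
      }
      barrier_cells <- which(inband)
    }

    # roads cross the landscape but bypass ring-walled reserves
    avoid <- NULL
    if (!is.null(barrier) && identical(barrier$type, "ring")) {
      avoid <- centers[barrier$patch, ]
      avoid$rad <- avoid$r + 1.5 + (barrier$width_km %||% 3) + 1
    }
    roads <- purrr::map_dfr(seq_len(n_roads), function(k) {
      horiz <- stats::runif(1) < 0.5
      if (horiz) {
        xs <- c(0, stats::runif(2, 0.3, 0.7) * nc * cell_size, nc * cell_size)
        ys <- stats::runif(4, 0.1, 0.9) * nr * cell_size
      } else {
        ys <- c(0, stats::runif(2, 0.3, 0.7) * nr * cell_size, nr * cell_size)
        xs <- stats::runif(4, 0.1, 0.9) * nc * cell_size
      }
      ord <- order(if (horiz) xs else ys)
      xs <- xs[ord]; ys <- ys[ord]
      # densify, then cut out any stretch inside an exclusion disc: roads
      # terminate at the reserve boundary instead of crossing (or ringing) it
      px <- stats::approx(seq_along(xs), xs, n = 24)$y
      py <- stats::approx(seq_along(ys), ys, n = 24)$y
      keep <- rep(TRUE, length(px))
      if (!is.null(avoid)) {
        for (a in seq_len(nrow(avoid))) {
          keep <- keep & sqrt((px - avoid$x[a])^2 + (py - avoid$y[a])^2) >=
            avoid$rad[a]
        }
      }
      if (!any(keep)) return(NULL)
      piece <- cumsum(c(1, diff(which(keep)) > 1))
      tibble::tibble(road = paste0(k, "_", piece),
                     x = px[keep], y = py[keep])
    })
    roads$road <- match(roads$road, unique(roads$road))

    list(landcover = raster_grid(habitat, cell_size),
         tree = raster_grid(tree, cell_size),
         lights = raster_grid(lights, cell_size),
         roads = roads,
         truth = list(patches = centers, small_patches = small,
                      extra_patches = extra,
                      settlements = tibble::tibble(x = sx, y = sy, peak = peak),
                      barrier = barrier, barrier_cells = barrier_cells,
                      gap_cells = gap_cells, seed = seed))
  })
}

smooth_noise <- function(nr, nc, sigma = 2) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  g <- as.matrix(EBImage::gblur(z, sigma = sigma))
  g / stats::sd(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read a simulation truth record as JSON
#'
#' Truth records (planted migrants, patch centres, settlement cells,
#' barrier geometry, seeds) round-trip through JSON so that downstream
#' recovery tests can run from files alone.
#'
#' @param truth A truth record (list / tibbles) from a simulation function.
#' @param path Output path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   parsed record with data frames as tibbles.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tbl <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x)
    else if (is.list(x)) lapply(x, as_tbl)
    else x
  }
  as_tbl(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Forward migration-drift simulation of allele frequencies
#'
#' Each generation applies deterministic migration mixing
#' `p_i <- (1 - sum_j m_ij) p_i + sum_j m_ij p_j` followed by binomial drift
#' (multinomial resampling of `2 N_e` gene copies per population per locus).
#' Set `n_e = Inf` to disable drift.
#'
#' @param freqs0 Starting allele-frequency tibble.
#' @param m Migration matrix (rows = receiving population); off-diagonal
#'   `m[i, j]` is the fraction of population i's gene pool drawn from j each
#'   generation; row sums of the off-diagonal must be <= 1.
#' @param n_e Effective population size (>= 10, or `Inf`).
#' @param generations Number of generations to iterate.
#' @param seed Integer seed.
#' @return An allele-frequency tibble of the final generation.
#' @export
sim_geneflow_forward <- function(freqs0, m, n_e = 100, generations = 100, seed = 1) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  diag(m) <- 0
  if (any(rowSums(m) > 1 + 1e-12)) stop("migration matrix rows must sum to <= 1")
  if (!is.infinite(n_e) && n_e < 10) stop("n_e must be >= 10 (or Inf to disable drift)")
  fa <- freq_arrays(freqs0)
  pops <- rownames(fa[[1]]$freq)
  stopifnot(length(pops) == nrow(m))
  mix <- m
  diag(mix) <- 1 - rowSums(m)
  withr::with_seed(seed, {
    out <- purrr::map_dfr(names(fa), function(loc) {
      p <- fa[[loc]]$freq
      for (g in seq_len(generations)) {
        p <- mix %*% p
        if (!is.infinite(n_e)) {
          for (i in seq_len(nrow(p))) {
            p[i, ] <- stats::rmultinom(1, 2 * n_e, p[i, ]) / (2 * n_e)
          }
        }
      }
      tibble::tibble(pop = rep(pops, each = length(fa[[loc]]$codes)),
                     locus = loc,
                     allele = rep(fa[[loc]]$codes, times = length(pops)),
                     freq = as.vector(t(p)), n = NA_real_)
    })
    new_allele_freqs(out)
  })
}

#' Migration matrix from pairwise resistances
#'
#' Converts a pairwise effective-resistance matrix into a migration matrix
#' with `m_ij` proportional to `exp(-R_ij / tau)`, scaled so the largest row
#' sum of off-diagonal migration equals `total_mig`.
#'
#' @param R Symmetric pairwise resistance matrix.
#' @param tau Resistance scale of the exponential decay.
#' @param total_mig Largest per-population total immigration rate.
#' @return A migration matrix usable by [sim_geneflow_forward()].
#' @export
migration_from_resistance <- function(R, tau, total_mig = 0.2) {
  w <- exp(-R / tau)
  diag(w) <- 0
  w * total_mig / max(rowSums(w))
}
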