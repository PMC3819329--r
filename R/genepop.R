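#' Read a Genepop file
#'
#' Parses the classic Genepop text format: a title line, one locus name per
#' line (or a single comma-separated line), then `Pop` blocks of individual
#' records `id ,  aabb aabb ...` in the 2- or 3-digit dialect. `00`/`000`
#' allele codes mean a missing call, never allele zero. Population labels are
#' taken from the id of the first individual in each block (the Genepop
#' convention) unless ids carry no structure, in which case `pop1..popK` are
#' used.
#'
#' @param path Path to a Genepop file.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file (fewer than 3 non-blank lines): ", path)
  body <- lines[-1]
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  loci <- trimws(unlist(strsplit(body[seq_len(first_pop - 1)], ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("no locus names before first 'Pop' (line 2 of ", path, ")")

  pop_idx <- cumsum(is_pop)
  rows <- list()
  pop_names <- character(0)
  for (i in seq_along(body)) {
    if (is_pop[i]) next
    if (pop_idx[i] == 0) next # locus name region
    parts <- strsplit(body[i], ",")[[1]]
    if (length(parts) < 2) {
      stop("malformed individual line ", i + 1, " in ", path, ": no comma")
    }
    id <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gstr) != length(loci)) {
      stop("line ", i + 1, " in ", path, ": ", length(gstr),
           " genotypes for ", length(loci), " loci")
    }
    w <- nchar(gstr[1])
    if (!w %in% c(4L, 6L) || !all(nchar(gstr) == w)) {
      stop("line ", i + 1, " in ", path, ": allele fields must all be 4 or 6 digits")
    }
    d <- w / 2
    a1 <- as.integer(substr(gstr, 1, d))
    a2 <- as.integer(substr(gstr, d + 1, w))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    k <- pop_idx[i]
    if (length(pop_names) < k || is.na(pop_names[k])) {
      pop_names[k] <- sub("[_-].*$", "", id)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = id, pop_k = k, locus = loci, a1 = a1, a2 = a2)
  }
  if (anyDuplicated(pop_names) || any(!nzchar(pop_names))) {
    pop_names <- paste0("pop", seq_along(pop_names))
  }
  calls <- dplyr::bind_rows(rows)
  calls$pop <- pop_names[calls$pop_k]
  calls$pop_k <- NULL
  genotype_table(calls, pop_levels = pop_names)
}

#' Write a genotype table as a Genepop file
#'
#' Allele codes are zero-padded to 3 digits; missing calls become `000000`.
#' Population membership is encoded with `Pop` separators in the order of
#' `pop_levels(table)`; each individual id is prefixed with its population
#' label so that population names survive a round trip.
#'
#' @param table A [genotype_table()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "corridorgen export") {
  arr <- gt_array(table)
  if (any(arr$a1 > 999, na.rm = TRUE)) stop("allele codes above 999 cannot be written in 3-digit Genepop")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(arr$loci, con)
  fmt <- function(a1, a2) {
    out <- sprintf("%03d%03d", a1, a2)
    out[is.na(a1)] <- "000000"
    out
  }
  for (p in arr$pop_levels) {
    writeLines("Pop", con)
    for (i in which(arr$pops == p)) {
      gid <- if (startsWith(arr$ids[i], paste0(p, "_"))) arr$ids[i] else paste0(p, "_", arr$ids[i])
      writeLines(paste0(gid, " ,  ",
                        paste(fmt(arr$a1[i, ], arr$a2[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
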