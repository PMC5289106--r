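#' Suitability and binary grids
#'
#' Regular rasters stored as plain matrices with a cell size in km; NA
#' marks nodata. `suitability_grid` holds continuous habitat suitability
#' in `[0, 1]`; `binary_grid` holds presence/absence.
#'
#' @param values numeric matrix in `[0, 1]` (NA = nodata).
#' @param cellsize cell edge length in km.
#' @return an object of class `suitability_grid` or `binary_grid`.
#' @export
suitability_grid <- function(values, cellsize = 1) {
  values <- as.matrix(values)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, cellsize = cellsize),
            class = "suitability_grid")
}

#' @param presence logical (or 0/1) matrix, NA = nodata.
#' @rdname suitability_grid
#' @export
binary_grid <- function(presence, cellsize = 1) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  structure(list(presence = presence, cellsize = cellsize),
            class = "binary_grid")
}

#' Equal sensitivity-plus-specificity threshold
#'
#' Chooses the binarisation cutoff at which the model's sensitivity
#' (fraction of presence scores >= t) and specificity (fraction of absence
#' scores < t) are as close as possible, scanning the union of observed
#' scores as candidates. Ties are broken by maximal sensitivity +
#' specificity, then by the lowest threshold.
#'
#' @param presence_scores suitability scores at presence records.
#' @param absence_scores suitability scores at absence/background records.
#' @return the selected threshold.
#' @export
equal_ss_threshold <- function(presence_scores, absence_scores) {
  if (!length(presence_scores) || !length(absence_scores))
    stop("presence and absence score sets must be non-empty", call. = FALSE)
  cand <- sort(unique(c(presence_scores, absence_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(absence_scores < t), numeric(1))
  gap <- abs(sens - spec)
  best <- which(gap == min(gap))
  ss <- sens[best] + spec[best]
  best <- best[ss == max(ss)]
  cand[best[1]]
}

#' Binarise a suitability grid
#'
#' @param g a `suitability_grid`.
#' @param t threshold; cells with suitability `>= t` become presence.
#' @return a `binary_grid`; nodata cells stay NA.
#' @export
binarize <- function(g, t) {
  stopifnot(is.finite(t))
  binary_grid(g$values >= t, cellsize = g$cellsize)
}

#' Ensemble agreement map
#'
#' Cellwise mean of presence indicators across an ensemble of binary
#' maps: the fraction of models predicting presence, in `[0, 1]`.
#'
#' @param grids list of congruent `binary_grid` objects.
#' @return a `suitability_grid` of agreement values.
#' @export
ensemble_agreement <- function(grids) {
  if (!length(grids)) stop("need at least one grid", call. = FALSE)
  dims <- vapply(grids, function(g) dim(g$presence), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ensemble grids have mismatched shapes", call. = FALSE)
  acc <- Reduce(`+`, lapply(grids, function(g) {
    m <- g$presence * 1; m
  }))
  suitability_grid(acc / length(grids), cellsize = grids[[1]]$cellsize)
}

#' Per-catchment patch area and cohesion
#'
#' Identifies 8-connected patches of presence cells within a catchment
#' mask and reports their count, total area, and the patch cohesion index
#' `PC = 100 * [1 - sum(p_i) / sum(p_i * sqrt(a_i))] * [1 - 1/sqrt(Z)]^-1`
#' where `p_i` is patch perimeter in cell-edge units (4-neighbour edges
#' facing non-presence cells or the mask boundary), `a_i` patch area in
#' cells, and `Z` the number of cells in the mask. Cohesion is 100 for a
#' mask fully covered by one patch, 0 for a single isolated cell, and is
#' clamped to `[0, 100]`.
#'
#' @param b a `binary_grid`.
#' @param mask logical matrix congruent with the grid (the catchment),
#'   or a list with elements `label` and `mask`.
#' @param label catchment label for the report.
#' @param scenario scenario label (e.g. `"current"` or `"LGM"`).
#' @return data frame with catchment, scenario, n_patches, area_cells,
#'   area_km2, cohesion.
#' @export
patch_metrics <- function(b, mask, label = "catchment", scenario = "current") {
  if (is.list(mask) && !is.matrix(mask)) {
    label <- mask$label
    mask <- mask$mask
  }
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(b$presence)))
    stop("mask shape does not match grid", call. = FALSE)
  Z <- sum(mask, na.rm = TRUE)
  if (Z == 1L) stop("single-cell mask: cohesion normalization undefined",
                    call. = FALSE)
  pres <- !is.na(b$presence) & b$presence & !is.na(mask) & mask
  lab <- .label_patches(pres)
  np <- max(lab)
  area_cells <- sum(pres)
  if (np == 0L)
    return(data.frame(catchment = label, scenario = scenario, n_patches = 0L,
                      area_cells = 0L, area_km2 = 0, cohesion = NA_real_))
  perim <- numeric(np); area <- numeric(np)
  nr <- nrow(pres); nc <- ncol(pres)
  inmask <- !is.na(mask) & mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- lab[i, j]
    if (k == 0L) next
    area[k] <- area[k] + 1
    for (dd in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + dd[1]; jj <- j + dd[2]
      open <- ii < 1L || ii > nr || jj < 1L || jj > nc ||
        !inmask[ii, jj] || !pres[ii, jj]
      if (open) perim[k] <- perim[k] + 1
    }
  }
  coh <- 100 * (1 - sum(perim) / sum(perim * sqrt(area))) /
    (1 - 1 / sqrt(Z))
  coh <- min(max(coh, 0), 100)
  data.frame(catchment = label, scenario = scenario, n_patches = np,
             area_cells = area_cells,
             area_km2 = area_cells * b$cellsize^2, cohesion = coh)
}

# 8-connected component labelling by iterative flood fill
.label_patches <- function(pres) {
  nr <- nrow(pres); nc <- ncol(pres)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!pres[i0, j0] || lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        if (pres[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

#' Compare current and LGM patch reports
#'
#' Per catchment: change in area and cohesion from current to LGM, with a
#' fragmentation flag set when the LGM landscape is both less cohesive and
#' split into more patches.
#'
#' @param current,lgm data frames as returned by [patch_metrics()] (one
#'   row per catchment), with matching catchment labels.
#' @return data frame: catchment, d_area_km2, d_cohesion, fragmentation.
#' @export
scenario_change <- function(current, lgm) {
  if (!setequal(current$catchment, lgm$catchment) ||
      nrow(current) != nrow(lgm))
    stop("catchment labels do not match between scenarios", call. = FALSE)
  lgm <- lgm[match(current$catchment, lgm$catchment), ]
  data.frame(
    catchment = current$catchment,
    d_area_km2 = lgm$area_km2 - current$area_km2,
    d_cohesion = lgm$cohesion - current$cohesion,
    fragmentation = !is.na(lgm$cohesion) & !is.na(current$cohesion) &
      lgm$cohesion < current$cohesion & lgm$n_patches > current$n_patches)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' matrix rows top to bottom.
#'
#' @param g a `suitability_grid` or `binary_grid`.
#' @param path file path.
#' @param nodata nodata sentinel written for NA cells.
#' @return `read_ascii_grid` returns a `suitability_grid`;
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  m <- if (inherits(g, "binary_grid")) g$presence * 1 else g$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", g$cellsize),
               paste("NODATA_value", nodata)), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  m <- as.matrix(read.table(text = lines[-(1:6)]))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"])
    stop("grid shape disagrees with header", call. = FALSE)
  m[m == vals["nodata_value"]] <- NA
  suitability_grid(m, cellsize = vals["cellsize"])
}
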