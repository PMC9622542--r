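# D8 raster hydrology: depression filling, flow directions, accumulation,
# stream derivation, relative elevation to the nearest downstream stream
# cell, and the ecohydrologically active area (EHA) mask.
#
# Direction codes: 0 = outlet (flow leaves the grid), 1..8 = the neighbor in
# fixed order E, SE, S, SW, W, NW, N, NE; NA = nodata. Ties in steepest
# descent are broken by that order, which makes routing deterministic.

d8_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
d8_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
d8_dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Fill closed depressions in a DEM
#'
#' Raises every cell inside a closed depression to its lowest pour point so
#' that each cell has a non-ascending eight-neighbor path to the grid edge
#' (Planchon-Darboux style inundation). Cells never drop below their input
#' elevation; already-drained DEMs are returned unchanged. Flats created at
#' pour-point level are resolved later by [d8_flow_directions()].
#'
#' @param dem Numeric elevation matrix; `NA` marks nodata.
#' @return Filled elevation matrix of the same shape.
#' @export
fill_depressions <- function(dem) {
  if (all(is.na(dem))) stop("DEM is entirely nodata")
  nr <- nrow(dem); nc <- ncol(dem)
  w <- matrix(Inf, nr, nc)
  edge <- row(dem) == 1L | row(dem) == nr | col(dem) == 1L | col(dem) == nc
  # cells next to nodata can drain into it, treat them as edges too
  if (anyNA(dem)) {
    nearna <- matrix(FALSE, nr, nc)
    for (k in 1:8) {
      r2 <- pmin(pmax(row(dem) + d8_dr[k], 1L), nr)
      c2 <- pmin(pmax(col(dem) + d8_dc[k], 1L), nc)
      nearna <- nearna | is.na(dem[cbind(as.vector(r2), as.vector(c2))])
    }
    edge <- edge | nearna
  }
  w[edge] <- dem[edge]
  w[is.na(dem)] <- NA_real_
  repeat {
    changed <- FALSE
    for (sweep in 1:2) {
      rows <- if (sweep == 1L) 1:nr else nr:1
      cols <- if (sweep == 1L) 1:nc else nc:1
      for (r in rows) for (cc in cols) {
        if (is.na(dem[r, cc]) || w[r, cc] <= dem[r, cc]) next
        nmin <- Inf
        for (k in 1:8) {
          r2 <- r + d8_dr[k]; c2 <- cc + d8_dc[k]
          if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
          if (is.na(w[r2, c2])) next
          if (w[r2, c2] < nmin) nmin <- w[r2, c2]
        }
        new <- max(dem[r, cc], nmin)
        if (new < w[r, cc]) { w[r, cc] <- new; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  w
}

#' D8 flow directions
#'
#' Assigns each valid cell the direction of its steepest-descent neighbor
#' among the eight adjacent cells, with drop measured per unit distance
#' (diagonal neighbors are sqrt(2) cells away). Edge cells with no lower
#' neighbor are outlets (code 0). Cells on filled flats are routed across
#' the flat toward its spill cell by breadth-first assignment, so the
#' direction graph is acyclic whenever the DEM has been run through
#' [fill_depressions()].
#'
#' @param dem Numeric elevation matrix, hydrologically conditioned.
#' @return Integer matrix of direction codes (0 outlet, 1..8 = E, SE, S, SW,
#'   W, NW, N, NE; `NA` nodata).
#' @export
d8_flow_directions <- function(dem) {
  if (all(is.na(dem))) stop("DEM is entirely nodata")
  nr <- nrow(dem); nc <- ncol(dem)
  dir <- matrix(NA_integer_, nr, nc)
  unresolved <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    z <- dem[r, cc]
    if (is.na(z)) next
    best <- 0; bestk <- 0L; onedge <- r == 1L || r == nr || cc == 1L || cc == nc
    for (k in 1:8) {
      r2 <- r + d8_dr[k]; c2 <- cc + d8_dc[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      zn <- dem[r2, c2]
      if (is.na(zn)) { onedge <- TRUE; next }  # nodata drains like the edge
      drop <- (z - zn) / d8_dist[k]
      if (drop > best) { best <- drop; bestk <- k }
    }
    if (bestk > 0L) dir[r, cc] <- bestk
    else if (onedge) dir[r, cc] <- 0L
    else unresolved[r, cc] <- TRUE
  }
  # route flats: repeatedly point unresolved cells at an equal-elevation
  # neighbor that already has a direction; BFS order keeps the graph acyclic
  while (any(unresolved)) {
    progressed <- FALSE
    idx <- which(unresolved, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; cc <- idx[i, 2]
      for (k in 1:8) {
        r2 <- r + d8_dr[k]; c2 <- cc + d8_dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (is.na(dem[r2, c2]) || is.na(dir[r2, c2])) next
        if (unresolved[r2, c2]) next
        if (dem[r2, c2] == dem[r, cc]) {
          dir[r, cc] <- k
          unresolved[r, cc] <- FALSE
          progressed <- TRUE
          break
        }
      }
    }
    if (!progressed)
      stop("unresolved interior pit or flat; run fill_depressions() first")
  }
  dir
}

# linear index of the cell that `i` (linear index) flows into, or NA for
# outlets/nodata
d8_target <- function(dir, i) {
  nr <- nrow(dir)
  k <- dir[i]
  if (is.na(k) || k == 0L) return(NA_integer_)
  r <- ((i - 1L) %% nr) + 1L
  cc <- ((i - 1L) %/% nr) + 1L
  (cc + d8_dc[k] - 1L) * nr + r + d8_dr[k]
}

#' Flow accumulation
#'
#' Counts, for each cell, the number of cells draining through it (itself
#' included): `acc(c) = 1 + sum of acc over cells whose direction points at
#' c`. Computed by topological (Kahn) ordering of the direction graph; a
#' cycle raises an error.
#'
#' @param dir Integer D8 direction matrix from [d8_flow_directions()].
#' @return Numeric matrix of upstream cell counts (`NA` on nodata cells).
#' @export
flow_accumulation <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  n <- nr * nc
  target <- rep(NA_integer_, n)
  indeg <- integer(n)
  valid <- !is.na(dir)
  for (i in which(valid)) {
    t <- d8_target(dir, i)
    if (!is.na(t)) {
      if (!valid[t]) stop("flow direction points at a nodata cell")
      target[i] <- t
      indeg[t] <- indeg[t] + 1L
    }
  }
  acc <- ifelse(valid, 1, NA_real_)
  queue <- which(valid & indeg == 0L)
  done <- 0L
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    done <- done + 1L
    t <- target[i]
    if (!is.na(t)) {
      acc[t] <- acc[t] + acc[i]
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  if (done != sum(valid)) stop("cycle detected in flow directions")
  matrix(acc, nr, nc)
}

#' Derive a stream mask from flow accumulation
#'
#' A cell is a stream cell when its accumulation reaches `threshold`
#' upstream cells; open-water land-use cells are always stream cells.
#'
#' @param acc Accumulation matrix from [flow_accumulation()].
#' @param threshold Minimum upstream cell count (>= 1).
#' @param water Optional logical/0-1 matrix of open-water cells.
#' @return Logical stream mask (`NA` on nodata cells).
#' @export
derive_streams <- function(acc, threshold = 50, water = NULL) {
  if (threshold < 1) stop("stream threshold must be >= 1")
  stream <- acc >= threshold
  if (!is.null(water)) stream <- stream | (!is.na(stream) & water > 0)
  stream
}

#' Relative elevation above the nearest downstream stream cell
#'
#' Walks each cell's D8 flow path until it meets a stream cell and reports
#' the elevation difference `dem(cell) - dem(stream cell)`. Stream cells are
#' 0; cells whose flow path leaves the grid without meeting a stream are
#' `NA`.
#'
#' @param dem Elevation matrix (conditioned, same as used for `dir`).
#' @param dir D8 direction matrix.
#' @param stream Logical stream mask.
#' @return Numeric matrix of relative elevations (m).
#' @export
relative_elevation <- function(dem, dir, stream) {
  nr <- nrow(dem); nc <- ncol(dem)
  n <- nr * nc
  # elevation of the first stream cell on each cell's downstream chain;
  # NaN marks chains that exit the grid unstreamed
  sel <- rep(NA_real_, n)
  done <- rep(FALSE, n)
  for (start in seq_len(n)) {
    if (done[start] || is.na(dir[start])) next
    path <- integer(0)
    i <- start
    val <- NaN
    repeat {
      if (done[i]) { val <- sel[i]; break }
      if (isTRUE(stream[i])) { val <- dem[i]; done[i] <- TRUE; sel[i] <- val; break }
      path <- c(path, i)
      t <- d8_target(dir, i)
      if (is.na(t)) { val <- NaN; break }   # chain exits the grid
      i <- t
    }
    sel[path] <- val
    done[path] <- TRUE
  }
  rel <- matrix(dem - sel, nr, nc)
  rel[matrix(is.nan(sel), nr, nc)] <- NA_real_
  rel
}

#' Ecohydrologically active area mask
#'
#' EHA cells sit within `cutoff` meters of vertical elevation above the
#' nearest down-gradient surface-water feature along the flow path; the
#' cutoff is inclusive.
#'
#' @param rel Relative-elevation matrix from [relative_elevation()].
#' @param cutoff Vertical cutoff in meters (default 0.5).
#' @return Logical mask (`NA` where relative elevation is undefined).
#' @export
map_eha <- function(rel, cutoff = 0.5) {
  if (cutoff <= 0) stop("EHA cutoff must be positive")
  rel >= 0 & rel <= cutoff
}
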