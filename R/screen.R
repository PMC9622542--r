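# Patch delineation and criteria computation: connected eligible patches
# become candidate restoration alternatives, each gets a contributing
# watershed from the D8 flow field, and the seven decision criteria are
# tallied per patch/watershed.

#' Nutrient loading rates per land-use sector
#'
#' Export-coefficient style loading rates (kg ha^-1 yr^-1) for total
#' nitrogen and total phosphorus in the three land-use sectors. Two named
#' scenarios are shipped: "2019" (practices in place) and "2025" (projected
#' future practices, somewhat lower agricultural rates). Rates are synthetic
#' round numbers of realistic magnitude; any non-negative set can be
#' supplied.
#'
#' @param scenario "2019" or "2025", or `NULL` when giving rates directly.
#' @param tn,tp Named numeric vectors with elements `agriculture`,
#'   `developed`, `natural` (kg ha^-1 yr^-1).
#' @return An object of class `loading_rates`.
#' @export
loading_rates <- function(scenario = "2025", tn = NULL, tp = NULL) {
  defaults <- list(
    `2019` = list(tn = c(agriculture = 30, developed = 12, natural = 5),
                  tp = c(agriculture = 1.5, developed = 0.8, natural = 0.1)),
    `2025` = list(tn = c(agriculture = 25, developed = 10, natural = 5),
                  tp = c(agriculture = 1.2, developed = 0.7, natural = 0.1)))
  if (is.null(tn) || is.null(tp)) {
    if (!scenario %in% names(defaults))
      stop("unknown loading-rate scenario: ", scenario)
    if (is.null(tn)) tn <- defaults[[scenario]]$tn
    if (is.null(tp)) tp <- defaults[[scenario]]$tp
  }
  sectors <- c("agriculture", "developed", "natural")
  for (v in list(tn, tp)) {
    if (!all(sectors %in% names(v)))
      stop("rates must be named for agriculture, developed and natural")
    if (any(v < 0)) stop("loading rates must be non-negative")
  }
  structure(list(scenario = scenario, tn = tn[sectors], tp = tp[sectors]),
            class = "loading_rates")
}

new_alt_polygon <- function(id, cells, nr, nc, cell_size, eha_cells) {
  cell_ha <- cell_size^2 / 1e4
  r <- ((cells - 1L) %% nr) + 1L
  cc <- ((cells - 1L) %/% nr) + 1L
  structure(list(id = id, cells = cells,
                 area_ha = length(cells) * cell_ha,
                 eha_ha = eha_cells * cell_ha,
                 centroid = c(row = mean(r), col = mean(cc))),
            class = "alt_polygon")
}

#' Delineate candidate restoration alternatives
#'
#' Candidate patches are 8-connected components of agricultural plus natural
#' land use, minus prime-farmland and tidal exclusion cells, that are at
#' least `min_area_ha` in size and contain at least `min_eha_ha` of
#' ecohydrologically active area. Component ids are assigned in scanline
#' order (north to south, west to east) of each component's first cell.
#'
#' @param landuse Integer land-use matrix (see [landuse_codes()]).
#' @param eha Logical EHA mask from [map_eha()].
#' @param cell_size Cell side length (m).
#' @param prime_farmland,tidal Optional logical exclusion masks (default
#'   empty).
#' @param min_area_ha Minimum patch area, hectares (default 121 = 300 ac).
#' @param min_eha_ha Minimum EHA area inside the patch, hectares
#'   (default 61 = 150 ac).
#' @return List of `alt_polygon` objects (possibly empty), each with `id`,
#'   linear `cells`, `area_ha`, `eha_ha` and `centroid`.
#' @export
delineate_alternatives <- function(landuse, eha, cell_size,
                                   prime_farmland = NULL, tidal = NULL,
                                   min_area_ha = 121, min_eha_ha = 61) {
  nr <- nrow(landuse); nc <- ncol(landuse)
  codes <- landuse_codes()
  eligible <- !is.na(landuse) &
    (landuse == codes[["agriculture"]] | landuse == codes[["natural"]])
  if (!is.null(prime_farmland)) eligible <- eligible & !(prime_farmland > 0)
  if (!is.null(tidal)) eligible <- eligible & !(tidal > 0)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  next_id <- 1L
  # scanline order over linear indices transposed so row-major (north-first)
  scan_order <- as.vector(t(matrix(seq_len(nr * nc), nr, nc)))
  for (start in scan_order) {
    if (!eligible[start] || seen[start]) next
    comp <- integer(0)
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      i <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      comp <- c(comp, i)
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- r + d8_dr[k]; c2 <- cc + d8_dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (eligible[j] && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
      }
    }
    poly <- new_alt_polygon(next_id, sort(comp), nr, nc, cell_size,
                            eha_cells = sum(eha[comp], na.rm = TRUE))
    if (poly$area_ha >= min_area_ha && poly$eha_ha >= min_eha_ha) {
      out[[length(out) + 1L]] <- poly
      next_id <- next_id + 1L
    }
  }
  out
}

#' Delineate the contributing watershed of a patch
#'
#' The watershed is the patch's own cells plus every cell whose D8 flow path
#' enters the patch, found by breadth-first search up the inverted direction
#' graph.
#'
#' @param dir D8 direction matrix.
#' @param polygon An `alt_polygon` (or a bare integer vector of linear cell
#'   indices).
#' @return Sorted integer vector of linear cell indices.
#' @export
delineate_watershed <- function(dir, polygon) {
  cells <- if (inherits(polygon, "alt_polygon")) polygon$cells else polygon
  n <- length(dir)
  if (any(cells < 1L | cells > n)) stop("polygon cells fall outside the grid")
  # invert the flow graph: upstream[[t]] = cells pointing at t
  valid <- which(!is.na(dir))
  targets <- vapply(valid, function(i) {
    t <- d8_target(dir, i); if (is.na(t)) 0L else t
  }, integer(1))
  keep <- targets > 0L
  upstream <- split(valid[keep], targets[keep])
  inset <- rep(FALSE, n)
  inset[cells] <- TRUE
  queue <- cells
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    ups <- upstream[[as.character(i)]]
    if (!is.null(ups)) {
      new <- ups[!inset[ups]]
      inset[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  which(inset)
}

#' Compute the seven decision criteria for one alternative
#'
#' Nutrient loads multiply per-sector land-use areas in the contributing
#' watershed by the scenario loading rates; AG is the agricultural share of
#' watershed land use (water cells excluded from the denominator); EHA is
#' the patch's ecohydrologically-active share; FP flags any floodplain cell
#' inside the patch; WS is the patch share of high-storage dual-class soils
#' (A/D, B/D, C/D); CF is the patch share of above-average climate flow.
#'
#' @param polygon An `alt_polygon`.
#' @param watershed Linear cell indices from [delineate_watershed()].
#' @param stack A [raster_stack()].
#' @param rates A [loading_rates()] object.
#' @return Named list: `TN_kg_yr`, `TP_kg_yr`, `AG_pct`, `EHA_pct`, `FP`,
#'   `WS_pct`, `CF_pct`.
#' @export
compute_criteria <- function(polygon, watershed, stack, rates) {
  stopifnot(inherits(polygon, "alt_polygon"), inherits(rates, "loading_rates"))
  if (length(watershed) == 0L) stop("watershed has zero area")
  cell_ha <- stack$cell_size^2 / 1e4
  codes <- landuse_codes()
  lu <- stack$landuse[watershed]
  sector_ha <- c(
    agriculture = sum(lu == codes[["agriculture"]], na.rm = TRUE),
    developed = sum(lu == codes[["developed"]], na.rm = TRUE),
    natural = sum(lu == codes[["natural"]], na.rm = TRUE)) * cell_ha
  tn <- sum(sector_ha * rates$tn)
  tp <- sum(sector_ha * rates$tp)
  land_ha <- sum(sector_ha)  # water excluded from the AG denominator
  ag <- if (land_ha > 0) 100 * sector_ha[["agriculture"]] / land_ha else 0
  pc <- polygon$cells
  npc <- length(pc)
  eha_pct <- 100 * polygon$eha_ha / polygon$area_ha
  fp <- as.integer(any(stack$floodplain[pc] > 0, na.rm = TRUE))
  ws <- 100 * sum(stack$soils[pc] %in% soil_codes()[c("A/D", "B/D", "C/D")]) / npc
  cf <- 100 * sum(stack$climateflow[pc] > 0, na.rm = TRUE) / npc
  list(TN_kg_yr = tn, TP_kg_yr = tp, AG_pct = ag, EHA_pct = eha_pct,
       FP = fp, WS_pct = ws, CF_pct = cf)
}

# adjacency between patches in raster mode: maximal components never touch,
# so "adjacent" means cell sets within a one-cell gap (Chebyshev radius 2)
patch_adjacency <- function(polys, nr) {
  n <- length(polys)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (n < 2L) return(adj)
  coords <- lapply(polys, function(p)
    cbind(((p$cells - 1L) %% nr) + 1L, ((p$cells - 1L) %/% nr) + 1L))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- coords[[i]]; b <- coords[[j]]
    near <- FALSE
    for (q in seq_len(nrow(a))) {
      if (any(abs(b[, 1] - a[q, 1]) <= 2L & abs(b[, 2] - a[q, 2]) <= 2L)) {
        near <- TRUE; break
      }
    }
    if (near) {
      adj[[i]] <- c(adj[[i]], polys[[j]]$id)
      adj[[j]] <- c(adj[[j]], polys[[i]]$id)
    }
  }
  adj
}

#' Screen a landscape into an alternatives table
#'
#' Runs the full raster pipeline: depression filling, D8 directions, flow
#' accumulation, stream derivation (open-water cells always count as
#' streams), relative elevation, EHA mapping, patch delineation, watershed
#' delineation and criteria computation, returning one row per surviving
#' alternative in the standard alternatives-table schema.
#'
#' @param stack A [raster_stack()].
#' @param rates A [loading_rates()] object.
#' @param stream_threshold Accumulation threshold for streams (cells).
#' @param eha_cutoff Vertical EHA cutoff (m).
#' @param min_area_ha,min_eha_ha Patch screening thresholds (ha).
#' @param prime_farmland,tidal Optional exclusion masks.
#' @param low_elev_cutoff Patches whose minimum DEM elevation falls below
#'   this value (m; default 0.6096 m = 2 ft) are flagged `low_elev`.
#' @return A data.frame with columns `id`, `TN_kg_yr`, `TP_kg_yr`, `AG_pct`,
#'   `EHA_pct`, `FP`, `WS_pct`, `CF_pct`, `low_elev`, `region`, `adjacency`
#'   (semicolon-joined neighbor ids), plus the polygon list as attribute
#'   `polygons`.
#' @export
screen_landscape <- function(stack, rates = loading_rates("2025"),
                             stream_threshold = 50, eha_cutoff = 0.5,
                             min_area_ha = 121, min_eha_ha = 61,
                             prime_farmland = NULL, tidal = NULL,
                             low_elev_cutoff = 0.6096) {
  stopifnot(inherits(stack, "raster_stack"))
  dem <- fill_depressions(stack$dem)
  dir <- d8_flow_directions(dem)
  acc <- flow_accumulation(dir)
  water <- stack$landuse == landuse_codes()[["water"]]
  stream <- derive_streams(acc, stream_threshold, water = water)
  rel <- relative_elevation(dem, dir, stream)
  eha <- map_eha(rel, eha_cutoff)
  polys <- delineate_alternatives(stack$landuse, eha, stack$cell_size,
                                  prime_farmland = prime_farmland,
                                  tidal = tidal, min_area_ha = min_area_ha,
                                  min_eha_ha = min_eha_ha)
  adj <- patch_adjacency(polys, nrow(dem))
  rows <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    ws <- delineate_watershed(dir, p)
    cr <- compute_criteria(p, ws, stack, rates)
    data.frame(id = p$id, TN_kg_yr = cr$TN_kg_yr, TP_kg_yr = cr$TP_kg_yr,
               AG_pct = cr$AG_pct, EHA_pct = cr$EHA_pct, FP = cr$FP,
               WS_pct = cr$WS_pct, CF_pct = cr$CF_pct,
               low_elev = as.integer(min(stack$dem[p$cells], na.rm = TRUE) <
                                       low_elev_cutoff),
               region = NA_character_,
               adjacency = paste(adj[[i]], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else empty_alternatives()
  attr(tab, "polygons") <- polys
  tab
}
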