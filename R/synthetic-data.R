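# Synthetic study systems: alternatives tables with right-skewed nutrient
# loads and bounded-proportion criteria, and raster landscapes (tilted,
# channel-carved DEM with patchy land use) with planted ground truth for
# end-to-end recovery tests.

#' Configuration for the synthetic-data generators
#'
#' Nutrient loads (TN, TP) are lognormal, giving the heavy right tails whose
#' empirical CDFs are largely concave; climate flow and the other proportion
#' criteria are scaled Beta draws in `[0, 100]` (CF uses a right-skewed
#' shape so its ECDF is concave too). Each output column/grid draws from its
#' own RNG stream derived from the master seed, so reconfiguring one column
#' leaves the others bit-identical.
#'
#' @param n_alternatives Number of table rows (>= 0).
#' @param seed Master integer seed.
#' @param tn_params,tp_params Named `c(meanlog=, sdlog=)` for lognormal
#'   loads (kg/yr); `sdlog` must be positive.
#' @param cf_params,ag_params,eha_params,ws_params Named
#'   `c(shape1=, shape2=)` Beta parameters for percent criteria; both
#'   positive.
#' @param fp_prob Probability a row has floodplain present.
#' @param low_elev_prob Probability a row is flagged below the 2-ft
#'   elevation cutoff.
#' @param n_planted_dominant Number of planted dominant rows (>= 0,
#'   <= `n_alternatives`). The default is 1 (0 for an empty table): planted
#'   dominants are written
#'   as identical best-on-everything rows, so with more than one they tie.
#' @param n_regions Number of planted region labels.
#' @param grid_rows,grid_cols Landscape grid shape (>= 2 each for
#'   [gen_landscape()]).
#' @param cell_size Cell side length in meters.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_alternatives = 500, seed = 1L,
                         tn_params = c(meanlog = 7.5, sdlog = 0.8),
                         tp_params = c(meanlog = 4.5, sdlog = 0.8),
                         cf_params = c(shape1 = 1.2, shape2 = 4),
                         ag_params = c(shape1 = 4, shape2 = 2),
                         eha_params = c(shape1 = 2, shape2 = 2),
                         ws_params = c(shape1 = 2, shape2 = 3),
                         fp_prob = 0.5, low_elev_prob = 0.1,
                         n_planted_dominant = NULL, n_regions = 4L,
                         grid_rows = 60L, grid_cols = 80L, cell_size = 30) {
  if (is.null(n_planted_dominant))
    n_planted_dominant <- min(1L, as.integer(n_alternatives))
  cfg <- list(n_alternatives = as.integer(n_alternatives),
              seed = as.integer(seed),
              tn_params = tn_params, tp_params = tp_params,
              cf_params = cf_params, ag_params = ag_params,
              eha_params = eha_params, ws_params = ws_params,
              fp_prob = fp_prob, low_elev_prob = low_elev_prob,
              n_planted_dominant = as.integer(n_planted_dominant),
              n_regions = as.integer(n_regions),
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size)
  if (cfg$n_alternatives < 0) stop("n_alternatives must be >= 0")
  for (p in c("tn_params", "tp_params"))
    if (cfg[[p]][["sdlog"]] <= 0)
      stop("lognormal sdlog must be positive in ", p)
  for (p in c("cf_params", "ag_params", "eha_params", "ws_params"))
    if (any(cfg[[p]] <= 0)) stop("Beta shapes must be positive in ", p)
  for (p in c("fp_prob", "low_elev_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (cfg$n_planted_dominant < 0 ||
      cfg$n_planted_dominant > cfg$n_alternatives)
    stop("n_planted_dominant must be in [0, n_alternatives]")
  if (cfg$cell_size <= 0) stop("cell_size must be positive")
  class(cfg) <- "synth_config"
  cfg
}

# draw from an independent RNG stream (offset from the master seed) without
# disturbing the caller's RNG state
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  force(expr)
}

#' Generate a synthetic alternatives table with planted ground truth
#'
#' Draws `n_alternatives` rows: lognormal TN/TP, Beta-scaled percent
#' criteria, Bernoulli floodplain and low-elevation flags, region labels by
#' planted centroid quadrant, and a nearest-centroid adjacency graph
#' (each row linked to at most 4 nearest centroids, symmetrized). The first
#' `n_planted_dominant` drawn rows are then overwritten so each holds the
#' strict per-table maximum on every increase-preferred criterion, has
#' floodplain present and is not low-elevation; these are the planted
#' dominants that every ranking method must recover at the top.
#'
#' @param config A [synth_config()].
#' @return A list with `table` (alternatives data.frame) and `truth` (class
#'   `planted_truth`: `dominant_ids`, `region_of_ids`).
#' @export
gen_alternatives <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_alternatives
  if (n == 0L) {
    return(list(table = empty_alternatives(),
                truth = structure(list(dominant_ids = integer(0),
                                       region_of_ids = character(0)),
                                  class = "planted_truth")))
  }
  s <- config$seed
  tn <- with_stream(s, 1L, stats::rlnorm(n, config$tn_params[["meanlog"]],
                                         config$tn_params[["sdlog"]]))
  tp <- with_stream(s, 2L, stats::rlnorm(n, config$tp_params[["meanlog"]],
                                         config$tp_params[["sdlog"]]))
  ag <- with_stream(s, 3L, 100 * stats::rbeta(n, config$ag_params[["shape1"]],
                                              config$ag_params[["shape2"]]))
  eha <- with_stream(s, 4L, 100 * stats::rbeta(n, config$eha_params[["shape1"]],
                                               config$eha_params[["shape2"]]))
  ws <- with_stream(s, 5L, 100 * stats::rbeta(n, config$ws_params[["shape1"]],
                                              config$ws_params[["shape2"]]))
  cf <- with_stream(s, 6L, 100 * stats::rbeta(n, config$cf_params[["shape1"]],
                                              config$cf_params[["shape2"]]))
  fp <- with_stream(s, 7L, stats::rbinom(n, 1L, config$fp_prob))
  low <- with_stream(s, 8L, stats::rbinom(n, 1L, config$low_elev_prob))
  cent <- with_stream(s, 9L, cbind(stats::runif(n), stats::runif(n)))
  # region = quadrant-style block of the unit square holding the centroid
  nrg <- max(1L, config$n_regions)
  side <- ceiling(sqrt(nrg))
  block <- pmin(floor(cent[, 1] * side), side - 1) +
    side * pmin(floor(cent[, 2] * side), side - 1)
  region <- paste0("R", (block %% nrg) + 1L)

  # planted dominants: strict maximum on every increase-preferred criterion
  k <- config$n_planted_dominant
  dominant <- seq_len(k)
  if (k > 0L) {
    bump_load <- function(v) max(v) * 1.05
    bump_pct <- function(v) {
      m <- max(v); if (m >= 100) 100 else m + 0.5 * (100 - m)
    }
    tn[dominant] <- bump_load(tn); tp[dominant] <- bump_load(tp)
    ag[dominant] <- bump_pct(ag); eha[dominant] <- bump_pct(eha)
    ws[dominant] <- bump_pct(ws); cf[dominant] <- bump_pct(cf)
    fp[dominant] <- 1L
    low[dominant] <- 0L
  }

  # adjacency: link each row to its <= 4 nearest other centroids, symmetric
  adj <- lapply(seq_len(n), function(i) {
    d <- sqrt((cent[, 1] - cent[i, 1])^2 + (cent[, 2] - cent[i, 2])^2)
    d[i] <- Inf
    utils::head(order(d), min(4L, n - 1L))
  })
  for (i in seq_len(n)) for (j in adj[[i]])
    if (!(i %in% adj[[j]])) adj[[j]] <- sort(c(adj[[j]], i))

  tab <- data.frame(id = seq_len(n), TN_kg_yr = tn, TP_kg_yr = tp,
                    AG_pct = ag, EHA_pct = eha, FP = as.integer(fp),
                    WS_pct = ws, CF_pct = cf, low_elev = as.integer(low),
                    region = region,
                    adjacency = vapply(adj, paste, character(1),
                                       collapse = ";"),
                    stringsAsFactors = FALSE)
  truth <- structure(list(dominant_ids = as.integer(dominant),
                          region_of_ids = stats::setNames(region,
                                                          as.character(tab$id))),
                     class = "planted_truth")
  list(table = tab, truth = truth)
}

#' Generate a synthetic raster landscape
#'
#' The DEM is a plane tilted toward the south edge plus bounded uniform
#' noise, with one carved channel walked from the north edge to the south
#' edge whose elevations decrease strictly downstream (so D8 routing has a
#' guaranteed outlet). Land-use and soil grids are contiguous patches
#' (nearest-seed tessellation); channel cells are open water; the
#' floodplain mask buffers the channel by two cells; climate flow is a
#' binary patch mosaic.
#'
#' @param config A [synth_config()]; `grid_rows` and `grid_cols` must be
#'   >= 2.
#' @param relief Total north-south elevation drop of the plane (m).
#' @param noise Half-width of the uniform DEM noise (m); 0 gives an exact
#'   plane (no channel carving, for degenerate-grid checks use this).
#' @return A [raster_stack()] with attribute `channel` (two-column matrix of
#'   the carved channel's row/col path, north to south).
#' @export
gen_landscape <- function(config, relief = 10, noise = 0.3) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (nr < 2L || nc < 2L) stop("landscape grid must be at least 2 x 2")
  s <- config$seed
  base <- matrix(rep(seq(relief, 0, length.out = nr), nc), nr, nc)
  dem <- base
  if (noise > 0)
    dem <- dem + with_stream(s, 101L, matrix(stats::runif(nr * nc, -noise,
                                                          noise), nr, nc))
  channel <- matrix(integer(0), 0, 2)
  if (noise > 0) {
    # carve one monotone channel from the north edge to the south edge
    path <- with_stream(s, 102L, {
      col <- sample.int(nc, 1L)
      p <- matrix(NA_integer_, nr, 2)
      for (r in 1:nr) {
        p[r, ] <- c(r, col)
        col <- min(max(col + sample(c(-1L, 0L, 1L), 1L), 1L), nc)
      }
      p
    })
    depth <- noise + 0.2
    for (r in 1:nr) {
      i <- path[r, ]
      carved <- base[i[1], i[2]] - depth
      if (r > 1L) {
        prev <- path[r - 1L, ]
        carved <- min(carved, dem[prev[1], prev[2]] - 0.01)
      }
      dem[i[1], i[2]] <- carved
    }
    channel <- path
  }
  landuse <- with_stream(s, 103L, patch_mosaic(nr, nc,
    n_seeds = max(6L, (nr * nc) %/% 200L),
    classes = landuse_codes(),
    probs = c(0.45, 0.12, 0.35, 0.08)))
  soils <- with_stream(s, 104L, patch_mosaic(nr, nc,
    n_seeds = max(6L, (nr * nc) %/% 250L),
    classes = soil_codes(),
    probs = c(0.4, 0.2, 0.2, 0.2)))
  cfgrid <- with_stream(s, 105L, patch_mosaic(nr, nc,
    n_seeds = max(6L, (nr * nc) %/% 300L),
    classes = c(no = 0L, yes = 1L), probs = c(0.5, 0.5)))
  if (nrow(channel)) landuse[channel] <- landuse_codes()[["water"]]
  flood <- matrix(0L, nr, nc)
  if (nrow(channel)) {
    for (r in seq_len(nrow(channel))) {
      rr <- max(1L, channel[r, 1] - 2L):min(nr, channel[r, 1] + 2L)
      cc <- max(1L, channel[r, 2] - 2L):min(nc, channel[r, 2] + 2L)
      flood[rr, cc] <- 1L
    }
  }
  stack <- raster_stack(dem, landuse, soils, flood, cfgrid,
                        cell_size = config$cell_size)
  attr(stack, "channel") <- channel
  stack
}

# contiguous class patches: every cell takes the class of its nearest seed
patch_mosaic <- function(nr, nc, n_seeds, classes, probs) {
  sr <- stats::runif(n_seeds, 1, nr)
  sc <- stats::runif(n_seeds, 1, nc)
  scl <- sample(classes, n_seeds, replace = TRUE, prob = probs)
  g <- matrix(classes[[1]], nr, nc)
  for (r in 1:nr) {
    d2 <- outer(rep(1, nc), (r - sr)^2) + outer(1:nc, sc, function(x, y) (x - y)^2)
    g[r, ] <- scl[max.col(-d2, ties.method = "first")]
  }
  g
}

#' Write planted ground truth as JSON
#'
#' @param truth A `planted_truth` object from [gen_alternatives()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(list(dominant_ids = truth$dominant_ids,
                            region_of_ids = as.list(truth$region_of_ids)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
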