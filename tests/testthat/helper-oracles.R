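# Independent brute-force oracles and small fixture builders. These
# re-derive every result by direct definition (chain walking, all-pairs
# comparison, elementwise loops) so the package's graph/matrix
# implementations are checked against something structurally different.

# neighbor geometry shared with the package contract:
# codes 1..8 = E, SE, S, SW, W, NW, N, NE
OFF <- list(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
            dc = c(1, 1, 0, -1, -1, -1, 0, 1),
            dist = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))

oracle_target <- function(dir, r, cc) {
  k <- dir[r, cc]
  if (is.na(k) || k == 0) return(NULL)
  c(r + OFF$dr[k], cc + OFF$dc[k])
}

# per-cell argmax of drop/distance over the 8 neighbors; NA where no
# strictly lower neighbor exists (the oracle does not route flats)
oracle_d8 <- function(dem) {
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_integer_, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    if (is.na(dem[r, cc])) next
    drops <- rep(-Inf, 8)
    for (k in 1:8) {
      r2 <- r + OFF$dr[k]; c2 <- cc + OFF$dc[k]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && !is.na(dem[r2, c2]))
        drops[k] <- (dem[r, cc] - dem[r2, c2]) / OFF$dist[k]
    }
    if (max(drops) > 0) out[r, cc] <- which.max(drops)
    else if (r == 1 || r == nr || cc == 1 || cc == nc) out[r, cc] <- 0L
  }
  out
}

# walk the full chain from (r, cc); returns matrix of visited (row, col)
oracle_chain <- function(dir, r, cc, max_steps = length(dir) + 1) {
  path <- matrix(c(r, cc), 1, 2)
  for (s in seq_len(max_steps)) {
    nxt <- oracle_target(dir, path[nrow(path), 1], path[nrow(path), 2])
    if (is.null(nxt)) return(path)
    path <- rbind(path, nxt)
  }
  stop("chain did not terminate: cycle")
}

# accumulation by counting, for every cell, all cells whose chain passes
# through it
oracle_accumulation <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  acc <- matrix(0, nr, nc)
  acc[is.na(dir)] <- NA
  for (r in 1:nr) for (cc in 1:nc) {
    if (is.na(dir[r, cc])) next
    path <- oracle_chain(dir, r, cc)
    for (i in seq_len(nrow(path))) acc[path[i, 1], path[i, 2]] <-
        acc[path[i, 1], path[i, 2]] + 1
  }
  acc
}

# watershed by chain membership: every cell whose chain enters the set
oracle_watershed <- function(dir, cells) {
  nr <- nrow(dir)
  inset <- rep(FALSE, length(dir))
  inset[cells] <- TRUE
  out <- logical(length(dir))
  for (i in seq_along(dir)) {
    if (is.na(dir[i])) next
    r <- ((i - 1) %% nr) + 1; cc <- ((i - 1) %/% nr) + 1
    path <- oracle_chain(dir, r, cc)
    idx <- (path[, 2] - 1) * nr + path[, 1]
    if (any(inset[idx])) out[i] <- TRUE
  }
  which(out)
}

# sort-and-assign ranking with average ties
oracle_rank <- function(scores, higher = TRUE) {
  s <- if (higher) -scores else scores
  out <- numeric(length(s))
  for (i in seq_along(s))
    out[i] <- sum(s < s[i]) + (1 + sum(s == s[i])) / 2
  out
}

# elementwise weighted aggregation oracles
oracle_value <- function(x, w) {
  v <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    v[i] <- v[i] + w[j] * x[i, j]
  v
}
oracle_distance <- function(x, w, p) {
  d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    d[i] <- d[i] + w[j]^p * x[i, j]^p
  d
}

# all-pairs dominance on an ordinal level matrix (rows = regions)
oracle_dominance_pairs <- function(lv) {
  out <- NULL
  for (a in rownames(lv)) for (b in rownames(lv)) {
    if (a == b) next
    if (all(lv[a, ] >= lv[b, ]) && any(lv[a, ] > lv[b, ]))
      out <- rbind(out, data.frame(dominator = a, dominated = b,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(dominator = character(0),
                               dominated = character(0),
                               stringsAsFactors = FALSE) else out
}

# flood fill over an eligibility mask with 8-connectivity, scanline seeds
oracle_components <- function(eligible) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  label <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in 1:nr) for (cc in 1:nc) {
    if (!eligible[r, cc] || label[r, cc] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    label[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in 1:8) {
        r2 <- p[1] + OFF$dr[k]; c2 <- p[2] + OFF$dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            eligible[r2, c2] && label[r2, c2] == 0L) {
          label[r2, c2] <- nxt
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
  }
  label
}

# pit-free random DEM: strong north-south gradient plus sub-gradient noise,
# so every interior cell has a strictly lower neighbor and no ties occur
random_drained_dem <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rep(rev(seq_len(nr)), nc), nr, nc) + runif(nr * nc, -0.3, 0.3)
}

# fully random DEM (will generally contain pits)
random_rough_dem <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc, 0, 5), nr, nc)
}

# tiny raster stack around a given landuse grid, flat criteria layers
tiny_stack <- function(landuse, dem = NULL, cell_size = 100,
                       soils = NULL, flood = NULL, cf = NULL) {
  nr <- nrow(landuse); nc <- ncol(landuse)
  if (is.null(dem)) dem <- matrix(rep(rev(seq_len(nr)), nc), nr, nc)
  if (is.null(soils)) soils <- matrix(0L, nr, nc)
  if (is.null(flood)) flood <- matrix(0L, nr, nc)
  if (is.null(cf)) cf <- matrix(0L, nr, nc)
  raster_stack(dem, landuse, soils, flood, cf, cell_size = cell_size)
}

# minimal alternatives table holding arbitrary criteria columns
make_table <- function(..., low_elev = NULL, region = NULL,
                       adjacency = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  tab <- data.frame(id = seq_len(n))
  map <- criterion_columns()
  for (nm in names(cols)) tab[[map[[nm]]]] <- cols[[nm]]
  tab$low_elev <- if (is.null(low_elev)) rep(0L, n) else low_elev
  tab$region <- if (is.null(region)) rep("R1", n) else region
  tab$adjacency <- if (is.null(adjacency)) rep("", n) else adjacency
  tab
}

# random ordinal coded table as produced by color_code()
random_coded_table <- function(n_regions, n_criteria) {
  codes <- matrix(sample(c("unfavorable", "middle", "favorable"),
                         n_regions * n_criteria, replace = TRUE),
                  n_regions, n_criteria,
                  dimnames = list(paste0("R", seq_len(n_regions)),
                                  paste0("C", seq_len(n_criteria))))
  structure(list(codes = codes, dropped = character(0),
                 category = "overall"),
            class = "coded_table")
}
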