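# Priority-set assembly: combine the two objectives' top-k sets and the
# lowest-Z1 set, expand to adjacent alternatives, exclude low-elevation
# alternatives and assign regions.

#' Combine top-ranked and lowest-Z1 sets into priority categories
#'
#' Highest-priority (`both`) alternatives rank in the top k under both
#' weighting scenarios. Water-quality priorities are the remaining
#' top-water-quality alternatives plus the lowest-Z1 alternatives not
#' already in `both`; climate-resilience priorities are the remaining
#' top-climate alternatives. The three categories are disjoint: an id that
#' qualifies as a water-quality priority via its Z1 score is not repeated
#' under climate resilience.
#'
#' @param top_wq,top_cr,low_z1 Character id vectors (top 100 water quality,
#'   top 100 climate resilience, lowest-100 Z1).
#' @return An object of class `priority_sets`: `wq`, `cr`, `both` (sorted
#'   character vectors), plus empty `adjacent` and `excluded_low_elev`
#'   placeholders filled by the downstream steps.
#' @export
build_priority_sets <- function(top_wq, top_cr, low_z1 = character(0)) {
  top_wq <- as.character(top_wq); top_cr <- as.character(top_cr)
  low_z1 <- as.character(low_z1)
  both <- intersect(top_wq, top_cr)
  wq <- union(setdiff(top_wq, top_cr), setdiff(low_z1, both))
  cr <- setdiff(setdiff(top_cr, top_wq), wq)
  sort_ids <- function(x) {
    num <- suppressWarnings(as.numeric(x))
    if (anyNA(num)) sort(x) else x[order(num)]
  }
  structure(list(wq = sort_ids(wq), cr = sort_ids(cr), both = sort_ids(both),
                 adjacent = character(0), excluded_low_elev = character(0),
                 regions = NULL),
            class = "priority_sets")
}

#' @export
print.priority_sets <- function(x, ...) {
  cat(sprintf(paste0("priority sets: %d water quality, %d climate",
                     " resilience, %d both, %d adjacent, %d excluded",
                     " (low elevation)\n"),
              length(x$wq), length(x$cr), length(x$both),
              length(x$adjacent), length(x$excluded_low_elev)))
  invisible(x)
}

#' Alternatives adjacent to a priority set
#'
#' Returns the ids not already in the priority set that neighbor at least
#' one priority id under the (symmetric) adjacency relation.
#'
#' @param priority_ids Character/integer id vector.
#' @param adjacency Named list of neighbor-id vectors
#'   (see [adjacency_list()]).
#' @return Character vector of adjacent ids.
#' @export
expand_adjacent <- function(priority_ids, adjacency) {
  pr <- as.character(priority_ids)
  nb <- unique(as.character(unlist(adjacency[pr], use.names = FALSE)))
  setdiff(nb, pr)
}

#' Partition ids by the low-elevation flag
#'
#' Splits a set of ids into those at or above the two-foot elevation cutoff
#' (kept) and those below it (excluded from mapping, reported for audit).
#' The cutoff itself is applied upstream as a boolean attribute.
#'
#' @param ids Character/integer id vector.
#' @param low_elev Named 0/1 vector (names = ids) or an alternatives
#'   data.frame with `id` and `low_elev` columns.
#' @return List with `kept` and `excluded` character vectors.
#' @export
exclude_low_elevation <- function(ids, low_elev) {
  ids <- as.character(ids)
  if (is.data.frame(low_elev))
    low_elev <- stats::setNames(low_elev$low_elev, as.character(low_elev$id))
  if (!all(ids %in% names(low_elev)))
    stop("low-elevation attribute missing for some ids")
  flag <- low_elev[ids] > 0
  list(kept = ids[!flag], excluded = ids[flag])
}

#' Assign ids to regions and count memberships
#'
#' @param ids Character/integer id vector.
#' @param region_map Named character vector (names = ids) or an
#'   alternatives data.frame with `id` and `region` columns. Unmapped ids
#'   fall into `"unassigned"`.
#' @return List with `membership` (named region per id) and `counts`
#'   (table of ids per region).
#' @export
assign_regions <- function(ids, region_map) {
  ids <- as.character(ids)
  if (is.data.frame(region_map))
    region_map <- stats::setNames(region_map$region,
                                  as.character(region_map$id))
  membership <- region_map[ids]
  membership[is.na(membership)] <- "unassigned"
  names(membership) <- ids
  list(membership = membership, counts = table(membership))
}

#' Full priority-set pipeline for an alternatives table
#'
#' Runs the 28-run ranking sweep, aggregates mean ranks per objective,
#' takes the two top-k sets and the lowest-k Z1 set, builds the priority
#' categories, expands to adjacent alternatives, then applies the
#' low-elevation exclusion to every category (adjacent ids included) and
#' assigns regions to the surviving priority ids.
#'
#' @param table Alternatives data.frame.
#' @param specs Criterion specifications.
#' @param k Top-set size (default 100).
#' @param p,form Distance-function parameters (see [distance_score()]).
#' @return A `priority_sets` object with `adjacent`, `excluded_low_elev`
#'   and `regions` filled in, plus attributes `runs` (the ranking runs),
#'   `mean_ranks` (per objective) and `pca` (the `pca_result`).
#' @export
prioritize_alternatives <- function(table, specs = default_criterion_specs(),
                                    k = 100, p = 2,
                                    form = c("powersum", "lp")) {
  form <- match.arg(form)
  runs <- run_ranking_sweep(table, specs, p = p, form = form)
  obj <- vapply(runs, `[[`, character(1), "objective")
  mean_wq <- aggregate_scenario(runs[obj == "water_quality"])
  mean_cr <- aggregate_scenario(runs[obj == "climate_resilience"])
  pca <- pca_first_component(table, specs$name)
  sets <- build_priority_sets(top_k(mean_wq, k), top_k(mean_cr, k),
                              lowest_k_z1(pca, k))
  priority <- c(sets$wq, sets$cr, sets$both)
  sets$adjacent <- expand_adjacent(priority, adjacency_list(table))
  part <- exclude_low_elevation(c(priority, sets$adjacent), table)
  sets$excluded_low_elev <- part$excluded
  sets$wq <- setdiff(sets$wq, part$excluded)
  sets$cr <- setdiff(sets$cr, part$excluded)
  sets$both <- setdiff(sets$both, part$excluded)
  sets$adjacent <- setdiff(sets$adjacent, part$excluded)
  sets$regions <- assign_regions(c(sets$wq, sets$cr, sets$both), table)
  attr(sets, "runs") <- runs
  attr(sets, "mean_ranks") <- list(water_quality = mean_wq,
                                   climate_resilience = mean_cr)
  attr(sets, "pca") <- pca
  sets
}

#' Write priority sets as JSON
#'
#' @param sets A `priority_sets` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_priority_sets <- function(sets, path) {
  stopifnot(inherits(sets, "priority_sets"))
  jsonlite::write_json(
    list(wq = sets$wq, cr = sets$cr, both = sets$both,
         adjacent = sets$adjacent,
         excluded_low_elev = sets$excluded_low_elev,
         region_counts = if (is.null(sets$regions)) NULL
                         else as.list(sets$regions$counts)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
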