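# Consequence-table tradeoff screening: region x criterion averages over a
# priority category, 20/60/20 ordinal color coding with preference
# direction, irrelevant-criterion elimination, and dominance analysis on
# the coded rows.

#' Build a region-by-criterion consequence table
#'
#' Averages the raw criteria measures of the category's priority
#' alternatives inside each region. Categories: `overall` covers all
#' priority alternatives (wq, cr and both), `water_quality` covers wq plus
#' both, `climate_resilience` covers cr plus both. Regions with no category
#' members are omitted (not zero-filled).
#'
#' @param table Alternatives data.frame (must carry `region`).
#' @param sets A `priority_sets` object.
#' @param category `"overall"`, `"water_quality"` or
#'   `"climate_resilience"`.
#' @param criteria Criterion names (default all seven).
#' @return An object of class `consequence_table`: `means` (region x
#'   criterion matrix), `category`, `n_members` (per region).
#' @export
consequence_table <- function(table, sets,
                              category = c("overall", "water_quality",
                                           "climate_resilience"),
                              criteria = names(criterion_columns())) {
  category <- match.arg(category)
  stopifnot(inherits(sets, "priority_sets"))
  members <- switch(category,
                    overall = c(sets$wq, sets$cr, sets$both),
                    water_quality = c(sets$wq, sets$both),
                    climate_resilience = c(sets$cr, sets$both))
  sub <- table[as.character(table$id) %in% members, , drop = FALSE]
  if (!nrow(sub)) stop("no priority alternatives in category ", category)
  regions <- sort(unique(sub$region))
  m <- criteria_matrix(sub, criteria)
  means <- do.call(rbind, lapply(regions, function(rg)
    colMeans(m[sub$region == rg, , drop = FALSE])))
  rownames(means) <- regions
  structure(list(means = means, category = category,
                 n_members = stats::setNames(
                   vapply(regions, function(rg) sum(sub$region == rg),
                          integer(1)), regions)),
            class = "consequence_table")
}

#' @export
print.consequence_table <- function(x, ...) {
  cat(sprintf("consequence table (%s): %d regions\n", x$category,
              nrow(x$means)))
  print(round(x$means, 2))
  invisible(x)
}

#' Color-code a consequence table by 20/60/20 placement
#'
#' Within each criterion, region means at or above the 80th percentile of
#' desirability are coded `favorable`, at or below the 20th percentile
#' `unfavorable`, and `middle` otherwise (linear-interpolation percentiles;
#' cells exactly at a cut take the non-middle class). All criteria prefer
#' larger values. For the nonlinear (ECDF-scaled) criteria the cuts are
#' taken on ECDF-transformed means when a reference table is supplied
#' (`coding = "scaled"`), mirroring the risk-averse preference scale; the
#' transform is monotone, so codes differ from raw coding only through the
#' percentile geometry. Columns without spread, and every column of a
#' single-region table, are coded all-middle.
#'
#' @param ct A `consequence_table`.
#' @param specs Criterion specifications ([default_criterion_specs()]).
#' @param reference Alternatives data.frame supplying the full-table ECDF
#'   for nonlinear criteria (required for `coding = "scaled"`).
#' @param coding `"scaled"` (default when `reference` given) or `"raw"`.
#' @return An object of class `coded_table`: `codes` (region x criterion
#'   character matrix: `"favorable"`, `"middle"`, `"unfavorable"`),
#'   `dropped` (criteria removed so far, empty here), `category`.
#' @export
color_code <- function(ct, specs = default_criterion_specs(),
                       reference = NULL, coding = c("scaled", "raw")) {
  coding <- match.arg(coding)
  stopifnot(inherits(ct, "consequence_table"))
  if (coding == "scaled" && is.null(reference)) coding <- "raw"
  means <- ct$means
  codes <- matrix("middle", nrow(means), ncol(means),
                  dimnames = dimnames(means))
  if (nrow(means) >= 2L) {
    for (j in colnames(means)) {
      v <- means[, j]
      if (coding == "scaled" &&
          specs$scaling[specs$name == j] == "ecdf") {
        ref <- criteria_matrix(reference, j)[, 1]
        n <- length(ref)
        v <- vapply(v, function(x) sum(ref <= x) / n, numeric(1))
      }
      if (diff(range(v)) == 0) next  # no spread: all middle
      cuts <- stats::quantile(v, c(0.2, 0.8), names = FALSE, type = 7)
      codes[v >= cuts[2], j] <- "favorable"
      codes[v <= cuts[1], j] <- "unfavorable"
    }
  } else {
    message("single-region consequence table: all cells coded middle")
  }
  structure(list(codes = codes, dropped = character(0),
                 category = ct$category),
            class = "coded_table")
}

#' Drop criteria that do not distinguish the regions
#'
#' Criteria whose code is identical across all regions carry no information
#' for the comparison and are removed; the dropped names are recorded.
#'
#' @param coded A `coded_table`.
#' @return A `coded_table` with uniform columns removed and listed in
#'   `dropped`.
#' @export
drop_irrelevant <- function(coded) {
  stopifnot(inherits(coded, "coded_table"))
  uniform <- apply(coded$codes, 2, function(col) length(unique(col)) == 1L)
  if (all(uniform))
    warning("every criterion is uniform across regions; none retained")
  coded$dropped <- c(coded$dropped, colnames(coded$codes)[uniform])
  coded$codes <- coded$codes[, !uniform, drop = FALSE]
  coded
}

code_level <- c(unfavorable = 1L, middle = 2L, favorable = 3L)

#' Dominance analysis on a coded consequence table
#'
#' Region A dominates region B when A's code is at least as good on every
#' retained criterion and strictly better on at least one
#' (favorable > middle > unfavorable). Reports all dominated pairs, the
#' non-dominated set, and the region (if any) that dominates all others.
#'
#' @param coded A `coded_table` (>= 2 regions).
#' @return List with `pairs` (data.frame `dominator`, `dominated`),
#'   `non_dominated` (character), `dominator_of_all` (character or `NA`).
#' @export
dominance <- function(coded) {
  stopifnot(inherits(coded, "coded_table"))
  codes <- coded$codes
  if (nrow(codes) < 2L) stop("dominance needs at least two regions")
  lv <- matrix(code_level[codes], nrow(codes), ncol(codes),
               dimnames = dimnames(codes))
  regions <- rownames(lv)
  pairs <- list()
  for (a in regions) for (b in setdiff(regions, a)) {
    da <- lv[a, ]; db <- lv[b, ]
    if (all(da >= db) && any(da > db))
      pairs[[length(pairs) + 1L]] <- data.frame(dominator = a, dominated = b,
                                                stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(dominator = character(0),
                           dominated = character(0),
                           stringsAsFactors = FALSE)
  non_dominated <- setdiff(regions, unique(pairs$dominated))
  dominates_all <- vapply(regions, function(a)
    all(setdiff(regions, a) %in% pairs$dominated[pairs$dominator == a]),
    logical(1))
  list(pairs = pairs, non_dominated = non_dominated,
       dominator_of_all = if (any(dominates_all))
         regions[dominates_all][1] else NA_character_)
}
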