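# Multi-criteria ranking: objective-emphasis weight scenarios, the additive
# value function, the compromise-programming distance function, rank
# assignment, sensitivity-sweep execution and top-k aggregation.

#' Build objective-emphasis weight scenarios
#'
#' For each objective, one scenario per emphasis proportion: the emphasized
#' objective's criteria share the emphasis weight equally and the other
#' objective's criteria share the remainder equally. With the default 60-90%
#' range in 5% steps this yields seven sensitivity iterations per objective;
#' e.g. at 60% water-quality emphasis each of the five water-quality
#' criteria gets 0.6/5 = 0.12 and each of the two climate-resilience
#' criteria gets 0.4/2 = 0.2.
#'
#' @param specs Criterion specification data.frame with `name` and `group`
#'   columns ([default_criterion_specs()]).
#' @param range Emphasis proportion range (default `c(0.60, 0.90)`).
#' @param step Emphasis increment (default 0.05).
#' @return List of `weight_scenario` objects: `objective`, `emphasis`, and
#'   `weights` (named vector summing to 1).
#' @export
make_weight_scenarios <- function(specs = default_criterion_specs(),
                                  range = c(0.60, 0.90), step = 0.05) {
  groups <- split(specs$name, specs$group)
  objectives <- names(groups)
  if (length(objectives) != 2L || any(lengths(groups) == 0L))
    stop("criteria must fall into exactly two non-empty objective groups")
  emphases <- seq(range[1], range[2], by = step)
  out <- list()
  for (obj in objectives) {
    other <- setdiff(objectives, obj)
    for (w in emphases) {
      weights <- stats::setNames(numeric(nrow(specs)), specs$name)
      weights[groups[[obj]]] <- w / length(groups[[obj]])
      weights[groups[[other]]] <- (1 - w) / length(groups[[other]])
      out[[length(out) + 1L]] <- structure(
        list(objective = obj, emphasis = w, weights = weights),
        class = "weight_scenario")
    }
  }
  out
}

check_weights <- function(weights, crits) {
  if (!all(crits %in% names(weights)))
    stop("weights missing for some criteria")
  w <- weights[crits]
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  w
}

#' Additive value score
#'
#' Aggregates a value-oriented scaled matrix into an overall value per
#' alternative, `V_i = sum_j w_j x_ij` (multi-attribute value theory).
#'
#' @param scaled A value-oriented `scaled_matrix` from [scale_matrix()].
#' @param weights Named weight vector summing to 1.
#' @return Numeric vector of values in `[0, 1]`, named by alternative id.
#' @export
value_score <- function(scaled, weights) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  if (scaled$orientation != "value")
    stop("value_score needs a value-oriented scaled matrix")
  w <- check_weights(weights, colnames(scaled$values))
  drop(scaled$values %*% w)
}

#' Compromise-programming distance score
#'
#' Aggregates a distance-oriented scaled matrix into an overall distance
#' from the ideal alternative. The default form is the power sum
#' `D_i = sum_j w_j^p x_ij^p` as used with the weighting sweeps here; the
#' conventional Lp norm `(sum_j (w_j x_ij)^p)^(1/p)` is available via
#' `form = "lp"`. With `p = 1` the two coincide and the ranking is the
#' mirror image of the value-function ranking under identical complementary
#' scalings. `D_i = 0` exactly when an alternative is ideal on every
#' criterion.
#'
#' @param scaled A distance-oriented `scaled_matrix`.
#' @param weights Named weight vector summing to 1.
#' @param p Distance norm, `p >= 1` (default 2, Euclidean-style).
#' @param form `"powersum"` (default) or `"lp"`.
#' @return Numeric non-negative vector, named by alternative id.
#' @export
distance_score <- function(scaled, weights, p = 2,
                           form = c("powersum", "lp")) {
  form <- match.arg(form)
  stopifnot(inherits(scaled, "scaled_matrix"))
  if (scaled$orientation != "distance")
    stop("distance_score needs a distance-oriented scaled matrix")
  if (p < 1) stop("distance norm p must be >= 1")
  w <- check_weights(weights, colnames(scaled$values))
  if (form == "powersum") drop(scaled$values^p %*% w^p)
  else drop((scaled$values^p %*% w^p))^(1 / p)
}

#' Rank scores with average ties
#'
#' Rank 1 is the best score (highest under `better = "higher"`, lowest
#' under `"lower"`); tied scores share the average of the ranks they cover,
#' so ranks always sum to `n(n+1)/2`.
#'
#' @param scores Finite numeric vector.
#' @param better `"higher"` or `"lower"`.
#' @return Numeric rank vector, names preserved.
#' @export
rank_alternatives <- function(scores, better = c("higher", "lower")) {
  better <- match.arg(better)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (better == "higher") rank(-scores, ties.method = "average")
  else rank(scores, ties.method = "average")
}

#' Run the full ranking sensitivity sweep
#'
#' Executes every weight scenario under both ranking methods: the value
#' function on the value-oriented scaling and the distance function on the
#' distance-oriented scaling. With the default seven emphasis levels and
#' two objectives this is 28 runs (7 iterations x 2 objectives x 2
#' methods).
#'
#' @param table Alternatives data.frame.
#' @param specs Criterion specifications.
#' @param p Distance norm for [distance_score()].
#' @param form Distance form (see [distance_score()]).
#' @param range,step Emphasis schedule for [make_weight_scenarios()].
#' @return List of `ranking_run` objects: `method`, `objective`,
#'   `emphasis`, `scores`, `ranks` (named by id).
#' @export
run_ranking_sweep <- function(table, specs = default_criterion_specs(),
                              p = 2, form = c("powersum", "lp"),
                              range = c(0.60, 0.90), step = 0.05) {
  form <- match.arg(form)
  measures <- criteria_matrix(table, specs$name)
  sc_val <- scale_matrix(measures, specs, "value")
  sc_dst <- scale_matrix(measures, specs, "distance")
  scenarios <- make_weight_scenarios(specs, range, step)
  runs <- list()
  for (sc in scenarios) {
    v <- value_score(sc_val, sc$weights)
    d <- distance_score(sc_dst, sc$weights, p = p, form = form)
    ids <- as.character(table$id)
    runs[[length(runs) + 1L]] <- structure(
      list(method = "value", objective = sc$objective,
           emphasis = sc$emphasis,
           scores = stats::setNames(v, ids),
           ranks = stats::setNames(rank_alternatives(v, "higher"), ids)),
      class = "ranking_run")
    runs[[length(runs) + 1L]] <- structure(
      list(method = "distance", objective = sc$objective,
           emphasis = sc$emphasis,
           scores = stats::setNames(d, ids),
           ranks = stats::setNames(rank_alternatives(d, "lower"), ids)),
      class = "ranking_run")
  }
  runs
}

#' Aggregate one objective's runs to mean ranks
#'
#' Averages each alternative's rank over the 14 runs of one objective's
#' scenario family (7 sensitivity iterations x 2 methods). Ranks, not raw
#' scores, are averaged: value and powered-distance scores live on
#' incommensurable scales.
#'
#' @param runs List of `ranking_run` objects, all for one objective,
#'   covering every emphasis under both methods.
#' @return Named numeric vector of mean ranks.
#' @export
aggregate_scenario <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  objectives <- unique(vapply(runs, `[[`, character(1), "objective"))
  if (length(objectives) != 1L)
    stop("aggregate_scenario expects runs for a single objective")
  key <- table(paste(vapply(runs, `[[`, character(1), "method"),
                     vapply(runs, function(r) format(r$emphasis), character(1))))
  if (any(key != 1L)) stop("duplicate method/emphasis runs")
  emphases <- unique(vapply(runs, `[[`, numeric(1), "emphasis"))
  methods <- unique(vapply(runs, `[[`, character(1), "method"))
  if (length(runs) != length(emphases) * length(methods))
    stop("incomplete scenario family: expected every emphasis x method run")
  rankmat <- vapply(runs, `[[`, runs[[1]]$ranks, "ranks")
  rowMeans(rankmat)
}

#' Select the top-k alternatives by mean rank
#'
#' The `k` alternatives with the smallest mean rank; ties at the boundary
#' are broken by ascending id, and all ids are returned when fewer than `k`
#' exist.
#'
#' @param mean_ranks Named numeric vector (names = ids).
#' @param k Set size (default 100).
#' @return Character vector of ids.
#' @export
top_k <- function(mean_ranks, k = 100) {
  if (k < 1) stop("k must be >= 1")
  ids <- names(mean_ranks)
  num <- suppressWarnings(as.numeric(ids))
  tie_key <- if (anyNA(num)) rank(ids) else num
  ord <- order(mean_ranks, tie_key)
  ids[utils::head(ord, min(k, length(ids)))]
}
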