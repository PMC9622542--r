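# The alternatives table is the package's central tabular container: one row
# per candidate patch with the seven criteria measures, attributes and a
# semicolon-joined adjacency column.

alt_columns <- c("id", "TN_kg_yr", "TP_kg_yr", "AG_pct", "EHA_pct", "FP",
                 "WS_pct", "CF_pct", "low_elev", "region", "adjacency")

empty_alternatives <- function() {
  data.frame(id = integer(0), TN_kg_yr = numeric(0), TP_kg_yr = numeric(0),
             AG_pct = numeric(0), EHA_pct = numeric(0), FP = integer(0),
             WS_pct = numeric(0), CF_pct = numeric(0), low_elev = integer(0),
             region = character(0), adjacency = character(0),
             stringsAsFactors = FALSE)
}

#' Map criterion names to alternatives-table columns
#'
#' The seven criteria are referred to by their short names TN, TP, AG, EHA,
#' FP, WS, CF; this maps them onto the table's measure columns.
#'
#' @return Named character vector, criterion name -> column name.
#' @export
criterion_columns <- function() {
  c(TN = "TN_kg_yr", TP = "TP_kg_yr", AG = "AG_pct", EHA = "EHA_pct",
    FP = "FP", WS = "WS_pct", CF = "CF_pct")
}

#' Extract the criteria measure matrix from an alternatives table
#'
#' @param table An alternatives data.frame.
#' @param criteria Criterion names to extract (default all seven).
#' @return Numeric matrix, rows named by alternative id, columns by
#'   criterion.
#' @export
criteria_matrix <- function(table, criteria = names(criterion_columns())) {
  cols <- criterion_columns()[criteria]
  if (anyNA(cols)) stop("unknown criterion name")
  m <- as.matrix(table[, cols, drop = FALSE])
  dimnames(m) <- list(as.character(table$id), criteria)
  m
}

#' Adjacency list from an alternatives table
#'
#' Expands the semicolon-joined `adjacency` column into a named list of
#' integer neighbor-id vectors.
#'
#' @param table An alternatives data.frame.
#' @return Named list (names = ids) of integer vectors.
#' @export
adjacency_list <- function(table) {
  out <- lapply(table$adjacency, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  names(out) <- as.character(table$id)
  out
}

#' Read and write alternatives tables as CSV
#'
#' @param table An alternatives data.frame.
#' @param path File path.
#' @return `read_alternatives` returns the data.frame;
#'   `write_alternatives` returns `path` invisibly.
#' @export
write_alternatives <- function(table, path) {
  stopifnot(all(alt_columns %in% names(table)))
  utils::write.csv(table[, alt_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_alternatives
#' @export
read_alternatives <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(region = "character",
                                        adjacency = "character"))
  missing <- setdiff(alt_columns, names(tab))
  if (length(missing))
    stop("alternatives CSV lacks columns: ", paste(missing, collapse = ", "))
  tab[tab$region == "", "region"] <- NA_character_
  tab
}
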