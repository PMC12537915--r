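#' Construct a decision matrix
#'
#' A decision matrix holds the raw evaluations `x[i, j]` of `m` alternatives
#' (rows) on `n` criteria (columns), together with the orientation of each
#' criterion: a *benefit* criterion is one where larger raw values are better
#' (e.g. seatbelt-wearing rate), a *cost* criterion one where smaller values
#' are better (e.g. fatality rate). Orientation is consumed by
#' [normalize()]; every downstream stage works on the normalized matrix, in
#' which "larger is better" holds uniformly.
#'
#' @param values numeric matrix (m x n) with unique, non-empty row names
#'   (alternative ids) and column names (criterion ids). All entries must be
#'   finite; missing data are rejected, not imputed.
#' @param directions character vector, one of `"benefit"` or `"cost"` per
#'   criterion. Either unnamed in column order or named by criterion id.
#'   Defaults to all-benefit.
#' @param labels optional named character vector of free-text criterion
#'   labels.
#' @return an object of class `decision_matrix`: a list with elements
#'   `values`, `directions`, `labels`.
#' @examples
#' X <- decision_matrix(matrix(1:6, 3, 2,
#'                             dimnames = list(c("a", "b", "c"), c("c1", "c2"))),
#'                      directions = c(c1 = "benefit", c2 = "cost"))
#' X
#' @export
decision_matrix <- function(values, directions = NULL, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_validation("`values` must be a numeric matrix",
                     "mcdm_nonnumeric_error")
  }
  m <- nrow(values); n <- ncol(values)
  if (m < 2L) abort_validation("a decision matrix needs at least 2 alternatives")
  if (n < 1L) abort_validation("a decision matrix needs at least 1 criterion")
  if (anyNA(values) || !all(is.finite(values))) {
    abort_validation("decision matrix entries must all be finite (no NA/NaN/Inf)",
                     "mcdm_nonfinite_error")
  }
  alts <- rownames(values); crits <- colnames(values)
  check_ids(alts, m, "alternative")
  check_ids(crits, n, "criterion")

  directions <- resolve_directions(directions, crits)
  if (!is.null(labels)) {
    labels <- labels[crits]
    names(labels) <- crits
  }
  structure(list(values = values, directions = directions, labels = labels),
            class = "decision_matrix")
}

check_ids <- function(ids, len, what) {
  if (is.null(ids) || any(!nzchar(ids))) {
    abort_validation(sprintf("%s ids must be present and non-empty", what),
                     "mcdm_missing_id_error")
  }
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate %s id: %s", what,
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                     "mcdm_duplicate_id_error")
  }
  invisible(ids)
}

resolve_directions <- function(directions, crits) {
  n <- length(crits)
  if (is.null(directions)) {
    directions <- rep("benefit", n)
    names(directions) <- crits
    return(directions)
  }
  if (!is.null(names(directions))) {
    missing <- setdiff(crits, names(directions))
    if (length(missing)) {
      abort_validation(paste0("direction missing for criterion: ",
                              paste(missing, collapse = ", ")),
                       "mcdm_missing_direction_error")
    }
    directions <- directions[crits]
  } else {
    if (length(directions) != n) {
      abort_validation("unnamed `directions` must have one entry per criterion",
                       "mcdm_missing_direction_error")
    }
    names(directions) <- crits
  }
  bad <- !(directions %in% c("benefit", "cost"))
  if (any(bad)) {
    abort_validation(paste0("directions must be 'benefit' or 'cost', got: ",
                            paste(unique(directions[bad]), collapse = ", ")),
                     "mcdm_direction_value_error")
  }
  directions
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("<decision_matrix> %d alternatives x %d criteria\n",
              nrow(x$values), ncol(x$values)))
  cat("directions:", paste(substr(x$directions, 1, 1), collapse = ""), "\n")
  print(utils::head(x$values, 5))
  if (nrow(x$values) > 5) cat("...\n")
  invisible(x)
}

#' @export
dim.decision_matrix <- function(x) dim(x$values)

# -- normalized matrix ------------------------------------------------------

new_normalized_matrix <- function(X, values, method) {
  structure(list(values = values, directions = X$directions,
                 labels = X$labels, method = method),
            class = c("normalized_matrix", "decision_matrix"))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix method=%s> %d x %d\n",
              x$method, nrow(x$values), ncol(x$values)))
  print(utils::head(x$values, 5))
  invisible(x)
}

#' Read a decision matrix from CSV
#'
#' The CSV must have a header row of criterion ids and a first column of
#' alternative ids. Directions come from a sidecar CSV with columns
#' `criterion_id,direction`, or from a named character vector.
#'
#' @param path path to the decision-matrix CSV.
#' @param directions path to the directions sidecar CSV, or a named character
#'   vector (`"benefit"`/`"cost"` per criterion id), or `NULL` for
#'   all-benefit.
#' @return a [decision_matrix()].
#' @export
read_decision_matrix <- function(path, directions = NULL) {
  if (!file.exists(path)) {
    abort_io(paste0("file not found: ", path), "mcdm_missing_file_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        comment.char = "#")
  if (ncol(df) < 2L) abort_validation("decision-matrix CSV needs an id column and at least one criterion")
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals),
                                     dimnames = list(NULL, names(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(vals) && length(bad)) {
    abort_validation(sprintf("non-numeric cell at row '%s', column '%s'",
                             ids[bad[1, 1]], colnames(num)[bad[1, 2]]),
                     "mcdm_nonnumeric_error")
  }
  rownames(num) <- ids
  if (is.character(directions) && length(directions) == 1L &&
      is.null(names(directions)) && file.exists(directions)) {
    directions <- read_directions(directions)
  }
  decision_matrix(num, directions = directions)
}

read_directions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("criterion_id", "direction") %in% names(df))) {
    abort_validation("directions sidecar needs columns criterion_id,direction")
  }
  stats::setNames(df$direction, df$criterion_id)
}

#' Write a decision matrix to CSV
#'
#' Values are written with full double precision so that
#' `read_decision_matrix(write_decision_matrix(X))` round-trips exactly.
#'
#' @param X a [decision_matrix()].
#' @param path output CSV path.
#' @param directions_path optional path for the directions sidecar.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(X, path, directions_path = NULL) {
  df <- data.frame(alternative = rownames(X$values),
                   format_full(X$values), check.names = FALSE)
  write_csv_checked(df, path)
  if (!is.null(directions_path)) {
    write_csv_checked(data.frame(criterion_id = names(X$directions),
                                 direction = unname(X$directions)),
                      directions_path)
  }
  invisible(path)
}

format_full <- function(x) {
  # 17 significant digits: lossless for doubles
  out <- apply(x, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x))
  colnames(out) <- colnames(x)
  as.data.frame(out, check.names = FALSE)
}

write_csv_checked <- function(df, path, header_lines = character()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_io(paste0("directory does not exist: ", dir), "mcdm_unwritable_error")
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    abort_io(paste0("cannot write: ", path), "mcdm_unwritable_error")
  }
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- rank vectors -----------------------------------------------------------

new_rank_vector <- function(ranks, ids, source = "unknown") {
  ranks <- as.integer(ranks)
  names(ranks) <- ids
  structure(ranks, source = source, class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat(sprintf("<rank_vector source=%s>\n", attr(x, "source")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# -- packaged fixtures ------------------------------------------------------

#' Load a packaged published-table fixture
#'
#' The package ships transcriptions of the published score, rank and group
#' tables of a 35-country road-safety benchmarking case study (two study
#' years, 2010 and 2020):
#'
#' * `table1_scores`: composite safety score and rank per country and year.
#' * `table2_groups`: the published 6-group cluster labels per country/year.
#' * `table3_norm_ranks`: ranks under the fuzzy-quantization, decimal-scaling
#'   and vector normalizations.
#' * `table4_weight_ranks`: ranks under DCRITIC, entropy and MEREC weighting.
#' * `table5_agg_ranks`: ranks under WASPAS, TOPSIS and VIKOR aggregation.
#'
#' Note: in the published source, the 2010 decimal-scaling rank column of
#' `table3_norm_ranks` contains rank 23 twice and no 24; the transcription
#' reproduces the source as printed.
#'
#' @param name fixture name (see above).
#' @return a `data.frame` with a `country` column (35 rows).
#' @examples
#' t1 <- load_fixture("table1_scores")
#' t1[t1$country == "US", ]
#' @export
load_fixture <- function(name) {
  known <- c("table1_scores", "table2_groups", "table3_norm_ranks",
             "table4_weight_ranks", "table5_agg_ranks")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    abort_validation(paste0("unknown fixture name: ", paste(name, collapse = ", "),
                            "; known: ", paste(known, collapse = ", ")),
                     "mcdm_unknown_fixture_error")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "graphMCDM",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Published scores as a one-criterion decision matrix
#'
#' Convenience accessor: the composite scores of one study year as a 35 x 1
#' [decision_matrix()] (criterion `"score"`, benefit orientation), the form
#' consumed by the clustering stage.
#'
#' @param year 2010 or 2020.
#' @return a [decision_matrix()].
#' @export
fixture_score_matrix <- function(year = c(2010, 2020)) {
  year <- match.arg(as.character(year[1L]), c("2010", "2020"))
  t1 <- load_fixture("table1_scores")
  v <- matrix(t1[[paste0("score_", year)]], ncol = 1,
              dimnames = list(t1$country, "score"))
  decision_matrix(v)
}

# -- score tables -----------------------------------------------------------

new_score_table <- function(ids, WS, WP, WQ, rank, lambda) {
  structure(data.frame(alternative = ids, WS = WS, WP = WP, WQ = WQ,
                       rank = as.integer(rank), row.names = NULL),
            lambda = lambda, class = c("score_table", "data.frame"))
}

#' Write analysis objects to CSV
#'
#' A generic lossless CSV writer for the package's result objects
#' ([waspas_score()] tables, [cluster_graph_kmeans()] groupings,
#' [robustness_matrix()] comparison reports). Real values are written with
#' full double precision; provenance (e.g. lambda, sigma, the resolved
#' configuration) is embedded as leading `#` comment lines, which the
#' matching readers skip.
#'
#' @param x object to write.
#' @param path output CSV path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.score_table <- function(x, path, ...) {
  df <- data.frame(alternative = x$alternative,
                   WS = sprintf("%.17g", x$WS),
                   WP = sprintf("%.17g", x$WP),
                   WQ = sprintf("%.17g", x$WQ),
                   rank = x$rank)
  write_csv_checked(df, path,
                    header_lines = sprintf("lambda=%.17g", attr(x, "lambda")))
  invisible(path)
}

#' Read back a score table written by [write_report()]
#' @param path CSV path.
#' @return a `score_table`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path),
                                   "mcdm_missing_file_error")
  hdr <- readLines(path, n = 1L)
  lambda <- if (startsWith(hdr, "# lambda=")) {
    as.numeric(sub("^# lambda=", "", hdr))
  } else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  new_score_table(df$alternative, df$WS, df$WP, df$WQ, df$rank, lambda)
}

#' @export
write_report.grouping_result <- function(x, path, ids = NULL, ...) {
  if (is.null(ids)) ids <- names(x$labels)
  if (is.null(ids)) ids <- seq_along(x$labels)
  hdr <- c(sprintf("k=%d", nrow(x$centers)),
           sprintf("iterations=%d", x$iterations),
           sprintf("inertia=%.17g", x$inertia),
           sprintf("converged=%s", x$converged))
  write_csv_checked(data.frame(alternative = ids, label = x$labels),
                    path, header_lines = hdr)
  invisible(path)
}

#' @export
write_report.comparison_report <- function(x, path, ...) {
  stem <- sub("\\.csv$", "", path)
  mats <- list(spearman = x$spearman, vmeasure = x$vmeasure)
  for (nm in names(mats)) {
    M <- mats[[nm]]
    if (is.null(M)) next
    df <- data.frame(variant = rownames(M),
                     apply(M, 2, function(col) sprintf("%.17g", col)),
                     check.names = FALSE)
    write_csv_checked(df, paste0(stem, "_", nm, ".csv"),
                      header_lines = paste0("varied=", x$varied))
  }
  invisible(path)
}
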