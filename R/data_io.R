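#' Construct an occurrence matrix
#'
#' Canonical storage orientation is sampling units as rows and species as
#' columns; cells are 0/1 incidence. Species never observed in the matrix are
#' dropped (their pairs are undefined for co-occurrence) and, optionally,
#' reported with a warning.
#'
#' @param incidence numeric/integer matrix of 0/1 cells with unit ids as row
#'   names and species ids as column names.
#' @param scale_label one of `"europe"`, `"region"`, `"local"`.
#' @param name free-text matrix identifier (e.g. region or locality id).
#' @param warn warn when zero-occurrence species are dropped (default `TRUE`).
#' @return An object of class `occurrence_matrix`.
#' @export
occurrence_matrix <- function(incidence, scale_label = c("europe", "region", "local"),
                              name = "", warn = TRUE) {
  scale_label <- match.arg(scale_label)
  if (!is.matrix(incidence)) abort_validation("incidence must be a matrix")
  if (is.null(rownames(incidence)) || is.null(colnames(incidence))) {
    abort_validation("incidence needs unit row names and species column names")
  }
  if (anyDuplicated(rownames(incidence))) {
    abort_validation("duplicate sampling-unit ids")
  }
  if (anyDuplicated(colnames(incidence))) {
    abort_validation("duplicate species ids")
  }
  bad <- which(!(incidence %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(incidence))
    abort_format(sprintf(
      "non-binary cell '%s' at unit '%s', species '%s'",
      as.character(incidence[bad[1]]),
      rownames(incidence)[rc[1]], colnames(incidence)[rc[2]]))
  }
  storage.mode(incidence) <- "integer"
  empty <- colSums(incidence) == 0
  if (any(empty)) {
    if (warn) {
      warning(sprintf("dropping %d species with zero occurrences in '%s': %s",
                      sum(empty), name,
                      paste(colnames(incidence)[empty], collapse = ", ")),
              call. = FALSE)
    }
    tc_log("dropped zero-occurrence species: ",
           paste(colnames(incidence)[empty], collapse = ", "))
    incidence <- incidence[, !empty, drop = FALSE]
  }
  structure(list(incidence = incidence, scale_label = scale_label, name = name),
            class = "occurrence_matrix")
}

#' Read a presence-absence matrix from CSV/TSV
#'
#' The file must have a header row of species ids and a first column of
#' sampling-unit ids (sites at continental/regional scale, baits at local
#' scale). The delimiter is sniffed from the extension (`.csv` comma, `.tsv`
#' tab) unless `sep` is given. Files stored species-as-rows are transposed
#' on read with `species_as_rows = TRUE`; internally, units are always rows.
#'
#' @param path CSV/TSV file path.
#' @inheritParams occurrence_matrix
#' @param species_as_rows set `TRUE` when the file has species as rows and
#'   units as columns.
#' @param sep field delimiter override.
#' @return An [occurrence_matrix()].
#' @export
read_occurrence <- function(path, scale_label = c("europe", "region", "local"),
                            name = basename(path), species_as_rows = FALSE,
                            sep = NULL) {
  scale_label <- match.arg(scale_label)
  df <- read_delim_sniffed(path, sep)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_format(sprintf("non-numeric cells in '%s'", path))
  rownames(m) <- ids
  if (species_as_rows) m <- t(m)
  occurrence_matrix(m, scale_label = scale_label, name = name)
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("Occurrence matrix '%s' (%s scale): %d units x %d species, fill %.3f\n",
              x$name, x$scale_label, nrow(x$incidence), ncol(x$incidence),
              mean(x$incidence)))
  invisible(x)
}

#' Construct and validate a species trait table
#'
#' Checks the table against a [trait_schema()]: all schema columns present
#' (fuzzy traits as one column per component), no missing values (species
#' with missing traits must be removed upstream, not imputed), fuzzy
#' component rows non-negative and summing to 1, quantitative columns
#' numeric. Log transforms declared in the schema are applied here, so
#' stored values are always on the analysis scale.
#'
#' @param df data frame with a `species` column plus one column per schema
#'   column (see [ant_trait_schema()]).
#' @param schema a [trait_schema()].
#' @param transform apply the schema's declared transforms (default `TRUE`;
#'   set `FALSE` when values are already transformed).
#' @return An object of class `trait_table` (a validated data frame carrying
#'   the schema as an attribute).
#' @export
trait_table <- function(df, schema, transform = TRUE) {
  if (!"species" %in% names(df)) abort_validation("trait table needs a 'species' column")
  if (anyDuplicated(df$species)) abort_validation("duplicate species in trait table")
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort_validation(sprintf("trait table missing columns: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  df <- df[, c("species", cols), drop = FALSE]
  df$species <- as.character(df$species)
  na_cells <- which(is.na(df[cols]), arr.ind = TRUE)
  if (nrow(na_cells)) {
    abort_validation(sprintf(
      "missing trait values (species '%s', column '%s'%s)",
      df$species[na_cells[1, 1]], cols[na_cells[1, 2]],
      if (nrow(na_cells) > 1) sprintf(" and %d more", nrow(na_cells) - 1) else ""))
  }
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    if (schema$kind[i] == "quantitative") {
      if (!is.numeric(df[[tr]])) {
        abort_validation(sprintf("quantitative trait '%s' is not numeric", tr))
      }
      if (transform && schema$transform[i] == "log") {
        if (any(df[[tr]] <= 0)) {
          abort_validation(sprintf("trait '%s' must be positive for log transform", tr))
        }
        df[[tr]] <- log(df[[tr]])
      }
    } else if (schema$kind[i] == "fuzzy") {
      cc <- fuzzy_columns(schema, tr)
      mat <- as.matrix(df[cc])
      if (!is.numeric(mat) || any(mat < 0)) {
        abort_validation(sprintf("fuzzy trait '%s' has negative or non-numeric components", tr))
      }
      sums <- rowSums(mat)
      off <- which(abs(sums - 1) > 1e-9)
      if (length(off)) {
        abort_validation(sprintf(
          "fuzzy trait '%s' components do not sum to 1 for species: %s",
          tr, paste(df$species[off], collapse = ", ")))
      }
    } else {
      df[[tr]] <- as.character(df[[tr]])
    }
  }
  attr(df, "schema") <- schema
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a species trait table from CSV/TSV
#'
#' @param path CSV/TSV file with a `species` column and one column per schema
#'   column; fuzzy components are separate columns named
#'   `<trait>_<component>`.
#' @inheritParams trait_table
#' @inheritParams read_occurrence
#' @return A [trait_table()] with schema transforms applied.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(
#'   species = c("sp1", "sp2"), n_queens = c("monogynous", "both"),
#'   colony_size = c(1000, 250), brood_cycle = c("seasonal", "year_round"),
#'   diet_seed = c(0.2, 0), diet_insect = c(0.3, 0.6), diet_liquid = c(0.5, 0.4),
#'   diurnality = c("diurnal", "non_diurnal"), worker_size = c(4.2, 6.8)
#' ), tf, row.names = FALSE)
#' read_traits(tf, ant_trait_schema())
read_traits <- function(path, schema, sep = NULL) {
  df <- read_delim_sniffed(path, sep, first_col_name = "species")
  trait_table(df, schema, transform = TRUE)
}

#' @export
print.trait_table <- function(x, ...) {
  schema <- attr(x, "schema")
  cat(sprintf("Trait table: %d species x %d traits\n", nrow(x), nrow(schema)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more species\n", nrow(x) - 6))
  invisible(x)
}

results_columns <- c("scale_label", "matrix_name", "trait_set", "analysis_type",
                     "estimate", "std_error", "statistic", "p_value",
                     "n_obs", "n_zero", "eligible", "converged", "reason",
                     "mechanism")

#' Write model results to CSV
#'
#' Emits one row per fitted (or withheld) model with the full record: scale,
#' matrix, trait set, analysis type, slope estimate, standard error, test
#' statistic (Wald z for the binary analysis, t for the strength analysis),
#' p-value, sample sizes, eligibility/convergence flags and the mechanism
#' call.
#'
#' @param results a results data frame from [run_plan()] (or built from
#'   individual fits).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_results()] for the lossless inverse.
#' @export
write_results <- function(results, path) {
  if (!NROW(results)) abort_validation("no results to write")
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols)) {
    abort_validation(sprintf("results missing columns: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("output directory does not exist: %s", dir))
  utils::write.csv(as.data.frame(results)[results_columns], path,
                   row.names = FALSE, na = "")
  tc_log("wrote ", NROW(results), " result rows to ", path)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return A results data frame.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(results_columns, names(df))
  if (length(missing_cols)) {
    abort_format(sprintf("not a results file; missing columns: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df$eligible <- as.logical(df$eligible)
  df$converged <- as.logical(df$converged)
  df$reason <- ifelse(is.na(df$reason), "", df$reason)
  df
}

# Delimiter sniffing: .csv -> comma, .tsv/.txt -> tab; explicit sep wins.
read_delim_sniffed <- function(path, sep = NULL, first_col_name = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    sep <- switch(tolower(tools::file_ext(path)),
                  csv = ",", tsv = "\t", txt = "\t", ",")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) {
    abort_format(sprintf("'%s' parsed to <2 columns; wrong delimiter?", path))
  }
  if (!is.null(first_col_name) && names(df)[1] != first_col_name) {
    names(df)[1] <- first_col_name
  }
  df
}
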