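#' Construct a trait schema
#'
#' A trait schema declares, for each functional trait, its data kind
#' (`quantitative`, `categorical` or `fuzzy`), the ecological group it belongs
#' to (`tolerance` = traits mediating the response to the environment;
#' `niche` = traits mediating resource exploitation), an optional transform
#' applied on read (`none` or `log`, the latter allowed for quantitative
#' traits only), and, for fuzzy-coded traits, the names of the component
#' proportions (stored as columns `<trait>_<component>` in the trait table).
#'
#' @param trait character vector of trait names.
#' @param kind character vector, one of `"quantitative"`, `"categorical"`,
#'   `"fuzzy"` per trait.
#' @param group character vector, `"tolerance"` or `"niche"` per trait.
#' @param transform character vector, `"none"` or `"log"` per trait
#'   (default `"none"`).
#' @param components list of character vectors, one per trait; non-empty
#'   (length >= 2) only for fuzzy traits.
#'
#' @return An object of class `trait_schema`: a data frame with one row per
#'   trait and a `components` list-column.
#' @seealso [ant_trait_schema()] for the default six-trait ant schema,
#'   [read_trait_schema()] to load one from YAML/JSON.
#' @export
#' @examples
#' trait_schema(
#'   trait = c("body_mass", "habit"),
#'   kind = c("quantitative", "categorical"),
#'   group = c("tolerance", "niche"),
#'   transform = c("log", "none")
#' )
trait_schema <- function(trait, kind, group,
                         transform = rep("none", length(trait)),
                         components = vector("list", length(trait))) {
  n <- length(trait)
  if (length(kind) != n || length(group) != n || length(transform) != n ||
      length(components) != n) {
    abort_validation("schema fields must all have one entry per trait")
  }
  if (anyDuplicated(trait)) {
    abort_validation("duplicate trait names in schema")
  }
  kind <- match.arg(kind, c("quantitative", "categorical", "fuzzy"),
                    several.ok = TRUE)
  group <- match.arg(group, c("tolerance", "niche"), several.ok = TRUE)
  transform <- match.arg(transform, c("none", "log"), several.ok = TRUE)
  bad_log <- transform == "log" & kind != "quantitative"
  if (any(bad_log)) {
    abort_validation(sprintf(
      "transform 'log' is only valid for quantitative traits (offending: %s)",
      paste(trait[bad_log], collapse = ", ")))
  }
  n_comp <- lengths(components)
  if (any(kind == "fuzzy" & n_comp < 2)) {
    abort_validation("fuzzy traits need at least 2 components")
  }
  if (any(kind != "fuzzy" & n_comp > 0)) {
    abort_validation("components are only allowed for fuzzy traits")
  }
  out <- data.frame(trait = trait, kind = kind, group = group,
                    transform = transform, stringsAsFactors = FALSE)
  out$components <- components
  class(out) <- c("trait_schema", "data.frame")
  out
}

#' The default six-trait ant schema
#'
#' Three ecological tolerance traits (number of queens, colony size
#' log-transformed, brood cycle) and three ecological niche traits
#' (fuzzy-coded diet with seed/insect/liquid components, diurnality, worker
#' size in mm), the trait taxonomy commonly used for European ant faunas.
#'
#' @return A [trait_schema()] with six rows.
#' @export
#' @examples
#' ant_trait_schema()
ant_trait_schema <- function() {
  trait_schema(
    trait = c("n_queens", "colony_size", "brood_cycle",
              "diet", "diurnality", "worker_size"),
    kind = c("categorical", "quantitative", "categorical",
             "fuzzy", "categorical", "quantitative"),
    group = c("tolerance", "tolerance", "tolerance",
              "niche", "niche", "niche"),
    transform = c("none", "log", "none", "none", "none", "none"),
    components = list(NULL, NULL, NULL,
                      c("seed", "insect", "liquid"), NULL, NULL)
  )
}

#' Read a trait schema from YAML or JSON
#'
#' The file holds a list of trait entries, each with fields `trait`, `kind`,
#' `group` and optionally `transform` and `components`. The format is sniffed
#' from the extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path path to a YAML or JSON schema file.
#' @return A [trait_schema()].
#' @export
read_trait_schema <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("schema file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    abort_format(sprintf("unrecognised schema extension '.%s' (use .yaml or .json)", ext))
  )
  if (!length(raw)) abort_format("schema file contains no trait entries")
  get_field <- function(entry, field, default = NULL) {
    val <- entry[[field]] %||% default
    if (is.null(val)) {
      abort_format(sprintf("schema entry missing required field '%s'", field))
    }
    val
  }
  trait_schema(
    trait = vapply(raw, get_field, "", field = "trait"),
    kind = vapply(raw, get_field, "", field = "kind"),
    group = vapply(raw, get_field, "", field = "group"),
    transform = vapply(raw, get_field, "", field = "transform", default = "none"),
    components = lapply(raw, function(e) {
      if (is.null(e$components)) NULL else unlist(e$components)
    })
  )
}

#' @export
print.trait_schema <- function(x, ...) {
  cat(sprintf("Trait schema: %d traits (%d tolerance, %d niche)\n",
              nrow(x), sum(x$group == "tolerance"), sum(x$group == "niche")))
  for (i in seq_len(nrow(x))) {
    comp <- if (length(x$components[[i]])) {
      paste0(" [", paste(x$components[[i]], collapse = ", "), "]")
    } else ""
    tr <- if (x$transform[i] != "none") paste0(", ", x$transform[i]) else ""
    cat(sprintf("  %-12s %s/%s%s%s\n", x$trait[i], x$kind[i], x$group[i], tr, comp))
  }
  invisible(x)
}

# Column names a trait table must carry for this schema: fuzzy traits expand
# to one column per component.
schema_columns <- function(schema) {
  unlist(lapply(seq_len(nrow(schema)), function(i) {
    if (schema$kind[i] == "fuzzy") {
      paste(schema$trait[i], schema$components[[i]], sep = "_")
    } else {
      schema$trait[i]
    }
  }))
}

fuzzy_columns <- function(schema, trait) {
  i <- match(trait, schema$trait)
  paste(schema$trait[i], schema$components[[i]], sep = "_")
}
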