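#' Column schema for reading drug tables
#'
#' Maps the column names and label vocabularies of a delimited file onto
#' the internal drug-table model. The default schema expects the
#' canonical column names and literal `"positive"` / `"negative"`
#' labels, which is exactly what [write_drug_table()] emits, so the
#' default round-trips.
#'
#' @param sources Either a character vector of source names whose file
#'   columns share the same name and use the default vocabulary, or a
#'   named list where each element is a list with entries `column`
#'   (file column name, default: the source name), `positive` and
#'   `negative` (character vectors of file values mapped to each label).
#'   Any other value, including the empty string and `NA`, reads as
#'   absent — this is how "Ambiguous" style categories are excluded.
#' @param columns Named list overriding the file column used for
#'   `drug_id` and the property fields. Set an entry to `NULL` to
#'   declare that the file has no such column (it is filled with `NA`).
#' @param percent_fractions If `TRUE`, `metabolism_fraction` and
#'   `urinary_unchanged_fraction` are given as percentages in the file
#'   and are divided by 100 on read.
#' @return A `drug_schema` object.
#' @examples
#' # A DILIrank-style file with verbose concern categories:
#' drug_schema(sources = list(
#'   chen = list(
#'     column = "DILI_concern",
#'     positive = "Most-DILI-concern",
#'     negative = "No-DILI-concern"
#'   )
#' ))
#' @export
drug_schema <- function(sources = character(), columns = list(),
                        percent_fractions = FALSE) {
  if (is.character(sources)) {
    sources <- rlang::set_names(
      lapply(sources, function(s) list()),
      sources
    )
  }
  if (length(sources) && is.null(names(sources))) {
    abort_dili("`sources` must be named.", "dili_schema_error")
  }
  sources <- lapply(rlang::set_names(names(sources)), function(nm) {
    s <- sources[[nm]]
    list(
      column = s$column %||% nm,
      positive = as.character(s$positive %||% "positive"),
      negative = as.character(s$negative %||% "negative")
    )
  })
  cols <- rlang::set_names(
    as.list(c("drug_id", PROPERTY_FIELDS)),
    c("drug_id", PROPERTY_FIELDS)
  )
  for (nm in names(columns)) {
    if (!nm %in% names(cols)) {
      abort_dili(sprintf("Unknown schema column '%s'.", nm), "dili_schema_error")
    }
    cols[nm] <- list(columns[[nm]]) # keeps NULL entries
  }
  structure(
    list(
      columns = cols,
      sources = sources,
      percent_fractions = isTRUE(percent_fractions)
    ),
    class = "drug_schema"
  )
}

#' Read a drug-table schema from a YAML file
#'
#' The YAML mirrors the arguments of [drug_schema()]: top-level keys
#' `sources`, `columns` and `percent_fractions`.
#'
#' @param path Path to a YAML file.
#' @return A `drug_schema`.
#' @export
read_drug_schema <- function(path) {
  y <- yaml::read_yaml(path)
  drug_schema(
    sources = y$sources %||% character(),
    columns = y$columns %||% list(),
    percent_fractions = y$percent_fractions %||% FALSE
  )
}

#' Read a drug table from a CSV file
#'
#' Reads a comma-separated UTF-8 file with a header row, applies the
#' schema's column mapping and label vocabularies, and validates the
#' result. Rows that fail validation are reported with their row
#' numbers.
#'
#' @param path Path to the CSV file.
#' @param schema A [drug_schema()] describing the file's columns.
#' @return A [drug_table()].
#' @export
read_drug_table <- function(path, schema = drug_schema()) {
  if (!inherits(schema, "drug_schema")) {
    abort_dili("`schema` must be a drug_schema object.", "dili_schema_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE
  )
  mapped <- unlist(schema$columns)
  need <- c(mapped, vapply(schema$sources, `[[`, "", "column"))
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols)) {
    abort_dili(
      sprintf(
        "Input file lacks mandatory column(s): %s.",
        paste(missing_cols, collapse = ", ")
      ),
      "dili_schema_error"
    )
  }

  out <- tibble::tibble(drug_id = trimws(raw[[schema$columns$drug_id]]))
  for (f in PROPERTY_FIELDS) {
    col <- schema$columns[[f]]
    out[[f]] <- if (is.null(col)) NA_real_ else parse_numeric(raw[[col]], f)
  }
  if (schema$percent_fractions) {
    out$metabolism_fraction <- out$metabolism_fraction / 100
    out$urinary_unchanged_fraction <- out$urinary_unchanged_fraction / 100
  }
  for (nm in names(schema$sources)) {
    s <- schema$sources[[nm]]
    v <- trimws(raw[[s$column]])
    out[[nm]] <- dplyr::case_when(
      v %in% s$positive ~ "positive",
      v %in% s$negative ~ "negative",
      .default = "absent"
    )
  }
  drug_table(out, sources = names(schema$sources))
}

parse_numeric <- function(x, field) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(val))
  if (length(bad)) {
    abort_dili(
      sprintf(
        "Column '%s': non-numeric value in row %s.",
        field, paste(bad, collapse = ", ")
      ),
      "dili_validation_error"
    )
  }
  val
}

#' Write a drug table to a CSV file
#'
#' Emits the canonical column layout: `drug_id`, the four property
#' columns, then one column per source. Missing numeric values and
#' absent labels are written as empty cells, so
#' `read_drug_table(write_drug_table(t, path))` with the default schema
#' reproduces `t` field for field.
#'
#' @param table A [drug_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  for (s in dili_sources(table)) {
    out[[s]] <- ifelse(out[[s]] == "absent", NA_character_, out[[s]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
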