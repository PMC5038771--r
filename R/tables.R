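#' Attribute specification
#'
#' Declares one column of an information table: its name, whether values are
#' numeric or nominal, its role in a decision table, and free-text units.
#'
#' @param name Attribute name (unique within a schema).
#' @param kind `"numeric"` or `"nominal"`.
#' @param role `"identifier"`, `"condition"` or `"decision"`.
#' @param units Free-text units (e.g. `"ms"`, `"deg"`, `"score points"`).
#' @return A one-row data frame usable as a schema row.
#' @export
attribute_spec <- function(name, kind = c("numeric", "nominal"),
                           role = c("condition", "identifier", "decision"),
                           units = "") {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, kind = kind, role = role, units = units,
             stringsAsFactors = FALSE)
}

#' Assemble a schema from attribute specifications
#'
#' @param ... One-row data frames from [attribute_spec()] (or complete schema
#'   data frames to be concatenated).
#' @return A schema data frame with columns `name`, `kind`, `role`, `units`.
#' @export
schema <- function(...) {
  sch <- do.call(rbind, list(...))
  validate_schema(sch)
  sch
}

validate_schema <- function(sch) {
  stopifnot(is.data.frame(sch),
            all(c("name", "kind", "role", "units") %in% names(sch)))
  if (anyDuplicated(sch$name))
    stop("duplicate attribute names in schema: ",
         paste(unique(sch$name[duplicated(sch$name)]), collapse = ", "))
  if (!all(sch$kind %in% c("numeric", "nominal")))
    stop("schema kind must be 'numeric' or 'nominal'")
  if (!all(sch$role %in% c("identifier", "condition", "decision")))
    stop("schema role must be 'identifier', 'condition' or 'decision'")
  invisible(sch)
}

#' Construct an information table
#'
#' An information table is a finite universe of objects (rows) described by a
#' typed attribute schema. Numeric slots hold finite reals or `NA` (the
#' MISSING marker); nominal slots hold character values or `NA`.
#'
#' @param data A data frame whose column names match `schema$name`.
#' @param schema A schema data frame (see [attribute_spec()]).
#' @param ids Optional stable object ids (default `seq_len(nrow(data))`).
#' @return An object of class `infotable` with fields `data`, `schema`, `ids`.
#' @export
information_table <- function(data, schema, ids = NULL) {
  validate_schema(schema)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols))
    stop("data lacks schema column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), schema$name)
  if (length(extra))
    stop("unknown column(s) not in schema: ", paste(extra, collapse = ", "))
  data <- data[, schema$name, drop = FALSE]
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] == "numeric") {
      v <- data[[nm]]
      if (!is.numeric(v)) stop("column '", nm, "' must be numeric")
      if (any(is.infinite(v))) stop("non-finite value in numeric column '", nm, "'")
      data[[nm]] <- as.numeric(v)
    } else {
      data[[nm]] <- as.character(data[[nm]])
    }
  }
  if (is.null(ids)) ids <- seq_len(nrow(data))
  stopifnot(length(ids) == nrow(data), !anyDuplicated(ids))
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, ids = as.integer(ids)),
            class = "infotable")
}

#' @export
print.infotable <- function(x, ...) {
  cat(sprintf("<%s> %d objects x %d attributes\n",
              class(x)[1], nrow(x$data), nrow(x$schema)))
  if (!is.null(x$decision)) cat("decision:", x$decision, "\n")
  print(utils::head(x$data, 8L))
  invisible(x)
}

#' Number of objects in a table
#' @param x An `infotable`.
#' @export
n_objects <- function(x) nrow(x$data)

#' Attribute names by role
#' @param x An `infotable` or decision table.
#' @export
condition_attrs <- function(x) x$schema$name[x$schema$role == "condition"]

#' Value set of an attribute
#'
#' The finite set of distinct observed values (MISSING excluded).
#' @param x An `infotable`.
#' @param attr Attribute name.
#' @export
value_set <- function(x, attr) {
  v <- x$data[[attr]]
  if (is.null(v)) stop("unknown attribute: ", attr)
  sort(unique(v[!is.na(v)]))
}

MISSING_TOKEN <- "MISSING"

#' Load an information table from CSV
#'
#' Reads an RFC-4180 CSV with a header row whose names must match the schema.
#' The token `"MISSING"` (case-insensitive) and empty cells map to the MISSING
#' marker (`NA`). Non-numeric text in a numeric column raises a parse error
#' naming the offending row and column.
#'
#' @param path CSV file path.
#' @param schema Schema data frame.
#' @return An `infotable`.
#' @export
load_table <- function(path, schema) {
  validate_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  missing_cols <- setdiff(schema$name, names(raw))
  if (length(missing_cols))
    stop("CSV lacks schema column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), schema$name)
  if (length(extra))
    stop("CSV has column(s) unknown to the schema: ",
         paste(extra, collapse = ", "))
  raw <- raw[, schema$name, drop = FALSE]
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- raw[[nm]]
    v[toupper(v) == MISSING_TOKEN | v == ""] <- NA_character_
    if (schema$kind[i] == "numeric") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop(sprintf("cannot parse '%s' as numeric at row %d, column '%s'",
                     v[bad[1]], bad[1], nm))
      raw[[nm]] <- num
    } else {
      raw[[nm]] <- v
    }
  }
  information_table(raw, schema)
}

#' Write an information table to CSV
#'
#' Inverse of [load_table()]: MISSING markers are written as the token
#' `"MISSING"`; a load/write/load round trip reproduces values bit-exactly.
#'
#' @param x An `infotable`.
#' @param path Output CSV path.
#' @export
write_table <- function(x, path) {
  out <- x$data
  for (nm in names(out)) {
    v <- out[[nm]]
    v <- as.character(v)
    v[is.na(v)] <- MISSING_TOKEN
    out[[nm]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a schema from a YAML or JSON file
#'
#' The file holds a list of records with fields `name`, `kind`, `role` and
#' optionally `units`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @export
read_schema <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  do.call(schema, lapply(recs, function(r)
    attribute_spec(r$name, r$kind, r$role %||% "condition", r$units %||% "")))
}

#' Restrict a table to named attributes
#'
#' Object ids are preserved. Projection is idempotent and commutes with row
#' filtering.
#'
#' @param x An `infotable`.
#' @param names Attribute names to keep (subset of the schema).
#' @export
project <- function(x, names) {
  unknown <- setdiff(names, x$schema$name)
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
  sch <- x$schema[match(names, x$schema$name), , drop = FALSE]
  rownames(sch) <- NULL
  information_table(x$data[, names, drop = FALSE], sch, ids = x$ids)
}

#' Keep a subset of objects by id
#'
#' @param x An `infotable` or decision table.
#' @param ids Object ids to keep (order preserved as given).
#' @export
filter_objects <- function(x, ids) {
  pos <- match(ids, x$ids)
  if (anyNA(pos)) stop("unknown object id(s): ",
                       paste(ids[is.na(pos)], collapse = ", "))
  out <- x
  out$data <- x$data[pos, , drop = FALSE]
  rownames(out$data) <- NULL
  out$ids <- x$ids[pos]
  out
}

#' Declare a decision attribute, forming a decision table
#'
#' All non-identifier attributes other than the decision become conditions
#' unless an explicit `conditions` vector is given (which may promote an
#' identifier, e.g. the patient number, to a condition attribute).
#'
#' @param x An `infotable`.
#' @param decision Name of the decision attribute (must have no MISSING
#'   values).
#' @param conditions Optional explicit condition attribute names.
#' @return An object of class `c("decisiontable", "infotable")`.
#' @export
as_decision_table <- function(x, decision, conditions = NULL) {
  if (!decision %in% x$schema$name)
    stop("decision attribute '", decision, "' not in schema")
  miss <- is.na(x$data[[decision]])
  if (any(miss))
    stop("MISSING values in decision column '", decision, "' for object id(s): ",
         paste(x$ids[miss], collapse = ", "))
  sch <- x$schema
  if (is.null(conditions)) {
    conditions <- sch$name[sch$role != "identifier" & sch$name != decision]
  } else {
    unknown <- setdiff(conditions, sch$name)
    if (length(unknown))
      stop("unknown condition attribute(s): ", paste(unknown, collapse = ", "))
    if (decision %in% conditions)
      stop("decision attribute cannot also be a condition")
  }
  sch$role <- ifelse(sch$name == decision, "decision",
                     ifelse(sch$name %in% conditions, "condition", "identifier"))
  out <- information_table(x$data, sch, ids = x$ids)
  out$decision <- decision
  class(out) <- c("decisiontable", "infotable")
  out
}

#' Decision labels of a decision table
#' @param x A `decisiontable` (or discretized table).
#' @export
decision_values <- function(x) {
  if (is.null(x$decision)) stop("not a decision table")
  x$data[[x$decision]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
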