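# JSON round-trip serialization for result reports. Every report is a list
# of atomic fields (plus optional matrices); files carry an explicit schema
# version and the report's class so read_report_json() can restore it.

REPORT_SCHEMA_VERSION <- 1L

# Matrices cannot round-trip through JSON arrays without losing dimnames,
# so they are boxed explicitly.
encode_report_field <- function(x) {
  if (is.matrix(x)) {
    list(
      `.matrix` = TRUE, nrow = nrow(x), ncol = ncol(x),
      rownames = rownames(x), colnames = colnames(x),
      data = as.vector(x)
    )
  } else if (is.data.frame(x)) {
    c(list(`.data_frame` = TRUE), as.list(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # JSON object, so names survive the round trip
  } else {
    x
  }
}

decode_report_field <- function(x) {
  if (is.null(x)) return(NaN)  # a null scalar field was a NaN score
  if (is.list(x) && isTRUE(x$`.matrix`)) {
    m <- matrix(restore_nan(x$data), nrow = x$nrow, ncol = x$ncol)
    rownames(m) <- x$rownames
    colnames(m) <- x$colnames
    m
  } else if (is.list(x) && isTRUE(x$`.data_frame`)) {
    x$`.data_frame` <- NULL
    as.data.frame(lapply(x, restore_nan), stringsAsFactors = FALSE)
  } else {
    restore_nan(x)
  }
}

# JSON has no NaN; nulls in numeric fields are restored as NaN by
# convention. jsonlite reads JSON objects as named lists, so all-scalar
# lists collapse back into the named vectors they came from.
restore_nan <- function(x) {
  if (is.list(x) && length(x) && all(vapply(x, function(e) {
    is.null(e) || (is.atomic(e) && length(e) == 1L)
  }, logical(1L)))) {
    types <- unique(unlist(lapply(x, class)))
    if (all(types %in% c("numeric", "integer", "NULL"))) {
      x <- vapply(x, function(e) if (is.null(e)) NaN else as.numeric(e),
                  numeric(1L))
    } else if (all(types == "character")) {
      x <- vapply(x, identity, character(1L))
    } else if (all(types == "logical")) {
      x <- vapply(x, identity, logical(1L))
    }
  }
  if (is.numeric(x)) x[is.na(x)] <- NaN
  x
}

#' Write a result report to JSON
#'
#' Reports (stability, rank stability, performance, signature, permutation
#' test, hit ratio, ...) round-trip: `read_report_json(write_report_json(x))`
#' reproduces `x`. `NaN` scores are serialized as `null` and restored as
#' `NaN`.
#'
#' @param report A classed report object (a named list of fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (is.null(attr(report, "class"))) stop("report must be a classed object")
  fields <- lapply(unclass(report), encode_report_field)
  ok <- vapply(fields, function(f) {
    is.atomic(f) || is.list(f) || is.null(f)
  }, logical(1L))
  if (!all(ok)) {
    stop("unserializable field(s): ", paste(names(fields)[!ok], collapse = ", "))
  }
  obj <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    report_type = class(report)[1L],
    payload = fields
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(obj$report_type)) stop("not a report file: ", path)
  payload <- lapply(obj$payload, decode_report_field)
  structure(payload, class = obj$report_type)
}
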