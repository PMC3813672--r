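# Writers/readers for result objects (round-trip stable).

#' Write an analysis result to disk
#'
#' JSON serialization is lossless for all result classes
#' (`correlation_result`, `path_result`, `equilibrium_result`):
#' `read_results(write_results(x))` reconstructs the object field for field.
#' CSV writes a flat tabular report (full numeric precision; matrices for
#' correlation results, one row per sample for equilibrium results, one row
#' per predictor for path results).
#'
#' @param obj a result object produced by [pearson_matrix()],
#'   [decompose_effects()] or [run_equilibrium_analysis()].
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(obj, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- .serialize_result(obj)
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
      TRUE
    }, error = function(e) stop("I/O error writing ", path, ": ",
                                conditionMessage(e), call. = FALSE))
  } else {
    df <- as.data.frame(obj)
    tryCatch(write.csv(df, path, row.names = inherits(obj, "correlation_result")),
             error = function(e) stop("I/O error writing ", path, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  invisible(path)
}

.serialize_result <- function(obj) {
  type <- intersect(class(obj),
                    c("correlation_result", "path_result", "equilibrium_result"))
  if (length(type) == 0) stop("unsupported result class: ",
                              paste(class(obj), collapse = "/"), call. = FALSE)
  payload <- if (type == "equilibrium_result")
    list(table = as.data.frame(obj), tolerance = attr(obj, "tolerance"))
  else unclass(obj)  # matrices serialize as nested arrays; dimnames restored on read
  c(list(type = type), payload)
}

#' Read back a result written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @param format `"json"` (full fidelity, any result class) or `"csv"`
#'   (correlation matrices and equilibrium tables).
#' @return the reconstructed result object.
#' @export
read_results <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if ("v_wsk_nek" %in% names(df)) return(.as_equilibrium_result(df, NA_real_))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    return(m)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  type <- x$type
  x$type <- NULL
  if (type == "correlation_result") {
    vars <- x$variables
    for (f in c("r", "pvalues", "n_pairs", "flags")) {
      m <- as.matrix(x[[f]])
      dimnames(m) <- list(vars, vars)
      x[[f]] <- m
    }
    return(structure(x, class = "correlation_result"))
  }
  if (type == "path_result") {
    for (f in c("direct", "indirect_total", "total", "r_xy"))
      x[[f]] <- setNames(as.numeric(x[[f]]), x$predictors)
    x$indirect <- {
      m <- as.matrix(x$indirect)
      dimnames(m) <- list(x$predictors, x$predictors)
      m
    }
    x$r_xx <- {
      m <- as.matrix(x$r_xx)
      dimnames(m) <- list(x$predictors, x$predictors)
      m
    }
    if (!is.null(x$eliminated) && length(x$eliminated))
      x$eliminated <- as.data.frame(x$eliminated)
    return(structure(x, class = "path_result"))
  }
  if (type == "equilibrium_result")
    return(.as_equilibrium_result(as.data.frame(x$table), x$tolerance))
  stop("unknown result type: ", type, call. = FALSE)
}
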