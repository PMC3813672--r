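# Domain types and tabular I/O for soil survey tables.

# canonical column vocabulary; values are printed units
.sk_schema <- c(
  group = "label", rhizosphere = "logical", genotype = "label", treatment = "label",
  na = "%", mg_a = "%", al = "%", si = "%", fe = "%", mg_b = "%", ca = "%",
  p = "ppm", co3 = "%", s = "ppm", cl = "ppm",
  k = "g/kg", wsk = "ug/g", nek = "ug/g", ek = "ug/g",
  wsk_w = "ug/g", nek_w = "ug/g", ek_w = "ug/g",
  bact_seedling = "1e4 CFU/g", bact_budding = "1e4 CFU/g", bact_wadding = "1e4 CFU/g",
  bacteria = "1e4 CFU/g",
  tc = "%", tn = "%", som = "%", pha = "%", nha = "%", hmi = "%", hmc = "%",
  orp = "eV", ph = "", ba = "", na_k = "", ica = "", saf = "", cia = "")

# header aliases beyond mechanical lower/underscore normalization
.sk_aliases <- c(
  "nak" = "na_k", "na_k_ratio" = "na_k", "co_3" = "co3", "k_g_kg" = "k",
  "sample" = "group", "group_id" = "group", "mg" = "mg_a",
  "wsk_ug_g" = "wsk", "nek_ug_g" = "nek", "ek_ug_g" = "ek",
  "hmi_" = "hmi", "hmc_" = "hmc", "nha_" = "nha", "pha_" = "pha",
  "som_" = "som", "orp_ev" = "orp")

.canonical_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  ifelse(x %in% names(.sk_aliases), unname(.sk_aliases[x]), x)
}

#' Construct a validated sample table
#'
#' A `sample_table` is a data frame of per-group soil measurements with a
#' mandatory unique `group` column. Values are stored in the units in which
#' they are reported (mass fractions in %, P/S/Cl in ppm, total K in g/kg,
#' K forms in ug/g); no unit conversion happens at I/O time.
#'
#' @param x data frame with a `group` column; headers are normalized to the
#'   canonical vocabulary (case-insensitive, punctuation-tolerant, e.g.
#'   `"Na/K"` and `"Na_K"` both map to `na_k`).
#' @param validate check value invariants (non-negative mass fractions,
#'   0 < pH < 14). Synthetic Gaussian tables may legitimately stray outside
#'   physical ranges and can skip this.
#' @param schema_version label stored on the object.
#' @return a data frame of class `sample_table`.
#' @export
sample_table <- function(x, validate = TRUE, schema_version = "1") {
  x <- as.data.frame(x)
  names(x) <- .canonical_name(names(x))
  if (!"group" %in% names(x))
    stop("schema error: mandatory column missing: group", call. = FALSE)
  x$group <- as.character(x$group)
  if (anyDuplicated(x$group))
    stop("validation error: duplicate group_id: ",
         paste(unique(x$group[duplicated(x$group)]), collapse = ", "), call. = FALSE)
  if (!"rhizosphere" %in% names(x))
    x$rhizosphere <- !grepl("^N", x$group)  # R* = rhizosphere, N*/NR* = bulk soil
  num_cols <- setdiff(intersect(names(x), names(.sk_schema)),
                      c("group", "rhizosphere", "genotype", "treatment"))
  n_bad <- 0L
  for (cl in num_cols) {
    if (!is.numeric(x[[cl]])) {
      v <- suppressWarnings(as.numeric(as.character(x[[cl]])))
      n_bad <- n_bad + sum(is.na(v) & !is.na(x[[cl]]) & x[[cl]] != "")
      x[[cl]] <- v
    }
  }
  if (n_bad > 0)
    warning(sprintf("%d unparseable cell(s) set to NA", n_bad), call. = FALSE)
  if (validate) .check_invariants(x)
  structure(x, class = c("sample_table", "data.frame"),
            schema_version = schema_version, n_unparseable = n_bad)
}

.check_invariants <- function(x) {
  nonneg <- intersect(names(x), c("na", "mg_a", "al", "si", "fe", "mg_b", "ca", "p",
                                  "co3", "s", "cl", "k", "wsk", "nek", "ek",
                                  "wsk_w", "nek_w", "ek_w", "bact_seedling",
                                  "bact_budding", "bact_wadding", "bacteria",
                                  "tc", "tn", "som", "pha", "nha", "hmi", "hmc"))
  for (cl in nonneg)
    if (any(x[[cl]] < 0, na.rm = TRUE))
      stop("validation error: negative values in column ", cl, call. = FALSE)
  if ("ph" %in% names(x) && any(x$ph <= 0 | x$ph >= 14, na.rm = TRUE))
    stop("validation error: pH outside (0, 14)", call. = FALSE)
  invisible(x)
}

#' Read a soil survey table from CSV or JSON
#'
#' @param path file path.
#' @param format `"csv"` (one row per sample group, mandatory header) or
#'   `"json"` (flat list of record objects).
#' @param validate passed to [sample_table()].
#' @return a [sample_table()].
#' @examples
#' tab <- read_sample_table(system.file("extdata", "table2_6.csv",
#'                                      package = "soilKpath"))
#' nrow(tab)  # 16 sample groups
#' @export
read_sample_table <- function(path, format = c("csv", "json"), validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (format == "csv") {
    if (file.size(path) == 0) stop("schema error: empty file", call. = FALSE)
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
  if (nrow(raw) == 0 || ncol(raw) == 0)
    stop("schema error: no records in ", path, call. = FALSE)
  sample_table(raw, validate = validate)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d group(s), %d column(s) [schema v%s]\n",
              nrow(x), ncol(x), attr(x, "schema_version")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

.fixture_files <- c(
  elements = "table_elements.csv", k_forms = "table_k_forms.csv",
  bacteria = "table_bacteria.csv", organics = "table_organics.csv",
  indices = "table_indices.csv", survey = "table2_6.csv",
  correlations = "table_correlations.csv",
  path_wsK = "table_path_wsK.csv", path_neK = "table_path_neK.csv",
  path_eK = "table_path_eK.csv", equilibrium = "table_equilibrium.csv",
  direction_rule = "direction_rule.csv", fertilization = "table_fertilization.csv")

#' Load a packaged reference table
#'
#' Verbatim transcriptions of the published survey of 16 cotton
#' rhizosphere/non-rhizosphere sample groups: measured inputs (`elements`,
#' `k_forms`, `bacteria`, `organics`, `indices`, or the merged `survey`) and
#' reference outputs (`correlations` with significance letters, the three
#' `path_*` coefficient tables, the `equilibrium` table with two-symbol
#' direction labels, and the calibrated `direction_rule` exemplars).
#'
#' Blank cells of the published correlation surface (values below the |r| =
#' 0.5 display threshold) are absent rows of the long-format `correlations`
#' table, never zeros.
#'
#' @param name fixture name, one of
#'   `r paste0('\x60', names(.fixture_files), '\x60', collapse = ", ")`.
#' @return a [sample_table()] for measured-input fixtures, otherwise a plain
#'   data frame.
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_files))
    stop("unknown fixture: ", name, "; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", .fixture_files[[name]], package = "soilKpath",
                      mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (name %in% c("elements", "k_forms", "bacteria", "organics", "indices", "survey"))
    sample_table(df) else df
}
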