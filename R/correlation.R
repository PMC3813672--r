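# Z-score normalization and the significance-flagged Pearson surface.

#' Column-standardize a survey table
#'
#' Centers and scales each selected column to mean 0 and sample standard
#' deviation 1 (n-1 denominator), keeping the original means and sds for
#' back-transformation. Variable labels follow the Z() notation of the
#' field, e.g. `Z(wsK)` for standardized water-soluble K.
#'
#' @param x a [sample_table()] or data frame.
#' @param variables columns to standardize; default: all numeric columns.
#' @param na_action `"fail"` (default) or `"drop"` rows with missing values.
#' @return a `zmatrix`: list with `values` (n x p matrix), `columns`,
#'   `n`, `means`, `sds`.
#' @examples
#' z <- zscore_matrix(data.frame(x = c(1, 2, 3)))
#' z$values[, "x"]  # -1, 0, 1
#' @export
zscore_matrix <- function(x, variables = NULL, na_action = c("fail", "drop")) {
  na_action <- match.arg(na_action)
  df <- as.data.frame(x)
  if (is.null(variables))
    variables <- names(df)[vapply(df, is.numeric, TRUE)]
  miss <- setdiff(variables, names(df))
  if (length(miss)) stop("schema error: missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, variables, drop = FALSE])
  if (anyNA(m)) {
    if (na_action == "fail")
      stop("missing values present; use na_action = \"drop\"", call. = FALSE)
    m <- m[complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 3) stop("domain error: need n >= 3 rows, got ", nrow(m),
                        call. = FALSE)
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  if (any(sdev == 0))
    stop("domain error: zero-variance column(s): ",
         paste(variables[sdev == 0], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  rownames(z) <- if ("group" %in% names(df) && nrow(df) == nrow(z))
    as.character(df$group) else NULL
  structure(list(values = z, columns = variables, n = nrow(z),
                 means = mu, sds = sdev),
            class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(sprintf("zmatrix: %d sample(s) x %d standardized variable(s)\n", x$n,
              length(x$columns)))
  cat("  ", paste0("Z(", x$columns, ")", collapse = " "), "\n")
  invisible(x)
}

.as_values <- function(x) {
  if (inherits(x, "zmatrix")) return(x$values)
  df <- as.data.frame(x)
  as.matrix(df[, vapply(df, is.numeric, TRUE), drop = FALSE])
}

#' Pairwise Pearson correlation surface with significance flags
#'
#' Computes the p x p Pearson matrix (pairwise-complete observations),
#' two-tailed p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom, and per-cell significance letters. The letter map
#' follows the published caption literally (`a`: p < 0.01, `b`: p < 0.05)
#' and is configurable. Cells with |r| below `display_threshold` are masked
#' in printed reports but retained in the full matrix.
#'
#' @param x a `zmatrix`, [sample_table()] or data frame (Pearson r is
#'   invariant under standardization, so raw and z-scored input agree).
#' @param display_threshold |r| cutoff used when formatting reports.
#' @param alpha_map named numeric vector mapping letters to alpha levels,
#'   tried in order.
#' @return a `correlation_result`: list with `variables`, `r`, `pvalues`,
#'   `n_pairs`, `flags`, `display_threshold`.
#' @examples
#' kf <- load_fixture("k_forms")
#' cr <- pearson_matrix(kf[, c("wsk", "nek", "ek")])
#' round(cr$r["wsk", "nek"], 2)  # 0.77
#' @export
pearson_matrix <- function(x, display_threshold = 0.5,
                           alpha_map = c(a = 0.01, b = 0.05)) {
  m <- .as_values(x)
  if (nrow(m) < 3) stop("domain error: need n >= 3 rows", call. = FALSE)
  r <- cor(m, use = "pairwise.complete.obs")
  obs <- !is.na(m)
  npair <- crossprod(obs)
  tt <- r * sqrt(pmax(npair - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = pmax(npair - 2, 1))
  diag(p) <- 0
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  for (letter in names(alpha_map)) {
    hit <- flags == "" & p < alpha_map[[letter]]
    flags[hit] <- letter
  }
  diag(flags) <- ""
  structure(list(variables = colnames(m), r = r, pvalues = p,
                 n_pairs = npair, flags = flags,
                 display_threshold = display_threshold,
                 alpha_map = as.list(alpha_map)),
            class = "correlation_result")
}

#' @export
as.data.frame.correlation_result <- function(x, ...) {
  disp <- ifelse(abs(x$r) >= x$display_threshold & row(x$r) != col(x$r),
                 paste0(format(round(x$r, 2), trim = TRUE), x$flags), "")
  diag(disp) <- "1"
  as.data.frame(matrix(disp, nrow(x$r), dimnames = dimnames(x$r)),
                stringsAsFactors = FALSE)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation surface: %d variables (display |r| >= %.2f; ",
              length(x$variables), x$display_threshold))
  cat(paste(names(x$alpha_map), "p <", unlist(x$alpha_map), collapse = "; "), ")\n")
  print(as.data.frame(x), right = TRUE)
  invisible(x)
}

#' Select the strongest significant correlates of a response
#'
#' Ranks variables by |r| against `response` among those carrying a
#' significance flag and returns the top `k`; ties broken by variable label
#' so that selection is deterministic.
#'
#' @param corr a `correlation_result`.
#' @param response variable label.
#' @param k number of parameters to keep (the published screen keeps 8 of
#'   16).
#' @return character vector of up to `k` labels; warns when fewer than `k`
#'   significant partners exist.
#' @export
select_parameters <- function(corr, response, k = 8) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!response %in% corr$variables)
    stop("unknown response: ", response, call. = FALSE)
  if (k == 0) return(character(0))
  cand <- setdiff(corr$variables, response)
  sig <- cand[corr$flags[cand, response] != ""]
  if (length(sig) < k)
    warning(sprintf("only %d significant partner(s) for %s (requested %d)",
                    length(sig), response, k), call. = FALSE)
  ord <- order(-abs(corr$r[sig, response]), sig)
  utils::head(sig[ord], k)
}

#' Compare a computed correlation surface with a reference table
#'
#' @param corr a `correlation_result`.
#' @param reference long-format data frame with columns `var1`, `var2`, `r`
#'   (defaults to the packaged published surface).
#' @return the reference table with `computed` and `deviation` columns
#'   (computed r rounded to 2-dp minus reference); pairs absent from `corr`
#'   get `NA`.
#' @export
compare_correlations <- function(corr, reference = load_fixture("correlations")) {
  stopifnot(inherits(corr, "correlation_result"))
  comp <- mapply(function(a, b) {
    if (a %in% corr$variables && b %in% corr$variables)
      round(corr$r[a, b], 2) else NA_real_
  }, reference$var1, reference$var2)
  reference$computed <- as.numeric(comp)
  reference$deviation <- reference$computed - reference$r
  reference
}
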