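# Standardized regression, backward elimination and Wright path
# decomposition of correlations into direct + indirect effects.

.corr_parts <- function(z, response, predictors) {
  stopifnot(inherits(z, "zmatrix"))
  bad <- setdiff(c(response, predictors), z$columns)
  if (length(bad)) stop("schema error: missing column(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (response %in% predictors)
    stop("response must not be among the predictors", call. = FALSE)
  r <- cor(z$values[, c(response, predictors), drop = FALSE])
  list(r_xx = r[predictors, predictors, drop = FALSE],
       r_xy = r[predictors, response])
}

#' Fit a standardized multiple regression via the normal equations
#'
#' Solves `R_xx P = r_xy` on the standardized scale. The solution `P` is the
#' vector of path coefficients (standardized partial regression
#' coefficients): the direct effect of each predictor on the response.
#' `R^2 = r_xy' P`. Coefficient standard errors use
#' `se_j^2 = [R_xx^-1]_jj (1 - R^2) / (n - p - 1)` and two-tailed t tests.
#'
#' @param z a [zscore_matrix()].
#' @param response,predictors column labels.
#' @param cond_bound condition-number bound above which the predictor
#'   correlation matrix is declared collinear (the survey's neK-eK r = 0.98
#'   makes near-singularity a live concern).
#' @return list with `direct` (named coefficients), `r2`, `residue`
#'   (`sqrt(1 - R^2)`), `se`, `tval`, `pval`, `df`, `r_xx`, `r_xy`, `n`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(20)); d$y <- d$x + rnorm(20)
#' f <- fit_standardized(zscore_matrix(d), "y", "x")
#' all.equal(unname(f$direct), cor(d$x, d$y))  # single predictor: P = r
#' @export
fit_standardized <- function(z, response, predictors, cond_bound = 1e8) {
  p <- length(predictors)
  if (z$n <= p + 1)
    stop(sprintf("domain error: n = %d too small for %d predictor(s)", z$n, p),
         call. = FALSE)
  parts <- .corr_parts(z, response, predictors)
  kap <- kappa(parts$r_xx, exact = TRUE)
  if (!is.finite(kap) || kap > cond_bound)
    stop("collinearity error (condition number ", format(kap, digits = 3),
         ") among: ", paste(predictors, collapse = ", "), call. = FALSE)
  direct <- drop(solve(parts$r_xx, parts$r_xy))
  names(direct) <- predictors
  r2 <- sum(direct * parts$r_xy)
  df <- z$n - p - 1
  if (df < 10)
    warning(sprintf("only %d residual degrees of freedom; coefficient tests are fragile", df),
            call. = FALSE)
  cinv <- diag(solve(parts$r_xx))
  se <- sqrt(pmax(cinv * (1 - r2), 0) / df)
  tval <- direct / se
  pval <- 2 * pt(-abs(tval), df)
  list(direct = direct, r2 = r2, residue = sqrt(max(1 - r2, 0)),
       se = se, tval = tval, pval = setNames(pval, predictors),
       df = df, r_xx = parts$r_xx, r_xy = parts$r_xy, n = z$n)
}

#' Backward elimination on the standardized model
#'
#' Starting from the full predictor set, repeatedly refits and removes the
#' predictor with the largest coefficient p-value while that p-value exceeds
#' `alpha_remove`. Ties are broken toward the larger p-value and then by
#' label, so the trace is deterministic.
#'
#' @inheritParams fit_standardized
#' @param alpha_remove removal threshold on the coefficient t-test p-value.
#' @return list with `retained` (labels, original order) and `trace`
#'   (data frame of `variable`, `p_at_removal`, `step`). An empty retained
#'   set (all predictors eliminated) is returned with a warning.
#' @export
backward_eliminate <- function(z, response, predictors, alpha_remove = 0.05,
                               cond_bound = 1e8) {
  current <- predictors
  trace <- data.frame(variable = character(0), p_at_removal = numeric(0),
                      step = integer(0), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 0) {
    fit <- suppressWarnings(
      fit_standardized(z, response, current, cond_bound = cond_bound))
    worst <- order(-fit$pval, current)[1]
    if (fit$pval[worst] <= alpha_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(variable = current[worst],
                                     p_at_removal = unname(fit$pval[worst]),
                                     step = step))
    current <- current[-worst]
  }
  if (length(current) == 0)
    warning("all predictors eliminated; returning empty model (residue = 1)",
            call. = FALSE)
  list(retained = current, trace = trace)
}

#' Decompose correlations into direct and indirect path effects
#'
#' For each retained predictor j, the simple correlation with the response
#' splits into the direct path coefficient `P_j` plus indirect effects
#' transmitted through every other retained predictor k, `r_jk * P_k`. With
#' all predictors retained the reconstruction is exact:
#' `P_j + sum_k r_jk P_k = r_jy`. The uncorrelated residue attached to the
#' response is `e = sqrt(1 - R^2)`.
#'
#' @inheritParams fit_standardized
#' @param retained predictor labels (e.g. from [backward_eliminate()]).
#' @param eliminated optional elimination trace stored on the result.
#' @return a `path_result`: list with `response`, `predictors`, `direct`,
#'   `indirect` (j x k matrix of `r_jk * P_k`, zero diagonal),
#'   `indirect_total`, `total`, `r_xy` (simple correlations), `r2`,
#'   `residue`, `r_xx`, `n`, `eliminated`.
#' @export
decompose_effects <- function(z, response, retained, eliminated = NULL,
                              cond_bound = 1e8) {
  if (length(retained) == 0) {
    return(structure(list(response = response, predictors = character(0),
                          direct = numeric(0), indirect = matrix(0, 0, 0),
                          indirect_total = numeric(0), total = numeric(0),
                          r_xy = numeric(0), r2 = 0, residue = 1,
                          r_xx = matrix(0, 0, 0), n = z$n,
                          eliminated = eliminated),
                     class = "path_result"))
  }
  fit <- fit_standardized(z, response, retained, cond_bound = cond_bound)
  ind <- fit$r_xx * rep(fit$direct, each = length(retained))  # r_jk * P_k
  diag(ind) <- 0
  indirect_total <- rowSums(ind)
  structure(list(response = response, predictors = retained,
                 direct = fit$direct, indirect = ind,
                 indirect_total = indirect_total,
                 total = fit$direct + indirect_total,
                 r_xy = fit$r_xy, r2 = fit$r2, residue = fit$residue,
                 r_xx = fit$r_xx, n = fit$n, eliminated = eliminated),
            class = "path_result")
}

#' @export
print.path_result <- function(x, digits = 3, ...) {
  cat(sprintf("path model for Z(%s): %d predictor(s), R^2 = %.*f, residue e = %.*f\n",
              x$response, length(x$predictors), digits, x$r2, digits, x$residue))
  if (length(x$predictors))
    print(round(data.frame(direct = x$direct, indirect = x$indirect_total,
                           total = x$total, simple_r = x$r_xy,
                           row.names = paste0("Z(", x$predictors, ")")),
                digits))
  if (!is.null(x$eliminated) && nrow(x$eliminated))
    cat("eliminated:", paste(x$eliminated$variable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.path_result <- function(x, ...) {
  data.frame(response = rep(x$response, length(x$predictors)),
             predictor = x$predictors, direct = unname(x$direct),
             indirect_total = unname(x$indirect_total),
             total = unname(x$total), simple_r = unname(x$r_xy),
             r2 = x$r2, residue = x$residue)
}

# predictor sets of the published wsK/neK/eK models (neK's printed set lists
# SOM twice; deduplicated here)
.survey_predictors <- list(
  wsk = c("nek", "pha", "s", "na_k", "cia", "na", "som", "ek"),
  nek = c("wsk", "som", "s", "na_k", "tn", "na", "ek"),
  ek  = c("nek", "som", "na_k", "na", "hmi", "tn", "wsk", "s"))

#' Fit the three survey path models (wsK, neK, eK)
#'
#' Runs the standardized backward-elimination regression and path
#' decomposition for each potassium form against its published predictor
#' set.
#'
#' @param x a [sample_table()], data frame or [zscore_matrix()] containing
#'   all model variables.
#' @param alpha_remove removal threshold; `1` keeps every predictor (the
#'   full-model decomposition, for which total effect = simple correlation
#'   holds exactly).
#' @param eliminate run backward elimination before decomposing.
#' @return named list (`wsk`, `nek`, `ek`) of `path_result` objects.
#' @examples
#' paths <- run_k_path_models(load_fixture("survey"), eliminate = FALSE)
#' paths$wsk$r2
#' @export
run_k_path_models <- function(x, alpha_remove = 0.05, eliminate = TRUE) {
  vars <- unique(c(names(.survey_predictors), unlist(.survey_predictors)))
  z <- if (inherits(x, "zmatrix")) x else zscore_matrix(x, variables = vars)
  out <- lapply(names(.survey_predictors), function(resp) {
    preds <- .survey_predictors[[resp]]
    el <- NULL
    if (eliminate) {
      bk <- backward_eliminate(z, resp, preds, alpha_remove = alpha_remove)
      preds <- bk$retained
      el <- bk$trace
    }
    decompose_effects(z, resp, preds, eliminated = el)
  })
  names(out) <- names(.survey_predictors)
  out
}

#' Compare a fitted path model with a published coefficient table
#'
#' The published three-column tables are internally ambiguous (their
#' "direct correlation coefficients" column demonstrably equals the simple
#' correlations), so all three candidate quantities computed by the model
#' (simple r, indirect total, direct P) are set against each printed column.
#'
#' @param result a `path_result`.
#' @param reference one of the packaged `path_*` fixtures.
#' @return merged data frame with computed columns alongside the printed
#'   ones.
#' @export
compare_path_table <- function(result, reference) {
  comp <- data.frame(variable = result$predictors,
                     simple_r = round(unname(result$r_xy), 2),
                     indirect_total = round(unname(result$indirect_total), 2),
                     direct_P = round(unname(result$direct), 2))
  merge(reference, comp, by = "variable", all.x = TRUE, sort = FALSE)
}

#' Export a path diagram in DOT format
#'
#' Writes a Graphviz digraph: dashed single-headed edges from each retained
#' predictor into the response (weighted by the direct path coefficient),
#' solid double-headed edges between predictors whose pairwise |r| reaches
#' the display threshold, and the uncorrelated-residue node `e` attached to
#' the response.
#'
#' @param result a `path_result`.
#' @param path output file.
#' @param display_threshold |r| cutoff for predictor-predictor edges.
#' @return `path`, invisibly.
#' @export
export_path_diagram <- function(result, path, display_threshold = 0.5) {
  stopifnot(inherits(result, "path_result"))
  q <- function(x) paste0("\"Z(", x, ")\"")
  lines <- c("digraph path_model {", "  rankdir=LR;",
             paste0("  ", q(result$response), " [shape=box];"),
             "  e [shape=plaintext];",
             sprintf("  e -> %s [label=\"%.2f\", style=dotted];",
                     q(result$response), result$residue))
  for (j in result$predictors)
    lines <- c(lines, sprintf("  %s -> %s [label=\"%.2f\", style=dashed];",
                              q(j), q(result$response), result$direct[[j]]))
  pr <- result$predictors
  if (length(pr) > 1) {
    for (a in seq_len(length(pr) - 1)) for (b in seq(a + 1, length(pr))) {
      rab <- result$r_xx[pr[a], pr[b]]
      if (abs(rab) >= display_threshold)
        lines <- c(lines, sprintf("  %s -> %s [label=\"%.2f\", dir=both, style=solid];",
                                  q(pr[a]), q(pr[b]), rab))
    }
  }
  lines <- c(lines, "}")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error writing ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
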