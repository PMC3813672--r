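# Build an n x p data frame whose *sample* correlation matrix equals R
# exactly: whiten standardized Gaussian noise, then color by chol(R).
make_exact_corr_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  X <- scale(matrix(rnorm(n * p), n, p))
  W <- solve(chol(crossprod(X) / (n - 1)))
  out <- (X %*% W) %*% chol(R)
  colnames(out) <- colnames(R)
  as.data.frame(out)
}

named_corr <- function(v, ...) {
  m <- matrix(c(...), length(v), length(v), dimnames = list(v, v))
  m
}

# standardized coefficients from an ordinary least-squares fit on the raw
# scale: the independent oracle for the normal-equations solver
lm_standardized <- function(df, response, predictors) {
  f <- stats::as.formula(paste(response, "~",
                               paste(sprintf("`%s`", predictors), collapse = "+")))
  fit <- stats::lm(f, data = df)
  b <- stats::coef(fit)[-1]
  sds <- vapply(df[predictors], stats::sd, 0)
  stats::setNames(b * sds / stats::sd(df[[response]]), predictors)
}
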