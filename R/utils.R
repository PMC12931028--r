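# Internal numerical helpers shared across the likelihood, posterior and
# standardization code.

.mlsurvstd_env <- new.env(parent = emptyenv())

# Gauss-Hermite rule for weight exp(-x^2); cached by node count.
gh_rule <- function(n) {
  key <- paste0("gh", n)
  rule <- .mlsurvstd_env[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussHermite(n)
    .mlsurvstd_env[[key]] <- rule
  }
  rule
}

# Row-wise log-sum-exp of a matrix.
lse_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Clamp exponent to avoid Inf * 0 artefacts; exp(700) is near .Machine limit.
safe_exp <- function(x) exp(pmin(x, 700))

`%||%` <- rlang::`%||%`
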