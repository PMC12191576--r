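#' @importFrom stats optim integrate rexp rgamma rlnorm rweibull rpois runif
#'   rnorm pnorm pgamma pexp plnorm pweibull dexp dgamma dlnorm dweibull
#'   uniroot lm coef median fft mvfft sd var quantile setNames
#' @importFrom utils head tail modifyList
#' @importFrom rlang .data
NULL

# largest |eigenvalue| of a square matrix
spectral_radius <- function(m) {
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# determinant of a (possibly complex) square matrix; base det() is
# real-only
cdet <- function(m) {
  if (is.complex(m)) {
    if (nrow(m) == 1) return(m[1, 1])
    if (nrow(m) == 2) return(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    prod(eigen(m, only.values = TRUE)$values)
  } else {
    det(m)
  }
}

as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- vapply(x, is.numeric, logical(1))
    nm <- names(x)[keep]
    nm <- setdiff(nm, c("bin", "time"))
    x <- as.matrix(x[nm])
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}
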