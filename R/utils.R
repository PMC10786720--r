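#' @importFrom stats pnorm qnorm pt qbeta pbeta dbeta pchisq qchisq rnorm runif
#'   rbinom rpois rmultinom rbeta cor cor.test lm lm.fit coef quantile median
#'   sd var p.adjust complete.cases kmeans prcomp optim setNames rexp
#'   wilcox.test ks.test shapiro.test predict
#' @importFrom utils head tail
#' @importFrom data.table := .N .SD
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a fixed RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_that <- function(ok, ...) if (!isTRUE(ok)) stop_config(...)

#' Derive a reproducible child seed from a parent seed and a label
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Column-standardize a matrix (mean 0, sd 1), tolerating constant columns
#' @noRd
standardize_cols <- function(x) {
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu, "-")
  s <- sqrt(colSums(x^2) / max(1, nrow(x) - 1))
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
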