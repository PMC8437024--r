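# numerical helpers shared across modules

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Gauss-Legendre nodes/weights on [0, 1], cached per order
.gl_cache <- new.env(parent = emptyenv())
gl_unit <- function(n = 24L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    g <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- g
  }
  .gl_cache[[key]]
}

# integral of f on [a, b] by fixed-order Gauss-Legendre; f must be vectorized
gl_integrate <- function(f, a, b, n = 24L) {
  if (b <= a) return(0)
  g <- gl_unit(n)
  (b - a) * sum(g$w * f(a + (b - a) * g$x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
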