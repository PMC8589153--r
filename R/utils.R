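# Internal helpers shared across modules.

# stop with a classed condition so callers/tests can match on class
stop_rbcmem <- function(msg, class = "rbcmem_error", ...) {
  rlang::abort(msg, class = class, ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_rbcmem(sprintf("`%s` must be a single number.", name),
                class = "rbcmem_invalid_parameter")
  }
  if (finite && !is.finite(x)) {
    stop_rbcmem(sprintf("`%s` must be finite.", name),
                class = "rbcmem_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_rbcmem(sprintf("`%s` must be > 0 (got %g).", name, x),
                class = "rbcmem_invalid_parameter")
  }
  invisible(x)
}

check_ascending <- function(x, name) {
  if (length(x) < 2L || any(diff(x) <= 0)) {
    stop_rbcmem(sprintf("`%s` must be strictly ascending.", name),
                class = "rbcmem_invalid_parameter")
  }
  invisible(x)
}

# trapezoid rule on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Gauss-Legendre nodes/weights on [a, b]; Golub-Welsch via symmetric
# tridiagonal eigenproblem (base R only).
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

# composite Gauss-Legendre over panels defined by `breaks`
gauss_legendre_panels <- function(breaks, n_per_panel) {
  base <- gauss_legendre(n_per_panel)
  nodes <- c()
  weights <- c()
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    nodes <- c(nodes, (b - a) / 2 * base$nodes + (a + b) / 2)
    weights <- c(weights, (b - a) / 2 * base$weights)
  }
  list(nodes = nodes, weights = weights)
}

# deterministic RNG scope: run `expr` under a seed without touching the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# full width at half maximum of a Gaussian with standard deviation sigma
sigma_to_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Bessel J0 valid for any non-negative argument: besselJ loses accuracy and
# warns for very large x; switch to the leading asymptotic there
j0_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 1e5
  if (any(!big)) out[!big] <- besselJ(x[!big], 0)
  if (any(big)) out[big] <- sqrt(2 / (pi * x[big])) * cos(x[big] - pi / 4)
  out
}
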