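# Simultaneous multi-Gaussian + polynomial-background least squares,
# shared by the specular and in-plane peak-fitting front ends.
# Parameterised with log-sigma and log-amplitude so widths/areas stay
# positive; box bounds keep centers inside the data and widths between one
# grid step and a third of the data range.

fit_gaussians <- function(x, y, init_centers, init_sigmas, init_amps,
                          bg_degree = 1, fix_centers = FALSE,
                          center_window = NULL, maxiter = 200) {
  k <- length(init_centers)
  stopifnot(length(init_sigmas) == k, length(init_amps) == k)
  yscale <- max(abs(y), 1e-300)
  init_amps <- pmax(init_amps, 1e-9 * yscale)
  nbg <- bg_degree + 1
  xr <- diff(range(x))
  dq <- min(diff(x))
  sig_lo <- max(dq, 1e-12)
  sig_hi <- xr / 3
  init_sigmas <- pmin(pmax(init_sigmas, sig_lo * 1.01), sig_hi * 0.99)
  par0 <- c(init_centers, log(init_sigmas), log(init_amps), rep(0, nbg))
  cw <- center_window %||% xr
  lower <- c(pmax(init_centers - cw, min(x)), rep(log(sig_lo), k),
             rep(log(1e-12 * yscale), k), rep(-Inf, nbg))
  upper <- c(pmin(init_centers + cw, max(x)), rep(log(sig_hi), k),
             rep(log(10 * yscale * xr), k), rep(Inf, nbg))
  model_fun <- function(par) {
    centers <- if (fix_centers) init_centers else par[seq_len(k)]
    sigmas <- exp(par[k + seq_len(k)])
    amps <- exp(par[2 * k + seq_len(k)])
    bg <- par[3 * k + seq_len(nbg)]
    xc <- (x - mean(x)) / xr
    bgv <- drop(outer(xc, 0:bg_degree, `^`) %*% bg)
    comps <- vapply(seq_len(k), function(i) {
      amps[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
    }, numeric(length(x)))
    rowSums(comps) + bgv
  }
  res <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) model_fun(par) - y,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  if (res$info == 0 || res$info == 9) {
    stop_rbcmem(sprintf("peak fit failed to converge (deviance %.3g).",
                        res$deviance),
                class = "rbcmem_fit_error", deviance = res$deviance)
  }
  par <- res$par
  centers <- if (fix_centers) init_centers else par[seq_len(k)]
  sigmas <- exp(par[k + seq_len(k)])
  amps <- exp(par[2 * k + seq_len(k)])
  se <- tryCatch(sqrt(diag(chol2inv(chol(res$hessian)) *
                             res$deviance / max(1, length(y) - length(par)))),
                 error = function(e) rep(NA_real_, length(par)))
  list(centers = centers, sigmas = sigmas, amps = amps,
       areas = amps * sigmas * sqrt(2 * pi),
       bg = par[3 * k + seq_len(nbg)],
       fitted = model_fun(par), residual = res$deviance,
       se_centers = if (fix_centers) rep(0, k) else se[seq_len(k)],
       converged = TRUE)
}
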