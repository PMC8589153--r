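#' Generate synthetic diffuse-scattering line cuts
#'
#' Forward-models in-plane line cuts through the diffuse scattering of a
#' membrane stack at `q_z = factor * (2 pi / d)` using the analytic
#' [structure_factor()], with multiplicative Gaussian noise. The generating
#' parameters are recorded in the cut metadata.
#'
#' @param stack A [smectic_stack()] or [caille_model()] carrying the ground
#'   truth (`kappa`, `B_mod`, `d`, `n_layers`).
#' @param qz_factors Multipliers on the first-order peak position (defaults
#'   2.0 and 2.5, the canonical two-cut choice).
#' @param qr_grid In-plane wavevector grid, 1/angstrom.
#' @param noise_level Fractional (multiplicative Gaussian) noise.
#' @param seed Integer seed.
#' @param r_domain Lateral envelope scale used when `stack` does not carry
#'   one.
#' @return A list of `diffuse_cut` tibbles (columns `q_r`, `intensity`)
#'   with attributes `q_z`, `q_z_factor` and `ground_truth`.
#' @export
gen_diffuse_cuts <- function(stack, qz_factors = c(2, 2.5),
                             qr_grid = seq(0.002, 0.05, by = 0.001),
                             noise_level = 0.03, seed = 1L,
                             r_domain = 2000) {
  if (length(qz_factors) == 0) {
    stop_rbcmem("`qz_factors` must be non-empty.",
                class = "rbcmem_invalid_parameter")
  }
  if (length(qr_grid) == 0) {
    stop_rbcmem("`qr_grid` must be non-empty.",
                class = "rbcmem_invalid_parameter")
  }
  model <- if (inherits(stack, "caille_model")) {
    stack
  } else {
    caille_model(stack$kappa, stack$B_mod, stack$d,
                 n_layers = max(stack$n_layers, 2L),
                 temperature = stack$temperature, r_domain = r_domain)
  }
  truth <- list(kappa = model$kappa, B_mod = model$B_mod, d = model$d,
                n_layers = model$n_layers, r_domain = model$r_domain,
                eta = model$eta, xi = model$xi)
  cuts <- with_seed(seed, lapply(qz_factors, function(f) {
    qz <- f * 2 * pi / model$d
    S <- structure_factor(model, qz, qr_grid)
    inten <- if (noise_level > 0) {
      S * (1 + rnorm(length(S), sd = noise_level))
    } else {
      S
    }
    cut <- tibble(q_r = qr_grid, intensity = inten)
    class(cut) <- c("diffuse_cut", class(cut))
    attr(cut, "q_z") <- qz
    attr(cut, "q_z_factor") <- f
    attr(cut, "ground_truth") <- truth
    cut
  }))
  cuts
}

#' Fit Caillé theory to two diffuse-scattering line cuts
#'
#' Simultaneous least squares of the analytic [structure_factor()] on the
#' log intensity of (at least) two in-plane cuts taken at distinct `q_z`.
#' Free parameters are `kappa`, `B_mod`, one amplitude per cut (the
#' absolute scale is instrument-dependent) and optionally the lateral
#' envelope scale `r_domain`; `d`, `n_layers` and the temperature are held
#' fixed. Parameters are fitted on log scale (bounded trust-region
#' Levenberg-Marquardt, tolerance 1e-8, max 500 iterations). Reported
#' uncertainties are 95% confidence half-widths (two standard errors).
#'
#' @param cuts List of two or more `diffuse_cut` tibbles (columns `q_r`,
#'   `intensity`, attribute `q_z`).
#' @param init A [caille_model()] with starting values.
#' @param free_r_domain Also fit the lateral envelope scale (within a
#'   factor 4 of the initial value)? Default TRUE.
#' @param n_coarse,n_q_delta Quadrature resolution passed to the
#'   structure-factor engine.
#' @return A `caille_fit` object: list with the fitted [caille_model()],
#'   a `tidy()`-able parameter table, per-cut amplitudes, convergence
#'   diagnostics and the fitted curves.
#' @export
fit_diffuse <- function(cuts, init, free_r_domain = TRUE,
                        n_coarse = 200, n_q_delta = 1500) {
  if (length(cuts) < 2L) {
    stop_rbcmem("at least two line cuts at distinct q_z are required.",
                class = "rbcmem_invalid_parameter")
  }
  stopifnot(inherits(init, "caille_model"))
  qz <- vapply(cuts, function(ct) attr(ct, "q_z"), numeric(1))
  if (anyNA(qz) || length(unique(round(qz, 10))) < length(qz)) {
    stop_rbcmem("cuts must carry distinct `q_z` attributes.",
                class = "rbcmem_invalid_parameter")
  }
  ncut <- length(cuts)
  ydata <- lapply(cuts, function(ct) log(pmax(ct$intensity, 1e-300)))

  # one quadrature cache per distinct q_r grid (usually just one)
  grid_key <- vapply(cuts, function(ct) paste(signif(ct$q_r, 12),
                                              collapse = ","), character(1))
  keys <- unique(grid_key)
  caches <- lapply(keys, function(k) {
    caille_sf_cache(cuts[[match(k, grid_key)]]$q_r,
                    r_max = 48 * init$r_domain,
                    n_coarse = n_coarse, n_q_delta = n_q_delta)
  })
  names(caches) <- keys

  # parameter vector: log kappa, log B, [log r_domain], log amp per cut
  make_model <- function(par) {
    caille_model(exp(par[1]), exp(par[2]), init$d, n_layers = init$n_layers,
                 q1 = init$q1, temperature = init$temperature,
                 r_domain = if (free_r_domain) exp(par[3]) else init$r_domain)
  }
  amp_idx <- (if (free_r_domain) 3 else 2) + seq_len(ncut)
  eval_cuts <- function(model) {
    out <- vector("list", ncut)
    for (k in keys) {
      idx <- which(grid_key == k)
      S <- caille_sf_eval(model, qz[idx], caches[[k]])
      out[idx] <- S
    }
    out
  }
  resid_fun <- function(par) {
    model <- make_model(par)
    S <- eval_cuts(model)
    unlist(lapply(seq_len(ncut), function(i) {
      log(pmax(S[[i]], 1e-300)) + par[amp_idx[i]] - ydata[[i]]
    }))
  }
  # initial amplitudes: median offset between data and model at init
  init_par <- c(log(init$kappa), log(init$B_mod),
                if (free_r_domain) log(init$r_domain))
  S0 <- eval_cuts(init)
  amps0 <- vapply(seq_len(ncut), function(i) {
    median(ydata[[i]] - log(pmax(S0[[i]], 1e-300)))
  }, numeric(1))
  par0 <- c(init_par, amps0)
  lower <- c(log(init$kappa) - log(100), log(init$B_mod) - log(1e4),
             if (free_r_domain) log(init$r_domain / 4),
             amps0 - 20)
  upper <- c(log(init$kappa) + log(100), log(init$B_mod) + log(1e4),
             if (free_r_domain) log(init$r_domain * 4),
             amps0 + 20)
  res <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8,
                                         ptol = 1e-8))
  par <- res$par
  at_bounds <- any(abs(par - lower) < 1e-6) || any(abs(par - upper) < 1e-6)
  dof <- max(1, sum(lengths(ydata)) - length(par))
  cov <- tryCatch(chol2inv(chol(res$hessian)) * res$deviance / dof,
                  error = function(e) {
                    # near-singular Hessian (flat direction): pseudo-inverse
                    s <- svd(res$hessian)
                    pos <- s$d > max(s$d) * 1e-10
                    (s$v[, pos, drop = FALSE] %*%
                       (t(s$u[, pos, drop = FALSE]) / s$d[pos])) *
                      res$deviance / dof
                  })
  se_log <- sqrt(diag(cov))
  model <- make_model(par)
  S_fit <- eval_cuts(model)
  fitted_curves <- lapply(seq_len(ncut), function(i) {
    tibble(q_r = cuts[[i]]$q_r, q_z = qz[i],
           intensity = cuts[[i]]$intensity,
           fitted = exp(log(pmax(S_fit[[i]], 1e-300)) + par[amp_idx[i]]))
  })
  params <- tibble(
    term = c("kappa", "B_mod",
             if (free_r_domain) "r_domain",
             paste0("amplitude_", seq_len(ncut)), "eta", "xi"),
    estimate = c(model$kappa, model$B_mod,
                 if (free_r_domain) model$r_domain,
                 exp(par[amp_idx]), model$eta, model$xi),
    # 95% half-widths (2 sigma), delta-method from the log-scale fit
    conf95 = c(2 * se_log[1] * model$kappa, 2 * se_log[2] * model$B_mod,
               if (free_r_domain) 2 * se_log[3] * model$r_domain,
               2 * se_log[amp_idx] * exp(par[amp_idx]),
               # eta, xi: delta method on log(kappa), log(B)
               model$eta * sqrt(se_log[1]^2 + se_log[2]^2),
               0.5 * model$xi * sqrt(se_log[1]^2 + se_log[2]^2))
  )
  structure(list(model = model, params = params, curves = fitted_curves,
                 deviance = res$deviance, niter = res$niter,
                 info = res$info, at_bounds = at_bounds,
                 converged = res$info %in% 1:4),
            class = "caille_fit")
}

#' @export
print.caille_fit <- function(x, ...) {
  cat(sprintf(
    "<caille_fit> kappa %.3g +/- %.2g kBT | B %.3g kBT/A^4 | eta %.3g | xi %.3g A | %s%s\n",
    x$model$kappa, x$params$conf95[x$params$term == "kappa"],
    x$model$B_mod, x$model$eta, x$model$xi,
    if (x$converged) "converged" else "NOT converged",
    if (x$at_bounds) " (at bounds)" else ""))
  invisible(x)
}

#' @export
tidy.caille_fit <- function(x, ...) {
  x$params
}

#' @export
glance.caille_fit <- function(x, ...) {
  tibble(kappa = x$model$kappa, B_mod = x$model$B_mod, eta = x$model$eta,
         xi = x$model$xi, deviance = x$deviance, niter = x$niter,
         converged = x$converged, at_bounds = x$at_bounds)
}

#' Plot diffuse-scattering cuts and the fitted structure factor
#' @param object A `caille_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.caille_fit <- function(object, ...) {
  df <- dplyr::bind_rows(object$curves)
  df$cut <- sprintf("q_z = %.4f", df$q_z)
  ggplot2::ggplot(df, ggplot2::aes(.data$q_r, .data$intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~cut, scales = "free_y") +
    ggplot2::labs(x = expression(q[r] ~ (ring(A)^-1)), y = "I (a.u.)")
}
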