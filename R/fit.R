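#' Four-parameter logistic response
#'
#' The sigmoid used throughout the package for dose-response data:
#' `response(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill_slope)`.
#' With a positive Hill slope the curve starts at `top` (untreated signal,
#' ~100%) and falls to `bottom` as the inhibitor concentration grows; the
#' IC50 is the concentration at the halfway response.
#'
#' @param conc concentration(s), g/L.
#' @param ic50 half-maximal concentration, g/L.
#' @param hill_slope Hill coefficient (> 0 for the falling-signal convention).
#' @param top,bottom upper and lower asymptotes, percent.
#' @return numeric vector of mean responses.
#' @export
hill_response <- function(conc, ic50, hill_slope, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill_slope)
}

#' Fit a logistic dose-response curve and extract a potency estimate
#'
#' Least-squares fit of the four-parameter logistic ([hill_response()]) to a
#' serial-dilution plate; the `"3PL"` variant pins `bottom = 0` (full
#' inhibition achievable). The fit is run on `log(ic50)` with box constraints
#' (Hill slope in (0.1, 10), top in (50, 120), bottom in (-10, 40)) from a
#' small multi-start grid seeded at the geometric mid-concentration, so it is
#' robust to poor single starts and exact on noiseless data. The IC50
#' standard error comes from the Gauss-Newton covariance at the optimum.
#'
#' If the fitted IC50 lies above the plate's highest tested concentration the
#' potency is right-censored: the data never reached the half-maximal
#' response, so only a bound is known. Non-convergence is reported via
#' `converged = FALSE` plus a warning, never as a silent number.
#'
#' @param plate a [dose_response_plate()] with at least 4 distinct
#'   concentrations.
#' @param model `"4PL"` (default) or `"3PL"`.
#' @return an object of class `dose_response_fit`: `fit` (class `hill_fit`
#'   with `ic50` g/L, `hill_slope`, `top`, `bottom`, `residual_sse`,
#'   `converged`, `model`) and `potency` (a [potency_estimate()] with
#'   `ic50_sd` from the fit standard error and the censoring flag set).
#' @examples
#' pl <- simulate_plate(true_ic50 = 0.01, hill_slope = 1, dilution_start = 1,
#'                      dilution_factor = 3, n_dilutions = 8, noise_sd = 0,
#'                      n_replicates = 1, seed = 1)
#' fit_dose_response(pl)$fit$ic50 # 0.01
#' @export
fit_dose_response <- function(plate, model = c("4PL", "3PL")) {
  model <- match.arg(model)
  if (!inherits(plate, "dose_response_plate")) abort_input("plate must be a dose_response_plate")
  x <- plate$points$concentration
  y <- plate$points$response
  if (length(unique(x)) < 4L) {
    abort_input("at least 4 distinct concentrations are required for fitting")
  }

  fixed_bottom <- model == "3PL"
  npar <- if (fixed_bottom) 3L else 4L
  predict_fun <- function(th) {
    hill_response(x, ic50 = exp(th[1]), hill_slope = th[2], top = th[3],
                  bottom = if (fixed_bottom) 0 else th[4])
  }
  sse <- function(th) sum((y - predict_fun(th))^2)

  lo_c <- min(x); hi_c <- max(x)
  lower <- c(log(lo_c) - log(1e4), 0.1, 50, -10)[seq_len(npar)]
  upper <- c(log(hi_c) + log(1e4), 10, 120, 40)[seq_len(npar)]
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

  top0 <- clamp(max(y), 50, 120)
  bot0 <- clamp(min(y), -10, 40)
  mid <- exp(mean(log(range(x)))) # geometric mid-concentration
  starts <- list()
  for (c0 in unique(c(mid, lo_c, hi_c))) {
    for (h0 in c(0.5, 1, 2)) {
      starts[[length(starts) + 1L]] <- c(log(c0), h0, top0, bot0)[seq_len(npar)]
    }
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 1000)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    warning("dose-response fit failed from every start; returning non-converged fit")
    best <- list(par = starts[[1]], value = sse(starts[[1]]), convergence = 99L)
  } else {
    # one polishing pass from the winner tightens the optimum on clean data;
    # at an exact optimum L-BFGS-B can abort its line search (code 52), so the
    # polish may only improve the parameters, never revoke convergence
    polish <- tryCatch(
      stats::optim(best$par, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1, maxit = 1000)),
      error = function(e) NULL
    )
    if (!is.null(polish) && polish$value <= best$value) {
      best$par <- polish$par
      best$value <- polish$value
      if (polish$convergence == 0L) best$convergence <- 0L
    }
    # Levenberg-Marquardt refinement: quadratic convergence where L-BFGS-B's
    # line search stalls, which is exactly the near-zero-residual regime
    lm <- lm_polish(predict_fun, best$par, y, lower, upper)
    if (lm$value <= best$value) {
      best$par <- lm$par
      best$value <- lm$value
    }
  }

  th <- best$par
  converged <- best$convergence == 0L
  if (!converged) {
    # a near-interpolating fit is converged no matter how optim exited
    converged <- best$value <= 1e-10 * (1 + sum(y^2))
  }
  if (!converged) {
    # L-BFGS-B aborts its line search (code 52) when no step improves an
    # already-optimal point; accept the fit if the gradient has vanished
    g <- vapply(seq_len(npar), function(j) {
      h <- max(1e-7, abs(th[j]) * 1e-7)
      up <- th; up[j] <- min(up[j] + h, upper[j])
      dn <- th; dn[j] <- max(dn[j] - h, lower[j])
      if (up[j] == dn[j]) 0 else (sse(up) - sse(dn)) / (up[j] - dn[j])
    }, 0)
    converged <- max(abs(g)) <= 1e-4 * (1 + best$value)
  }
  if (!converged) {
    warning(sprintf("dose-response fit did not converge (optim code %d); inspect HillFit before use",
                    best$convergence))
  }
  ic50 <- exp(th[1])
  se_ic50 <- fit_standard_error(predict_fun, th, best$value, length(y), npar, ic50)
  censored <- if (ic50 > plate$max_tested_concentration) "right" else "none"

  fit <- structure(
    list(
      ic50 = ic50,
      hill_slope = th[2],
      top = th[3],
      bottom = if (fixed_bottom) 0 else th[4],
      residual_sse = best$value,
      converged = converged,
      model = model,
      n_points = length(y)
    ),
    class = "hill_fit"
  )
  potency <- potency_estimate(
    ic50, "g/L",
    ic50_sd = if (is.na(se_ic50)) NA_real_ else se_ic50,
    censored = censored,
    sd_source = "fit standard error (Gauss-Newton covariance)"
  )
  structure(list(fit = fit, potency = potency), class = "dose_response_fit")
}

numeric_jacobian <- function(predict_fun, th) {
  n <- length(predict_fun(th))
  J <- matrix(0, nrow = n, ncol = length(th))
  for (j in seq_along(th)) {
    h <- max(1e-7, abs(th[j]) * 1e-7)
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    J[, j] <- (predict_fun(up) - predict_fun(dn)) / (2 * h)
  }
  J
}

# Damped Gauss-Newton (Levenberg-Marquardt) steps projected onto the box.
lm_polish <- function(predict_fun, th, y, lower, upper, max_iter = 50L) {
  value <- sum((y - predict_fun(th))^2)
  lambda <- 1e-6
  for (iter in seq_len(max_iter)) {
    r <- y - predict_fun(th)
    J <- numeric_jacobian(predict_fun, th)
    jtj <- crossprod(J)
    step <- tryCatch(
      solve(jtj + lambda * diag(diag(jtj) + 1e-12), crossprod(J, r)),
      error = function(e) NULL
    )
    if (is.null(step)) break
    cand <- pmin(pmax(th + as.numeric(step), lower), upper)
    cand_value <- sum((y - predict_fun(cand))^2)
    if (cand_value < value) {
      improvement <- value - cand_value
      th <- cand
      value <- cand_value
      lambda <- max(lambda / 10, 1e-12)
      if (improvement < 1e-14 * (1 + value)) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }
  list(par = th, value = value)
}

# Gauss-Newton covariance: sigma^2 * (J'J)^-1 with J the numerical Jacobian of
# the mean response w.r.t. the parameters; returns the SE of ic50 via the
# delta method from the log-ic50 parameterization.
fit_standard_error <- function(predict_fun, th, sse_val, n, p, ic50) {
  if (n <= p) return(NA_real_)
  J <- numeric_jacobian(predict_fun, th)
  sigma2 <- sse_val / (n - p)
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov_log) || cov_log[1, 1] < 0) return(NA_real_)
  ic50 * sqrt(cov_log[1, 1])
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit %s> ic50 %.6g g/L, slope %.3g, top %.4g, bottom %.4g, SSE %.4g%s\n",
    x$model, x$ic50, x$hill_slope, x$top, x$bottom, x$residual_sse,
    if (!x$converged) " [NOT CONVERGED]" else ""
  ))
  invisible(x)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  print(x$fit)
  print(x$potency)
  invisible(x)
}
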