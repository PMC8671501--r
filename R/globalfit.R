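## Global (multi-exponential, IRF-convolved) analysis of TA maps and
## mono-exponential population lifetime fits. The global fit is separable
## least squares: nonlinear in the time constants (and optionally t0),
## linear in the decay-associated spectra, solved by variable projection.

#' Exponential decay convolved with a Gaussian IRF
#'
#' \deqn{C(t) = \tfrac12 \exp\!\big(\tfrac{\sigma^2}{2\tau^2} -
#'   \tfrac{t - t_0}{\tau}\big)\,
#'   \mathrm{erfc}\!\big(\tfrac{\sigma}{\sqrt2 \tau} -
#'   \tfrac{t - t_0}{\sqrt2 \sigma}\big)}
#' with \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}; the unconvolved
#' step-exponential for FWHM = 0.
#'
#' @param t_fs times (fs).
#' @param tau_fs decay constant (fs).
#' @param irf_fwhm_fs IRF full width at half maximum (fs).
#' @param t0_fs time zero (fs).
#' @return numeric vector of the same length as `t_fs`.
#' @export
irf_exp <- function(t_fs, tau_fs, irf_fwhm_fs, t0_fs = 0) {
  tt <- t_fs - t0_fs
  if (irf_fwhm_fs <= 0) {
    return(ifelse(tt >= 0, exp(-tt / tau_fs), 0))
  }
  sig <- irf_fwhm_fs / (2 * sqrt(2 * log(2)))
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  arg <- sig / (sqrt(2) * tau_fs) - tt / (sqrt(2) * sig)
  ## log-space product avoids overflow of the exp prefactor for small tau
  pref <- sig^2 / (2 * tau_fs^2) - tt / tau_fs
  0.5 * exp(pref + log(pmax(erfc(arg), 1e-300)))
}

## design matrix of IRF-convolved exponentials
.gf_design <- function(t, taus, fwhm, t0) {
  vapply(taus, function(tau) irf_exp(t, tau, fwhm, t0), numeric(length(t)))
}

#' Global multi-exponential fit of a TA map
#'
#' Fits \eqn{\Delta A(t, E) = \sum_k \mathrm{DAS}_k(E)\, [e^{-t/\tau_k}
#' \circledast \mathrm{IRF}](t)} by separable least squares: for trial time
#' constants the decay-associated spectra (DAS) are obtained by linear least
#' squares across all probe energies simultaneously, and the profiled
#' residual is minimized over \eqn{\log \tau_k} (and optionally \eqn{t_0})
#' with multi-start initial values spread over the decades of the fit
#' window. Deterministic for given starting values.
#'
#' @param map a `ta_map` (or a list with `delays_fs`, `probe_ev`, `delta_a`).
#' @param n_exp number of exponential components (>= 1).
#' @param irf_fwhm_fs IRF FWHM (fs).
#' @param t_fit_window `c(t_min, t_max)` fs; default: the full delay range.
#' @param t0_fs fixed time zero (fs) unless `fit_t0 = TRUE`.
#' @param fit_t0 also optimize t0.
#' @param tau_init optional starting time constants (fs); replaces the
#'   multi-start grid.
#' @param n_starts number of multi-start initializations.
#' @return an object of class `global_fit`: `taus` (fs, ascending),
#'   `tau_se` (Jacobian-based standard errors), `das` (matrix `n_exp` x
#'   `n_E`), `t0_fs`, `irf_fwhm_fs`, `residual_rms`, `convergence`,
#'   `at_bounds` (logical per tau), plus the fitted `reconstruction` and the
#'   grids for reuse.
#' @export
global_fit <- function(map, n_exp, irf_fwhm_fs = 30, t_fit_window = NULL,
                       t0_fs = 0, fit_t0 = FALSE, tau_init = NULL,
                       n_starts = 8) {
  stopifnot(n_exp >= 1)
  t_all <- map$delays_fs
  if (is.null(t_fit_window)) t_fit_window <- range(t_all)
  if (t_fit_window[1] < min(t_all) - 1e-9 || t_fit_window[2] > max(t_all) + 1e-9) {
    stop("t_fit_window outside the delay grid")
  }
  sel <- t_all >= t_fit_window[1] & t_all <= t_fit_window[2]
  t <- t_all[sel]
  A <- map$delta_a[sel, , drop = FALSE]
  span <- diff(range(t))
  lo <- log(max(diff(t)[1] / 4, 1e-3)); hi <- log(span * 20)

  profiled <- function(par) {
    taus <- exp(pmin(pmax(par[seq_len(n_exp)], lo), hi))
    t0 <- if (fit_t0) par[n_exp + 1L] else t0_fs
    C <- .gf_design(t, taus, irf_fwhm_fs, t0)
    qrC <- qr(C)
    if (qrC$rank < n_exp) return(list(rss = Inf))
    das <- qr.coef(qrC, A)
    R <- A - C %*% das
    list(rss = sum(R^2), das = das, taus = taus, t0 = t0, C = C)
  }
  obj <- function(par) profiled(par)$rss

  starts <- list()
  if (!is.null(tau_init)) {
    starts[[1]] <- log(tau_init)
  } else {
    base <- seq(log(max(span / 100, 1)), log(span), length.out = n_exp + 2)[2:(n_exp + 1)]
    starts[[1]] <- base
    ## deterministic quasi-random jitter: the fit must not depend on the
    ## ambient RNG state
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- base + 1.2 * sin(2.399 * s * seq_len(n_exp))
    }
  }
  best <- NULL
  for (s in starts) {
    par0 <- if (fit_t0) c(s, t0_fs) else s
    o <- if (length(par0) == 1L) {
      stats::optim(par0, obj, method = "Brent", lower = lo, upper = hi,
                   control = list(maxit = 2000))
    } else {
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value)) {
    stop("global fit did not converge; last parameters: ",
         paste(signif(exp(best$par[seq_len(n_exp)]), 4), collapse = ", "))
  }
  fin <- profiled(best$par)
  ord <- order(fin$taus)
  taus <- fin$taus[ord]
  das <- t(fin$das)[, ord, drop = FALSE]   # n_E x n_exp -> transpose below
  das <- t(das)                            # n_exp x n_E

  ## Jacobian-based standard errors on the profiled objective
  r <- as.vector(A - fin$C %*% fin$das)
  npar <- n_exp + as.integer(fit_t0)
  Jc <- matrix(0, length(r), npar)
  h <- 1e-5
  for (k in seq_len(npar)) {
    pp <- best$par; pp[k] <- pp[k] + h
    fk <- profiled(pp)
    rk <- as.vector(A - fk$C %*% fk$das)
    Jc[, k] <- (rk - r) / h
  }
  dof <- max(length(r) - npar - n_exp * ncol(A), 1)
  s2 <- sum(r^2) / dof
  cov_log <- tryCatch(s2 * solve(crossprod(Jc)), error = function(e) NULL)
  tau_se <- if (is.null(cov_log)) rep(NA_real_, n_exp) else {
    (sqrt(pmax(diag(cov_log)[seq_len(n_exp)], 0)) * fin$taus)[ord]
  }
  at_bounds <- abs(log(taus) - lo) < 1e-6 | abs(log(taus) - hi) < 1e-6

  structure(list(
    taus = taus, tau_se = tau_se, das = das,
    t0_fs = fin$t0, irf_fwhm_fs = irf_fwhm_fs,
    residual_rms = sqrt(mean(r^2)),
    convergence = best$convergence, at_bounds = at_bounds,
    delays_fs = t, probe_ev = map$probe_ev,
    reconstruction = fin$C %*% fin$das
  ), class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>\n  time constants (fs):",
      paste(sprintf("%.1f +- %.1f", x$taus, x$tau_se), collapse = ", "), "\n")
  cat(sprintf("  t0 = %.1f fs, IRF FWHM = %.1f fs, residual RMS = %.3g\n",
              x$t0_fs, x$irf_fwhm_fs, x$residual_rms))
  if (any(x$at_bounds)) cat("  WARNING: time constant at search bound\n")
  invisible(x)
}

#' Mono-exponential population lifetime
#'
#' Least-squares fit of \eqn{P(t) = A\, e^{-t/\tau} + c} to a population
#' trace; by default the amplitude is fixed at 1 and the plateau at 0
#' (\eqn{P(t) = e^{-t/\tau}}).
#'
#' @param time_fs,population the trace (populations in `[0, 1]`); a
#'   two-column data.frame can be given as the first argument.
#' @param model only `"monoexp"`.
#' @param fit_amplitude,fit_plateau optional free amplitude / plateau.
#' @param t0_fs fixed time offset subtracted from `time_fs`.
#' @return list with `tau_fs`, `se_fs`, `amplitude`, `plateau`, `fitted`.
#' @examples
#' t <- 0:500
#' fit_population_lifetime(t, exp(-t / 300))$tau_fs  # 300
#' @export
fit_population_lifetime <- function(time_fs, population = NULL,
                                    model = "monoexp",
                                    fit_amplitude = FALSE, fit_plateau = FALSE,
                                    t0_fs = 0) {
  model <- match.arg(model, "monoexp")
  if (is.null(population)) {
    stopifnot(is.data.frame(time_fs), ncol(time_fs) >= 2)
    population <- time_fs[[2]]
    time_fs <- time_fs[[1]]
  }
  if (!length(time_fs)) stop("empty trace")
  if (any(population < -1e-9) || any(population > 1 + 1e-9)) {
    stop("populations must lie in [0, 1]")
  }
  t <- time_fs - t0_fs
  keep <- t >= 0
  t <- t[keep]; P <- population[keep]
  slope <- suppressWarnings(stats::cor(t, P))
  if (P[length(P)] >= P[1] - 1e-12 && (is.na(slope) || slope >= 0)) {
    stop("trace does not decay; cannot fit a lifetime")
  }
  span <- max(diff(range(t)), 1)
  pred <- function(tau, A, c0) A * exp(-t / tau) + c0
  if (!fit_amplitude && !fit_plateau) {
    o <- stats::optimize(function(lt) sum((P - pred(exp(lt), 1, 0))^2),
                         c(log(span * 1e-3), log(span * 50)), tol = 1e-12)
    tau <- exp(o$minimum); A <- 1; c0 <- 0
  } else {
    par0 <- c(log(span / 3), if (fit_amplitude) P[1] else NULL,
              if (fit_plateau) min(P) else NULL)
    f <- function(p) {
      tau <- exp(p[1]); i <- 2
      A <- if (fit_amplitude) { a <- p[i]; i <- i + 1; a } else 1
      c0 <- if (fit_plateau) p[i] else 0
      sum((P - pred(tau, A, c0))^2)
    }
    o <- stats::optim(par0, f, control = list(maxit = 2000, reltol = 1e-13))
    tau <- exp(o$par[1]); i <- 2
    A <- if (fit_amplitude) { a <- o$par[i]; i <- i + 1; a } else 1
    c0 <- if (fit_plateau) o$par[i] else 0
  }
  fit <- pred(tau, A, c0)
  r <- P - fit
  J <- A * (t / tau^2) * exp(-t / tau)
  dof <- max(length(P) - 1L - fit_amplitude - fit_plateau, 1L)
  se <- sqrt(sum(r^2) / dof / max(sum(J^2), .Machine$double.eps))
  list(tau_fs = tau, se_fs = se, amplitude = A, plateau = c0, fitted = fit)
}

#' Exponential build-up time of a rising signal
#'
#' Least-squares fit of \eqn{y(t) = B (1 - e^{-t/\tau})}, used to compare
#' the build-up of the hot-ground-state absorption band with the decay of
#' the stimulated emission.
#'
#' @param time_fs,signal the rising trace.
#' @return list with `tau_fs`, `se_fs` (Jacobian-based), `amplitude`.
#' @export
fit_buildup_time <- function(time_fs, signal) {
  t <- time_fs
  y <- signal
  if (max(y) <= 0) stop("signal does not rise")
  f <- function(p) sum((y - p[2] * (1 - exp(-t / exp(p[1]))))^2)
  o <- stats::optim(c(log(max(t) / 5), max(y)), f,
                    control = list(reltol = 1e-13, maxit = 4000))
  tau <- exp(o$par[1]); B <- o$par[2]
  r <- y - B * (1 - exp(-t / tau))
  J <- cbind(-B * (t / tau^2) * exp(-t / tau), 1 - exp(-t / tau))
  cv <- tryCatch(solve(crossprod(J)) * sum(r^2) / max(length(y) - 2, 1),
                 error = function(e) NULL)
  list(tau_fs = tau, se_fs = if (is.null(cv)) NA_real_ else sqrt(cv[1, 1]),
       amplitude = B)
}
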