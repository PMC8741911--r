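#' ARMAX model specification
#'
#' Linear forecasting baseline `A(q) y_t = sum_i B_i(q) x_ti + C(q) e(t)`
#' in the standard backshift convention: `A(q) = 1 + a_1 q^-1 + ... +
#' a_na q^-na`, `C(q) = 1 + c_1 q^-1 + ... + c_nc q^-nc`, and one
#' polynomial `B_i(q) = b_0i + b_1i q^-1 + ...` per exogenous input. With
#' no exogenous input (`k = 0`) the model reduces to ARMA. A process
#' `y_t = phi y_{t-1} + e_t` therefore has `a_1 = -phi`.
#'
#' @param ar Numeric vector of `A(q)` coefficients `a_1..a_na` (excluding
#'   the leading 1); may be empty.
#' @param ma Numeric vector of `C(q)` coefficients `c_1..c_nc`; may be
#'   empty.
#' @param exo List of `B_i(q)` coefficient vectors, one per exogenous
#'   input; empty for ARMA.
#' @param sigma2 Innovation (white-noise) variance.
#' @param stable Logical: all roots of `A(q)` outside the unit circle.
#' @return An object of class `armax_spec`.
#' @export
armax_spec <- function(ar = numeric(0), ma = numeric(0), exo = list(),
                       sigma2 = NA_real_, stable = NA) {
  ar <- as.numeric(ar); ma <- as.numeric(ma)
  if (is.na(stable)) stable <- armax_stable(ar)
  structure(list(
    ar = ar, ma = ma, exo = exo,
    order = c(na = length(ar),
              nb = if (length(exo)) max(lengths(exo)) else 0L,
              nc = length(ma)),
    k = length(exo),
    sigma2 = sigma2,
    stable = stable,
    convention = "backshift"
  ), class = "armax_spec")
}

armax_stable <- function(ar) {
  if (length(ar) == 0L) return(TRUE)
  all(Mod(polyroot(c(1, ar))) > 1)
}

#' @export
print.armax_spec <- function(x, ...) {
  cat(sprintf("<armax_spec> na=%d nb=%d nc=%d (k=%d exogenous)%s\n",
              x$order["na"], x$order["nb"], x$order["nc"], x$k,
              if (!x$stable) " [UNSTABLE]" else ""))
  if (length(x$ar)) cat("  a:", signif(x$ar, 5), "\n")
  if (length(x$ma)) cat("  c:", signif(x$ma, 5), "\n")
  invisible(x)
}

lag_matrix <- function(y, lags, t_idx) {
  out <- matrix(0, length(t_idx), lags)
  for (j in seq_len(lags)) out[, j] <- y[t_idx - j]
  out
}

## Innovations of an ARMA model on a series, by direct recursion with
## zero initial conditions: e_t = y_t + sum a_i y_{t-i} - sum c_j e_{t-j}.
armax_innovations <- function(y, ar, ma) {
  n <- length(y)
  na <- length(ar); nc <- length(ma)
  e <- numeric(n)
  for (t in seq_len(n)) {
    acc <- y[t]
    if (na) for (i in seq_len(min(na, t - 1L))) acc <- acc + ar[i] * y[t - i]
    if (nc) for (j in seq_len(min(nc, t - 1L))) acc <- acc - ma[j] * e[t - j]
    e[t] <- acc
  }
  e
}

fit_armax_fixed <- function(y, na, nb, nc, x = NULL, n_iter = 2L) {
  n <- length(y)
  phi <- numeric(na); theta <- numeric(nc); bcoef <- list()
  if (nc == 0L) {
    ## pure AR(X): one ordinary least-squares pass
    t0 <- max(na, nb) + 1L
    t_idx <- t0:n
    X <- NULL
    if (na) X <- lag_matrix(y, na, t_idx)
    if (nb && !is.null(x)) {
      for (i in seq_len(ncol(x))) {
        X <- cbind(X, lag_matrix(x[, i], nb, t_idx))
      }
    }
    if (is.null(X)) {
      resid <- y
      sigma2 <- mean(y^2)
      return(list(phi = phi, theta = theta, b = bcoef, sigma2 = sigma2,
                  resid = resid))
    }
    fit <- stats::lm.fit(X, y[t_idx])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    if (na) phi <- cf[seq_len(na)]
    if (nb && !is.null(x)) {
      for (i in seq_len(ncol(x))) {
        bcoef[[i]] <- cf[na + (i - 1L) * nb + seq_len(nb)]
      }
    }
    resid <- fit$residuals
    sigma2 <- mean(resid^2)
    return(list(phi = phi, theta = theta, b = bcoef, sigma2 = sigma2,
                resid = resid))
  }
  ## Hannan-Rissanen: long-AR residuals, then least squares on lagged y,
  ## lagged x and lagged residuals, iterated with model-based residuals.
  p_long <- min(max(20L, 2L * (na + nc + nb)), max(na + nc + 1L, n %/% 4L))
  t_idx <- (p_long + 1L):n
  Xl <- lag_matrix(y, p_long, t_idx)
  fit1 <- stats::lm.fit(Xl, y[t_idx])
  e <- numeric(n)
  e[t_idx] <- fit1$residuals
  for (it in seq_len(n_iter)) {
    t0 <- max(na, nc, nb, p_long) + 1L
    ti <- t0:n
    X <- NULL
    if (na) X <- cbind(X, lag_matrix(y, na, ti))
    if (nb && !is.null(x)) {
      for (i in seq_len(ncol(x))) X <- cbind(X, lag_matrix(x[, i], nb, ti))
    }
    X <- cbind(X, lag_matrix(e, nc, ti))
    fit2 <- stats::lm.fit(X, y[ti])
    cf <- fit2$coefficients
    cf[is.na(cf)] <- 0
    pos <- 0L
    if (na) { phi <- cf[pos + seq_len(na)]; pos <- pos + na }
    if (nb && !is.null(x)) {
      bcoef <- list()
      for (i in seq_len(ncol(x))) {
        bcoef[[i]] <- cf[pos + seq_len(nb)]; pos <- pos + nb
      }
    }
    theta <- cf[pos + seq_len(nc)]
    ## refresh residuals from the fitted ARMA for the next pass
    e <- armax_innovations(y, -phi, theta)
  }
  resid <- e
  sigma2 <- mean(resid[(max(na, nc) + 1L):n]^2)
  list(phi = phi, theta = theta, b = bcoef, sigma2 = sigma2, resid = resid)
}

#' Fit an ARMAX / ARMA model to a context window
#'
#' Coefficients are estimated by least squares (Hannan-Rissanen two-stage
#' estimation with residual refinement when a moving-average part is
#' present). With `orders = "auto"` the AR and MA orders are selected by
#' BIC over a small grid (`na` 1..4, `nc` 0..2). Without an exogenous
#' input the model is fitted as ARMA (`k = 0`).
#'
#' @param context Numeric sample vector; must contain at least
#'   `10 * (na + nb + nc)` samples.
#' @param orders Integer vector `c(na, nb, nc)`, or `"auto"`.
#' @param exogenous Optional numeric matrix of exogenous inputs (columns =
#'   inputs, rows aligned with `context`).
#' @return An [armax_spec()] with estimated coefficients, the innovation
#'   variance and a stability flag (a warning is raised for an unstable
#'   AR polynomial).
#' @export
#' @examples
#' y <- as.numeric(arima.sim(list(ar = 0.9), n = 500))
#' fit_armax(y, orders = c(1, 0, 0))$ar # close to -0.9
fit_armax <- function(context, orders = "auto", exogenous = NULL) {
  y <- as.numeric(context)
  if (!all(is.finite(y))) stop("context must be finite")
  n <- length(y)
  if (!is.null(exogenous)) exogenous <- as.matrix(exogenous)
  if (identical(orders, "auto")) {
    grid <- expand.grid(na = 1:4, nc = 0:2)
    nb <- if (is.null(exogenous)) 0L else 2L
    best <- NULL; best_bic <- Inf
    for (r in seq_len(nrow(grid))) {
      na <- grid$na[r]; nc <- grid$nc[r]
      if (n < 10 * (na + nb + nc)) next
      f <- tryCatch(fit_armax_fixed(y, na, nb, nc, exogenous),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$sigma2) || f$sigma2 <= 0) next
      p <- na + nc + nb * if (is.null(exogenous)) 0L else ncol(exogenous)
      bic <- n * log(f$sigma2) + p * log(n)
      if (bic < best_bic) {
        best_bic <- bic; best <- f
        best_orders <- c(na, nb, nc)
      }
    }
    if (is.null(best)) stop("fit error: no ARMAX order could be fitted")
    f <- best
    na <- best_orders[1]; nb <- best_orders[2]; nc <- best_orders[3]
  } else {
    if (length(orders) != 3L || any(orders < 0)) {
      stop("`orders` must be c(na, nb, nc) or \"auto\"")
    }
    na <- as.integer(orders[1]); nb <- as.integer(orders[2])
    nc <- as.integer(orders[3])
    if (nb > 0L && is.null(exogenous)) {
      stop("nb > 0 requires an `exogenous` input matrix")
    }
    if (n < 10 * (na + nb + nc)) {
      stop(sprintf("context too short: need >= %d samples for orders (%d,%d,%d)",
                   10 * (na + nb + nc), na, nb, nc))
    }
    f <- fit_armax_fixed(y, na, nb, nc, exogenous)
  }
  if (any(!is.finite(c(f$phi, f$theta)))) {
    stop("fit error: singular design matrix")
  }
  spec <- armax_spec(ar = -f$phi, ma = f$theta, exo = f$b, sigma2 = f$sigma2)
  if (!spec$stable) {
    warning("fitted AR polynomial is not stable; spec flagged")
  }
  spec
}

#' @describeIn forecast Multi-step linear forecast from an `armax_spec`.
#'   In-sample innovations are reconstructed from the supplied context and
#'   future innovations are set to their zero mean.
#' @param horizon Number of future samples to forecast (ARMAX method).
#' @export
forecast.armax_spec <- function(model, context, horizon = 1L, ...) {
  y <- as.numeric(context)
  na <- length(model$ar); nc <- length(model$ma)
  if (length(y) < max(na, nc, 1L)) {
    stop("shape error: context shorter than the model memory")
  }
  e <- armax_innovations(y, model$ar, model$ma)
  n <- length(y)
  yy <- c(y, numeric(horizon))
  ee <- c(e, numeric(horizon)) # future innovations at their mean (zero)
  for (h in seq_len(horizon)) {
    t <- n + h
    acc <- 0
    if (na) for (i in seq_len(na)) acc <- acc - model$ar[i] * yy[t - i]
    if (nc) for (j in seq_len(nc)) acc <- acc + model$ma[j] * ee[t - j]
    yy[t] <- acc
  }
  yy[n + seq_len(horizon)]
}
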