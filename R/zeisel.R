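# Relative threshold below which beta and gamma (or k and 1) are treated as
# equal and all expressions switch to their analytic limit: the closed forms
# divide by (gamma - beta) and are singular there.
.degenerate_tol <- 1e-6

.check_rates <- function(alpha, beta, gamma) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("synthesis rate alpha must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("processing rate beta must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("degradation rate gamma must be finite and > 0", call. = FALSE)
  }
  invisible(NULL)
}

.check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time must be finite and >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Unlabeled (pre-existing) RNA pool under a labeling pulse
#'
#' Closed-form solution of the two-stage RNA kinetics model
#' \deqn{\dot p = \alpha - \beta p, \qquad \dot m = \beta p - \gamma m}
#' for the pre-existing RNA pool: at pulse start (`t = 0`) the pool is at
#' steady state `(alpha/beta, alpha/gamma)` and no new premature RNA enters
#' it, so both species decay,
#' \deqn{p_u(t) = \frac{\alpha}{\beta} e^{-\beta t}, \qquad
#'       m_u(t) = \frac{\alpha}{\gamma-\beta} e^{-\beta t}
#'              - \frac{\beta\alpha}{\gamma(\gamma-\beta)} e^{-\gamma t}.}
#' When `beta` and `gamma` coincide (relative difference below `1e-6`) the
#' removable singularity is evaluated by its analytic limit
#' \eqn{m_u(t) = \alpha(1/\gamma + t) e^{-\gamma t}}.
#'
#' @param alpha synthesis rate (abundance units per time unit).
#' @param beta processing (splicing) rate, 1/time.
#' @param gamma degradation rate, 1/time.
#' @param t time since pulse start, same unit as the rates; vectorised.
#' @return list with components `p` (premature) and `m` (mature abundance).
#' @seealso [labeled_pool()], [ode_pool_oracle()]
#' @export
#' @examples
#' unlabeled_pool(2, 0.5, 1, 0)  # steady state (4, 2)
unlabeled_pool <- function(alpha, beta, gamma, t) {
  .check_rates(alpha, beta, gamma)
  .check_time(t)
  p <- alpha / beta * exp(-beta * t)
  degen <- abs(beta - gamma) / gamma < .degenerate_tol
  m <- if (any(degen)) {
    # recycle to common length before masking
    n <- max(length(alpha), length(beta), length(gamma), length(t))
    al <- rep_len(alpha, n); be <- rep_len(beta, n)
    ga <- rep_len(gamma, n); tt <- rep_len(t, n)
    dg <- rep_len(degen, n)
    out <- numeric(n)
    out[dg] <- al[dg] * (1 / ga[dg] + tt[dg]) * exp(-ga[dg] * tt[dg])
    out[!dg] <- al[!dg] / (ga[!dg] - be[!dg]) * exp(-be[!dg] * tt[!dg]) -
      be[!dg] * al[!dg] / (ga[!dg] * (ga[!dg] - be[!dg])) *
        exp(-ga[!dg] * tt[!dg])
    out
  } else {
    alpha / (gamma - beta) * exp(-beta * t) -
      beta * alpha / (gamma * (gamma - beta)) * exp(-gamma * t)
  }
  list(p = p, m = m)
}

#' Labeled (newly synthesized) RNA pool under a labeling pulse
#'
#' Closed-form solution of the same kinetics for the RNA synthesized during
#' the pulse: the pool starts empty at `t = 0` and approaches the steady
#' state `(alpha/beta, alpha/gamma)`,
#' \deqn{p_l(t) = \frac{\alpha}{\beta}(1 - e^{-\beta t}), \qquad
#'       m_l(t) = \frac{\alpha}{\gamma}\Big(1 +
#'                \frac{\beta}{\gamma-\beta} e^{-\gamma t}\Big)
#'              - \frac{\alpha}{\gamma-\beta} e^{-\beta t}.}
#' By linearity the labeled and unlabeled pools sum to the steady state at
#' every time point.
#'
#' @inheritParams unlabeled_pool
#' @return list with components `p` and `m`.
#' @export
#' @examples
#' labeled_pool(2, 0.5, 1, 0)  # starts empty: (0, 0)
labeled_pool <- function(alpha, beta, gamma, t) {
  .check_rates(alpha, beta, gamma)
  .check_time(t)
  p <- -alpha / beta * expm1(-beta * t)
  degen <- abs(beta - gamma) / gamma < .degenerate_tol
  m <- if (any(degen)) {
    n <- max(length(alpha), length(beta), length(gamma), length(t))
    al <- rep_len(alpha, n); be <- rep_len(beta, n)
    ga <- rep_len(gamma, n); tt <- rep_len(t, n)
    dg <- rep_len(degen, n)
    out <- numeric(n)
    out[dg] <- al[dg] / ga[dg] -
      al[dg] * (1 / ga[dg] + tt[dg]) * exp(-ga[dg] * tt[dg])
    out[!dg] <- al[!dg] / ga[!dg] *
      (1 + be[!dg] / (ga[!dg] - be[!dg]) * exp(-ga[!dg] * tt[!dg])) -
      al[!dg] / (ga[!dg] - be[!dg]) * exp(-be[!dg] * tt[!dg])
    out
  } else {
    alpha / gamma * (1 + beta / (gamma - beta) * exp(-gamma * t)) -
      alpha / (gamma - beta) * exp(-beta * t)
  }
  list(p = p, m = m)
}

#' Intron-to-exon ratio of the unlabeled pool
#'
#' The observable \eqn{a = p_u(T) / (p_u(T) + m_u(T))} in the dimensionless
#' parametrisation `k = beta/gamma`, `x = gamma * T`:
#' \deqn{a(k, x) = \frac{(1-k) e^{-kx}}{e^{-kx} - k^2 e^{-x}}
#'              = \frac{1-k}{1 - k^2 e^{(k-1)x}}.}
#' The ratio does not depend on the synthesis rate `alpha`. The second,
#' algebraically identical form is used for evaluation: it avoids 0/0
#' underflow at large `x` and tends to the correct limits
#' (`1/(1+k)` as `x -> 0`; `1-k` for `k < 1` and `0` for `k > 1` as
#' `x -> Inf`). At `k = 1` the removable singularity equals `1/(2+x)`.
#'
#' @param k dimensionless rate ratio beta/gamma, > 0.
#' @param x dimensionless time gamma * T, > 0.
#' @return the ratio `a`, in (0, 1); vectorised over `k` and `x`.
#' @export
ratio_unlabeled <- function(k, x) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("k must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("x = gamma * T must be finite and > 0", call. = FALSE)
  }
  n <- max(length(k), length(x))
  kk <- rep_len(k, n); xx <- rep_len(x, n)
  a <- (1 - kk) / (1 - kk^2 * exp((kk - 1) * xx))
  degen <- abs(kk - 1) < .degenerate_tol
  a[degen] <- 1 / (2 + xx[degen])
  a
}

#' Intron-to-exon ratio of the labeled pool
#'
#' The observable \eqn{b = p_l(T) / (p_l(T) + m_l(T))}:
#' \deqn{b(k, x) = \frac{(1-k)(1 - e^{-kx})}
#'                      {(1 - e^{-kx}) - k^2 (1 - e^{-x})},}
#' the unlabeled form with every exponential replaced by its complement to
#' one. Independent of `alpha`; `b -> 1` as `x -> 0` and
#' `b -> 1/(1+k)` as `x -> Inf`. Evaluated with `expm1` so that the
#' small-`x` cancellation is exact; at `k = 1` the limit
#' \eqn{(1-e^{-x}) / (2(1-e^{-x}) - x e^{-x})} is used.
#'
#' @inheritParams ratio_unlabeled
#' @return the ratio `b`, in (0, 1]; vectorised.
#' @export
ratio_labeled <- function(k, x) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("k must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("x = gamma * T must be finite and > 0", call. = FALSE)
  }
  n <- max(length(k), length(x))
  kk <- rep_len(k, n); xx <- rep_len(x, n)
  ekx <- -expm1(-kk * xx)   # 1 - exp(-k x)
  ex <- -expm1(-xx)         # 1 - exp(-x)
  b <- (1 - kk) * ekx / (ekx - kk^2 * ex)
  degen <- abs(kk - 1) < .degenerate_tol
  b[degen] <- ex[degen] / (2 * ex[degen] - xx[degen] * exp(-xx[degen]))
  b
}

#' Observable-plane trajectory for a fixed rate ratio k
#'
#' As the dimensionless time `x = gamma * T` grows, the observable pair
#' `(a, b)` traces a curve in the unit square that depends only on `k`:
#' it starts at `(1/(1+k), 1)` for `x -> 0` and converges to
#' `(1-k, 1/(1+k))` for `k < 1` or `(0, 1/(1+k))` for `k >= 1`. `b`
#' decreases monotonically along the trajectory. Trajectories with `k > 1`
#' dip below the separating curve `b = 1/(2-a)` and cross each other there,
#' which is where two distinct `(beta, gamma)` pairs explain the same
#' observables.
#'
#' @param k dimensionless rate ratio beta/gamma (scalar).
#' @param x_grid strictly positive, strictly ascending vector of
#'   `gamma * T` values.
#' @return data.frame with columns `x`, `a`, `b`.
#' @export
trajectory <- function(k, x_grid) {
  if (length(k) != 1L) stop("k must be a scalar", call. = FALSE)
  if (any(x_grid <= 0) || is.unsorted(x_grid, strictly = TRUE)) {
    stop("x_grid must be strictly positive and strictly ascending",
         call. = FALSE)
  }
  data.frame(x = x_grid,
             a = ratio_unlabeled(k, x_grid),
             b = ratio_labeled(k, x_grid))
}

#' Numerical-integration oracle for the kinetics model
#'
#' Integrates \eqn{\dot p = \alpha - \beta p}, \eqn{\dot m = \beta p -
#' \gamma m} from an arbitrary initial state with `deSolve`, at tight
#' tolerances. Exists to verify the closed forms independently: with the
#' steady-state initial condition and `alpha = 0` it reproduces
#' [unlabeled_pool()]; from the empty state with synthesis on it reproduces
#' [labeled_pool()].
#'
#' @param alpha synthesis rate, >= 0 (zero models the unlabeled pool, which
#'   receives no new premature RNA).
#' @param beta,gamma processing and degradation rates, > 0.
#' @param t end time, >= 0.
#' @param initial numeric vector or list with components `p` and `m`.
#' @return list with components `p` and `m` at time `t`.
#' @export
ode_pool_oracle <- function(alpha, beta, gamma, t, initial) {
  if (!is.finite(alpha) || alpha < 0) {
    stop("alpha must be finite and >= 0", call. = FALSE)
  }
  .check_rates(1, beta, gamma)
  .check_time(t)
  y0 <- c(p = as.numeric(initial[["p"]]), m = as.numeric(initial[["m"]]))
  if (t == 0) return(list(p = unname(y0["p"]), m = unname(y0["m"])))
  deriv <- function(time, y, parms) {
    list(c(parms["alpha"] - parms["beta"] * y["p"],
           parms["beta"] * y["p"] - parms["gamma"] * y["m"]))
  }
  sol <- deSolve::ode(y = y0, times = c(0, t), func = deriv,
                      parms = c(alpha = alpha, beta = beta, gamma = gamma),
                      rtol = 1e-12, atol = 1e-14, method = "lsoda")
  last <- sol[nrow(sol), ]
  if (any(!is.finite(last[c("p", "m")]))) {
    stop("ODE integration failed (non-finite state)", call. = FALSE)
  }
  list(p = unname(last[["p"]]), m = unname(last[["m"]]))
}
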