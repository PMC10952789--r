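# Unit system: lengths in micrometres, time in ms, gradient amplitude in
# mT/m.  The effective gyromagnetic ratio below is 2.675e8 rad s^-1 T^-1
# expressed in those units, so q = gamma * integral(G dt) comes out in
# rad/um and b-values in ms um^-2 directly.
GAMMA_EFF <- 2.675e-4  # rad ms^-1 um^-1 per (mT/m)

#' Specify a diffusion-encoding sequence
#'
#' Describes the effective diffusion gradient of one of three clinical
#' DT-CMR sequences: monopolar stimulated echo (STEAM, mixing interval of
#' order one cardiac cycle), monopolar pulsed-gradient spin echo (PGSE), and
#' gradient-duration-modulated second-order motion-compensated spin echo
#' (MCSE).  Timings default to representative clinical values and can be
#' overridden to match a particular protocol.
#'
#' @param kind `"STEAM"`, `"PGSE"` or `"MCSE"`.
#' @param delta Gradient flat-top duration in ms (STEAM/PGSE lobes).
#' @param epsilon Ramp-up/ramp-down time in ms.
#' @param Delta Gradient separation (leading edge to leading edge) in ms;
#'   for STEAM this spans the mixing interval.
#' @param T_enc Total encoding duration in ms (MCSE only; the four lobe
#'   flat-tops are solved so the zeroth, first and second gradient moments
#'   all vanish at `T_enc`).
#' @param t_rf Gap left for the refocusing pulse in ms (MCSE only).
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(kind = c("STEAM", "PGSE", "MCSE"),
                          delta = NULL, epsilon = 1, Delta = NULL,
                          T_enc = NULL, t_rf = 6) {
  kind <- match.arg(kind)
  if (kind == "PGSE") {
    if (is.null(delta)) delta <- 20
    if (is.null(Delta)) Delta <- 30
  } else if (kind == "STEAM") {
    if (is.null(delta)) delta <- 6
    if (is.null(Delta)) Delta <- 1000
  } else {
    if (is.null(T_enc)) T_enc <- 70
  }
  if (kind != "MCSE") {
    stopifnot(delta > 0, epsilon >= 0, Delta > 0)
    if (Delta < delta + 2 * epsilon) {
      stop("gradient lobes overlap: need Delta >= delta + 2 * epsilon")
    }
  } else {
    stopifnot(T_enc > 0, epsilon > 0, t_rf >= 0)
  }
  structure(list(kind = kind, delta = delta, epsilon = epsilon,
                 Delta = Delta, T_enc = T_enc, t_rf = t_rf),
            class = "sequence_spec")
}

new_waveform <- function(kind, t, g, Gmax, spec = NULL) {
  structure(list(kind = kind, t = t, g = g, T = t[length(t)], Gmax = Gmax,
                 spec = spec),
            class = "gradient_waveform")
}

#' Build the effective gradient waveform of a sequence
#'
#' Returns the piecewise-linear effective gradient G(t): the refocusing
#' pulses are folded into the sign of G so that the particle phase is the
#' single integral gamma * int X(t).G(t) dt.  STEAM and PGSE give two
#' matched trapezoidal lobes of opposite effective sign separated by
#' `Delta`; MCSE gives an asymmetric four-lobe train whose flat-top
#' durations are solved numerically so that the zeroth, first and second
#' moments all vanish at the end of encoding.
#'
#' @param spec A [sequence_spec()].
#' @param Gmax Gradient amplitude in mT/m (default 1; see [solve_gmax()]).
#' @return An object of class `gradient_waveform` with breakpoints `t` (ms)
#'   and signed amplitudes `g` (mT/m).
#' @export
make_waveform <- function(spec, Gmax = 1) {
  stopifnot(inherits(spec, "sequence_spec"), Gmax > 0)
  if (spec$kind %in% c("STEAM", "PGSE")) {
    d <- spec$delta; e <- spec$epsilon; D <- spec$Delta
    t <- c(0, e, e + d, 2 * e + d,
           D, D + e, D + e + d, D + 2 * e + d)
    g <- c(0, 1, 1, 0, 0, -1, -1, 0) * Gmax
    if (e == 0) {  # ideal rectangular limit
      t <- c(0, 0, d, d, D, D, D + d, D + d)
    }
    return(new_waveform(spec$kind, t, g, Gmax, spec))
  }
  f <- solve_mcse_flattops(spec)
  e <- spec$epsilon
  lob <- function(t0, ft, s) {
    list(t = c(t0, t0 + e, t0 + e + ft, t0 + 2 * e + ft),
         g = c(0, s, s, 0))
  }
  t0 <- 0
  signs <- c(1, -1, 1, -1)
  gaps <- c(0, 0, spec$t_rf, 0)
  t <- numeric(0); g <- numeric(0)
  for (i in 1:4) {
    t0 <- t0 + gaps[i]
    L <- lob(t0, f[i], signs[i])
    t <- c(t, L$t); g <- c(g, L$g)
    t0 <- L$t[4]
  }
  new_waveform("MCSE", t, g * Gmax, Gmax, spec)
}

# Solve the four MCSE flat-top durations so that m0(T) = m1(T) = m2(T) = 0
# and the lobes plus the RF gap fill T_enc exactly.  Newton iteration with a
# numerical Jacobian on exact piecewise moments.
solve_mcse_flattops <- function(spec) {
  e <- spec$epsilon; Tn <- spec$T_enc; trf <- spec$t_rf
  avail <- Tn - 8 * e - trf
  if (avail <= 0) stop("MCSE timings infeasible: no room for lobes")
  resid <- function(f) {
    if (any(f <= 0)) return(rep(1e6, 4))
    sp <- spec; w <- tryCatch({
      f_ <- f
      eloc <- e
      lobt <- function(t0, ft, s) {
        list(t = c(t0, t0 + eloc, t0 + eloc + ft, t0 + 2 * eloc + ft),
             g = c(0, s, s, 0))
      }
      t0 <- 0; signs <- c(1, -1, 1, -1); gaps <- c(0, 0, trf, 0)
      t <- numeric(0); g <- numeric(0)
      for (i in 1:4) {
        t0 <- t0 + gaps[i]
        L <- lobt(t0, f_[i], signs[i])
        t <- c(t, L$t); g <- c(g, L$g)
        t0 <- L$t[4]
      }
      new_waveform("MCSE", t, g, 1, sp)
    }, error = function(e) NULL)
    if (is.null(w)) return(rep(1e6, 4))
    m <- waveform_moments(w, 0:2)
    sc <- c(avail, avail^2, avail^3) / 4
    c(m / sc, (sum(f) - avail) / avail)
  }
  f <- avail * c(0.22, 0.30, 0.28, 0.20)
  for (it in 1:100) {
    r0 <- resid(f)
    if (max(abs(r0)) < 1e-12) break
    J <- matrix(0, 4, 4)
    h <- pmax(1e-7 * abs(f), 1e-9)
    for (j in 1:4) {
      fp <- f; fp[j] <- fp[j] + h[j]
      J[, j] <- (resid(fp) - r0) / h[j]
    }
    step <- tryCatch(solve(J, r0), error = function(e) NULL)
    if (is.null(step)) stop("MCSE moment-nulling failed: singular Jacobian")
    lam <- 1
    repeat {
      fn <- f - lam * step
      if (all(fn > 0) && sum(abs(resid(fn))) <= sum(abs(r0)) + 1e-15) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    f <- f - lam * step
  }
  if (max(abs(resid(f))) > 1e-9) {
    stop("MCSE moment-nulling did not converge for these timings")
  }
  f
}

# Exact gradient moments m_n = int t^n G(t) dt (n in `orders`) of a
# piecewise-linear waveform, via 2-point Gauss-Legendre per piece (exact for
# cubic integrands, i.e. n <= 2).
waveform_moments <- function(w, orders = 0:2) {
  t <- w$t; g <- w$g
  x <- c(-1, 1) / sqrt(3)
  out <- numeric(length(orders))
  for (i in seq_len(length(t) - 1)) {
    h <- t[i + 1] - t[i]
    if (h <= 0) next
    tm <- (t[i] + t[i + 1]) / 2 + x * h / 2
    gm <- g[i] + (g[i + 1] - g[i]) * (tm - t[i]) / h
    for (k in seq_along(orders)) {
      out[k] <- out[k] + h / 2 * sum(gm * tm^orders[k])
    }
  }
  out
}

# q(t) = gamma * int_0^t G at the waveform breakpoints (exact trapezoid).
waveform_q_breaks <- function(w) {
  t <- w$t; g <- w$g
  dq <- diff(t) * (utils::head(g, -1) + utils::tail(g, -1)) / 2
  GAMMA_EFF * c(0, cumsum(dq))
}

#' Compute the b-value of a gradient waveform
#'
#' Standard definition `b = int_0^T q(t)^2 dt` with
#' `q(t) = gamma int_0^t G dt'`, evaluated exactly for piecewise-linear G
#' (3-point Gauss-Legendre per piece, exact for the quartic integrand).
#'
#' @param w A `gradient_waveform`.
#' @return The b-value in ms um^-2.
#' @export
b_value <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"))
  t <- w$t; g <- w$g
  q0 <- waveform_q_breaks(w)
  xs <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  ws <- c(5, 8, 5) / 9
  b <- 0
  for (i in seq_len(length(t) - 1)) {
    h <- t[i + 1] - t[i]
    if (h <= 0) next
    tm <- (t[i] + t[i + 1]) / 2 + xs * h / 2
    dt_ <- tm - t[i]
    slope <- (g[i + 1] - g[i]) / h
    q <- q0[i] + GAMMA_EFF * (g[i] * dt_ + slope * dt_^2 / 2)
    b <- b + h / 2 * sum(ws * q^2)
  }
  b
}

#' Solve the gradient amplitude that yields a target b-value
#'
#' Exploits `b proportional to Gmax^2` for a fixed waveform shape, so the
#' solution is a single scaling of the unit-amplitude b-value.  The paper
#' protocol uses two amplitudes per sequence, matching a reference b-value
#' of 0.15 ms um^-2 and a main b-value of 0.6 ms um^-2.
#'
#' @param spec A [sequence_spec()].
#' @param target_b Target b-value in ms um^-2 (> 0).
#' @return Gmax in mT/m such that `b_value(make_waveform(spec, Gmax))`
#'   equals `target_b`.
#' @export
solve_gmax <- function(spec, target_b) {
  stopifnot(target_b > 0)
  b1 <- b_value(make_waveform(spec, Gmax = 1))
  sqrt(target_b / b1)
}

#' Normalized gradient profile and its running moment
#'
#' Normalizes the waveform in amplitude and time: `h(s) = G(sT) / Gmax` on
#' `s` in [0, 1], with running zeroth moment `m0(s) = int_0^s h` and its
#' integral `M(s) = int_0^s m0`, both evaluated exactly from the
#' piecewise-linear profile (no time-stepping).  `m0(1) = 0` by refocusing.
#'
#' @param w A `gradient_waveform` with `Gmax > 0`.
#' @return A list of class `waveform_profile` with vectorized functions
#'   `h(s)`, `m0(s)`, `M(s)` and the normalized breakpoints `s`.
#' @export
normalized_profile <- function(w) {
  stopifnot(inherits(w, "gradient_waveform"), w$Gmax > 0)
  Ttot <- w$T
  s <- w$t / Ttot
  h <- w$g / w$Gmax
  # collapse zero-length pieces from ideal (epsilon = 0) waveforms
  keep <- c(TRUE, diff(s) > 0 | diff(h) != 0)
  s <- s[keep]; h <- h[keep]
  n <- length(s)
  m0b <- numeric(n); Mb <- numeric(n)
  for (i in seq_len(n - 1)) {
    ds <- s[i + 1] - s[i]
    m0b[i + 1] <- m0b[i] + ds * (h[i] + h[i + 1]) / 2
    r <- if (ds > 0) (h[i + 1] - h[i]) / ds else 0
    Mb[i + 1] <- Mb[i] + m0b[i] * ds + h[i] * ds^2 / 2 + r * ds^3 / 6
  }
  piece <- function(x) pmin(pmax(findInterval(x, s), 1L), n - 1L)
  h_fun <- function(x) {
    i <- piece(x); ds <- s[i + 1] - s[i]
    r <- ifelse(ds > 0, (h[i + 1] - h[i]) / ds, 0)
    h[i] + r * (x - s[i])
  }
  m0_fun <- function(x) {
    i <- piece(x); ds <- s[i + 1] - s[i]
    r <- ifelse(ds > 0, (h[i + 1] - h[i]) / ds, 0)
    u <- x - s[i]
    m0b[i] + h[i] * u + r * u^2 / 2
  }
  M_fun <- function(x) {
    i <- piece(x); ds <- s[i + 1] - s[i]
    r <- ifelse(ds > 0, (h[i + 1] - h[i]) / ds, 0)
    u <- x - s[i]
    Mb[i] + m0b[i] * u + h[i] * u^2 / 2 + r * u^3 / 6
  }
  structure(list(h = h_fun, m0 = m0_fun, M = M_fun, s = s,
                 breaks_h = h, breaks_m0 = m0b, breaks_M = Mb),
            class = "waveform_profile")
}

# Per-step mean effective gradient (times gamma) used by the walker engine:
# amp[k] = gamma * (Q(t_{k+1}) - Q(t_k)) / dt with Q = int G, exact for the
# piecewise-linear waveform, so that sum(amp * dt) = gamma * int G = 0.
waveform_step_amps <- function(w, nt) {
  Ttot <- w$T
  dt <- Ttot / nt
  tt <- seq(0, Ttot, length.out = nt + 1)
  Q <- waveform_cumint(w, tt)
  GAMMA_EFF * diff(Q) / dt
}

# int_0^x G dt at arbitrary times (piecewise quadratic, exact)
waveform_cumint <- function(w, x) {
  t <- w$t; g <- w$g
  n <- length(t)
  Qb <- c(0, cumsum(diff(t) * (utils::head(g, -1) + utils::tail(g, -1)) / 2))
  i <- pmin(pmax(findInterval(x, t), 1L), n - 1L)
  h <- t[i + 1] - t[i]
  slope <- ifelse(h > 0, (g[i + 1] - g[i]) / h, 0)
  u <- pmin(pmax(x - t[i], 0), ifelse(h > 0, h, 0))
  Qb[i] + g[i] * u + slope * u^2 / 2
}

#' @export
print.sequence_spec <- function(x, ...) {
  if (x$kind == "MCSE") {
    cat(sprintf("<sequence_spec> MCSE, T_enc %.1f ms, ramp %.2f ms, RF gap %.1f ms\n",
                x$T_enc, x$epsilon, x$t_rf))
  } else {
    cat(sprintf("<sequence_spec> %s, delta %.1f ms, ramp %.2f ms, Delta %.1f ms\n",
                x$kind, x$delta, x$epsilon, x$Delta))
  }
  invisible(x)
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform> %s, T %.1f ms, Gmax %.3f mT/m, b %.4g ms/um^2\n",
              x$kind, x$T, x$Gmax, b_value(x)))
  invisible(x)
}

#' Plot a gradient waveform
#'
#' @param object A `gradient_waveform`.
#' @param ... Unused.
#' @return A ggplot of the effective gradient versus time.
#' @export
autoplot.gradient_waveform <- function(object, ...) {
  df <- tibble::tibble(t = object$t, G = object$g)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$G)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "effective gradient (mT/m)",
                  title = object$kind)
}
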