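#' Diffusion encoding scheme
#'
#' The default six directions are the normalized dual-gradient set
#' (1,1,0), (1,0,1), (0,1,1), (1,-1,0), (1,0,-1), (0,1,-1).  With a
#' positive reference b-value the scheme holds 12 measurements (six
#' directions at `bref` and at `b`); with `bref = 0` it holds seven (six at
#' `b` plus one unweighted).
#'
#' @param b Main b-value (ms um^-2), default 0.6.
#' @param bref Reference b-value (ms um^-2), 0 or 0.15 in the protocol;
#'   must be smaller than `b`.
#' @param directions Optional `6 x 3` (or more) matrix of directions; rows
#'   are normalized.  The design must span the six unique tensor components.
#' @return A list of class `encoding_scheme` with a `measurements` tibble.
#' @export
encoding_scheme <- function(b = 0.6, bref = 0.15, directions = NULL) {
  stopifnot(b > 0, bref >= 0, bref < b)
  if (is.null(directions)) {
    directions <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1,
                           1, -1, 0, 1, 0, -1, 0, 1, -1),
                         ncol = 3, byrow = TRUE)
  }
  directions <- matrix(as.numeric(directions), ncol = 3)
  directions <- directions / sqrt(rowSums(directions^2))
  if (qr(design_rows(directions))$rank < 6) {
    stop("encoding directions do not span the six tensor components")
  }
  dirs <- tibble::tibble(gx = directions[, 1], gy = directions[, 2],
                         gz = directions[, 3])
  meas <- if (bref > 0) {
    dplyr::bind_rows(dplyr::mutate(dirs, b = bref), dplyr::mutate(dirs, b = b))
  } else {
    dplyr::bind_rows(tibble::tibble(gx = 0, gy = 0, gz = 1, b = 0),
                     dplyr::mutate(dirs, b = b))
  }
  structure(list(b = b, bref = bref, directions = directions,
                 measurements = dplyr::select(meas, "b", "gx", "gy", "gz")),
            class = "encoding_scheme")
}

# rows [ex^2, ey^2, ez^2, 2 ex ey, 2 ex ez, 2 ey ez]
design_rows <- function(directions) {
  e <- directions
  cbind(e[, 1]^2, e[, 2]^2, e[, 3]^2,
        2 * e[, 1] * e[, 2], 2 * e[, 1] * e[, 3], 2 * e[, 2] * e[, 3])
}

#' Mix diffusion and perfusion signals
#'
#' Weighted sum `S = f * S_perf + (1 - f) * S_diff`, elementwise on an
#' identical (direction, b-value) grid.
#'
#' @param S_diff,S_perf Tibbles with columns `b`, `gx`, `gy`, `gz`,
#'   `S_over_S0` (e.g. from [run_diffusion()] and [run_perfusion()]).
#' @param f Perfusion fraction in [0, 1].
#' @return A tibble on the same grid with the mixed `S_over_S0`.
#' @export
combine_signals <- function(S_diff, S_perf, f) {
  stopifnot(f >= 0, f <= 1)
  key <- function(d) paste(signif(d$b, 10), signif(d$gx, 10),
                           signif(d$gy, 10), signif(d$gz, 10))
  a <- dplyr::arrange(S_diff, .data$b, .data$gx, .data$gy, .data$gz)
  p <- dplyr::arrange(S_perf, .data$b, .data$gx, .data$gy, .data$gz)
  if (nrow(a) != nrow(p) || any(key(a) != key(p))) {
    stop("diffusion and perfusion signals are not on the same grid")
  }
  dplyr::mutate(a, S_over_S0 = f * p$S_over_S0 + (1 - f) * .data$S_over_S0)
}

#' Fit the diffusion tensor to normalized signals
#'
#' Log-linear least squares on the mono-exponential model
#' `S/S0 = exp(-b e_g' D e_g)`.  With a positive reference b-value the
#' default (`method = "ratio"`) regresses the per-direction log-signal
#' difference `ln S(b) - ln S(bref)` against `(b - bref)`, so any signal
#' component common to both b-values (such as perfusion attenuation already
#' present at `bref`) cancels; `method = "joint"` instead fits all
#' measurements with a common intercept.  With `bref = 0` the normalized
#' `S(0) = 1` anchors the fit.
#'
#' @param signals Tibble with columns `b`, `gx`, `gy`, `gz`, `S_over_S0`
#'   (one sequence at a time), strictly positive signals.
#' @param bref Reference b-value; inferred from the data when `NULL`
#'   (smallest b present).
#' @param method `"ratio"` (default) or `"joint"` (only differs when
#'   `bref > 0`).
#' @param e1_ref Reference axis for the sign of the primary eigenvector
#'   (default the mean cardiomyocyte long axis, +Z).
#' @return An object of class `tensor_fit`.
#' @export
fit_tensor <- function(signals, bref = NULL, method = c("ratio", "joint"),
                       e1_ref = c(0, 0, 1)) {
  method <- match.arg(method)
  if (any(signals$S_over_S0 <= 0)) {
    stop("non-positive signal: log-linear tensor fit undefined")
  }
  bs <- sort(unique(signals$b))
  if (is.null(bref)) bref <- bs[1]
  bmain <- max(bs)
  if (!any(bs > bref)) stop("need measurements above the reference b-value")

  hi <- signals[signals$b == bmain, ]
  dirs_hi <- as.matrix(hi[, c("gx", "gy", "gz")])
  X <- design_rows(dirs_hi)
  if (qr(X)$rank < 6) stop("rank-deficient encoding scheme")

  if (bref > 0 && method == "joint") {
    use <- signals[signals$b > 0, ]
    Xj <- cbind(1, -use$b * design_rows(as.matrix(use[, c("gx", "gy", "gz")])))
    fitc <- stats::lsfit(Xj, log(use$S_over_S0), intercept = FALSE)
    dvec <- fitc$coefficients[-1]
    resid <- sqrt(mean(fitc$residuals^2))
  } else {
    if (bref > 0) {
      lo <- signals[signals$b == bref, ]
      klo <- paste(signif(lo$gx, 10), signif(lo$gy, 10), signif(lo$gz, 10))
      khi <- paste(signif(hi$gx, 10), signif(hi$gy, 10), signif(hi$gz, 10))
      m <- match(khi, klo)
      if (any(is.na(m))) stop("reference measurements missing some directions")
      y <- -(log(hi$S_over_S0) - log(lo$S_over_S0[m])) / (bmain - bref)
    } else {
      y <- -log(hi$S_over_S0) / bmain
    }
    fitc <- stats::lsfit(X, y, intercept = FALSE)
    dvec <- fitc$coefficients
    resid <- sqrt(mean(fitc$residuals^2))
  }

  D <- matrix(c(dvec[1], dvec[4], dvec[5],
                dvec[4], dvec[2], dvec[6],
                dvec[5], dvec[6], dvec[3]), 3, 3)
  eg <- eigen(D, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  lam <- eg$values[ord]
  V <- eg$vectors[, ord, drop = FALSE]
  if (sum(V[, 1] * e1_ref) < 0) V[, 1] <- -V[, 1]
  for (j in 2:3) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  md <- mean(lam)
  fa <- if (sum(lam^2) > 0) {
    sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  } else 0
  structure(list(D = D, eigenvalues = lam, eigenvectors = V,
                 MD = md, FA = fa,
                 lambda2_over_lambda3 = lam[2] / lam[3],
                 residual = resid,
                 b = bmain, bref = bref, method = method,
                 n_meas = nrow(signals)),
            class = "tensor_fit")
}

#' Scalar metrics of a fitted tensor
#'
#' @param fit A `tensor_fit`.
#' @return A one-row tibble with MD, FA, the eigenvalues and lambda2/lambda3.
#' @export
tensor_metrics <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  tibble::tibble(MD = fit$MD, FA = fit$FA,
                 lambda1 = fit$eigenvalues[1], lambda2 = fit$eigenvalues[2],
                 lambda3 = fit$eigenvalues[3],
                 lambda2_over_lambda3 = fit$lambda2_over_lambda3)
}

#' Cone of uncertainty of an eigenvector across replicates
#'
#' Forms the mean dyadic tensor `mean(e e')` of the chosen eigenvector over
#' replicate fits (sign-invariant by construction), takes its principal
#' axis as the mean orientation, and reports the 95th percentile of the
#' angular deviations from that axis.
#'
#' @param fits A list of `tensor_fit` objects (>= 3) or an `n x 3` matrix
#'   of replicate eigenvectors.
#' @param which Eigenvector index 1-3 (ignored for a matrix input).
#' @return Cone angle in degrees.
#' @export
cone_of_uncertainty <- function(fits, which = 1) {
  if (is.matrix(fits)) {
    E <- fits
  } else {
    if (length(fits) < 3) stop("need at least 3 replicate tensors")
    E <- t(vapply(fits, function(f) f$eigenvectors[, which], numeric(3)))
  }
  E <- E / sqrt(rowSums(E^2))
  dy <- crossprod(E) / nrow(E)            # mean dyadic
  p <- eigen(dy, symmetric = TRUE)$vectors[, 1]
  ang <- acos(pmin(abs(E %*% p), 1)) * 180 / pi
  as.numeric(stats::quantile(ang, 0.95))
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf(
    "<tensor_fit> b %.2f / bref %.2f (%s fit)\n  MD %.4f um^2/ms, FA %.4f, lambda (%.4f, %.4f, %.4f)\n",
    x$b, x$bref, x$method, x$MD, x$FA,
    x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  invisible(x)
}

#' Tidy a fitted tensor
#'
#' @param x A `tensor_fit`.
#' @param ... Unused.
#' @return A tibble with one row per unique tensor component.
#' @export
tidy.tensor_fit <- function(x, ...) {
  tibble::tibble(term = c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"),
                 estimate = c(x$D[1, 1], x$D[2, 2], x$D[3, 3],
                              x$D[1, 2], x$D[1, 3], x$D[2, 3]))
}

#' One-row summary of a fitted tensor
#'
#' @param x A `tensor_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the scalar metrics and fit metadata.
#' @export
glance.tensor_fit <- function(x, ...) {
  dplyr::mutate(tensor_metrics(x), residual = x$residual,
                b = x$b, bref = x$bref, n_meas = x$n_meas)
}

#' Plot the eigenvalue spectrum of a fitted tensor
#'
#' @param object A `tensor_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of the three eigenvalues.
#' @export
autoplot.tensor_fit <- function(object, ...) {
  df <- tibble::tibble(eigenvalue = factor(paste0("lambda", 1:3)),
                       value = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "diffusivity (um^2/ms)",
                  title = sprintf("MD %.3f, FA %.3f", object$MD, object$FA))
}

#' Plot signal attenuation versus b-value and direction
#'
#' @param signals A signals tibble (from [run_diffusion()],
#'   [run_perfusion()] or [combine_signals()]).
#' @return A ggplot of `S/S0` against b, one line per direction.
#' @export
plot_signal_attenuation <- function(signals) {
  df <- dplyr::mutate(signals,
                      direction = sprintf("(%.2g, %.2g, %.2g)",
                                          .data$gx, .data$gy, .data$gz))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$S_over_S0,
                                   colour = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~sequence) +
    ggplot2::labs(x = "b (ms/um^2)", y = "S / S0")
}
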