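#' Melting / denaturation curves
#'
#' A `melting_curve` pairs a strictly increasing x grid (temperature in degC
#' or denaturant concentration in mol/L) with a signal (raw spectroscopic
#' units or fraction unfolded).
#'
#' @param x numeric grid, strictly increasing.
#' @param y signal values, same length.
#' @param x_kind `"temperature"`, `"urea"` or `"gdnhcl"`.
#' @param y_kind `"ellipticity_222nm"`, `"fluorescence_308nm"` or
#'   `"fraction"`.
#' @param truth optional named list of generating parameters (kept as
#'   metadata by the synthetic generator for recovery tests).
#' @return Object of class `melting_curve`.
#' @export
melting_curve <- function(x, y,
                          x_kind = c("temperature", "urea", "gdnhcl"),
                          y_kind = c("fraction", "ellipticity_222nm",
                                     "fluorescence_308nm"),
                          truth = NULL) {
  x_kind <- match.arg(x_kind)
  y_kind <- match.arg(y_kind)
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  if (any(diff(x) <= 0)) stop_validation("x must be strictly increasing")
  structure(list(x = x, y = y, x_kind = x_kind, y_kind = y_kind,
                 truth = truth),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat("Melting curve:", length(x$x), "points,", x$x_kind, "vs", x$y_kind, "\n")
  invisible(x)
}

#' Read/write melting curves as CSV
#'
#' Two columns (x, y); the header names declare the axis kinds, e.g.
#' `temperature,fraction`.
#'
#' @param curve a `melting_curve`.
#' @param path CSV file.
#' @return `read_melting_curve()` returns a `melting_curve`;
#'   `write_melting_curve()` returns `path` invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  df <- data.frame(curve$x, curve$y)
  names(df) <- c(curve$x_kind, curve$y_kind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_melting_curve
#' @export
read_melting_curve <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop_validation("curve CSV needs two columns")
  if (!all(vapply(df[1:2], is.numeric, logical(1)))) {
    bad <- which(!vapply(df[1:2], is.numeric, logical(1)))[1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))))[1L]
    stop_validation("non-numeric value in column ", names(df)[bad],
                    ", row ", row)
  }
  xk <- names(df)[1L]; yk <- names(df)[2L]
  melting_curve(df[[1L]], df[[2L]],
                x_kind = if (xk %in% c("temperature", "urea", "gdnhcl")) xk
                         else "temperature",
                y_kind = if (yk %in% c("fraction", "ellipticity_222nm",
                                       "fluorescence_308nm")) yk
                         else "fraction")
}

#' Normalise a raw signal curve to fraction unfolded
#'
#' \eqn{f_U(x) = (y(x) - y_N) / (y_D - y_N)} with native and denatured
#' baselines either supplied or estimated from the flat ends of the curve
#' (mean of the first/last two points).  Noise can push values slightly
#' outside \[0, 1\]; they are flagged, not clipped.
#'
#' @param curve a `melting_curve` with a raw signal.
#' @param native_baseline,denatured_baseline baseline signal levels; `NULL`
#'   to estimate from the curve ends.
#' @return A `melting_curve` with `y_kind = "fraction"`; attribute
#'   `"out_of_range"` marks points outside \[0, 1\].
#' @export
normalize_to_fraction <- function(curve, native_baseline = NULL,
                                  denatured_baseline = NULL) {
  stopifnot(inherits(curve, "melting_curve"))
  n <- length(curve$x)
  if (is.null(native_baseline)) native_baseline <- mean(curve$y[1:2])
  if (is.null(denatured_baseline))
    denatured_baseline <- mean(curve$y[(n - 1):n])
  span <- denatured_baseline - native_baseline
  scale <- max(abs(c(native_baseline, denatured_baseline, curve$y)), 1)
  if (abs(span) < 1e-12 * scale)
    stop_validation("native and denatured baselines are indistinguishable")
  f <- (curve$y - native_baseline) / span
  out <- melting_curve(curve$x, f, x_kind = curve$x_kind, y_kind = "fraction",
                       truth = curve$truth)
  attr(out, "out_of_range") <- which(f < 0 | f > 1)
  out
}

sigmoid2 <- function(x, midpoint, width) 1 / (1 + exp((midpoint - x) / width))

#' Fit a two-state sigmoid to a melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the Boltzmann sigmoid
#' \deqn{f(x) = 1 / (1 + e^{(midpoint - x)/width})}
#' to a fraction-unfolded curve; for raw-signal curves
#' (`baselines = TRUE`, the default for non-fraction `y_kind`) the
#' four-parameter form \eqn{y = b_N + (b_D - b_N) f(x)} is fitted.  The
#' midpoint is the x at which the fitted fraction crosses 0.5 (the melting
#' temperature or mid-denaturation concentration).  Curves running in the
#' folding direction (decreasing fraction) are detected and fitted with the
#' mirrored sigmoid; the reported midpoint is unchanged by orientation.
#'
#' @param curve a `melting_curve` (>= 5 points).
#' @param baselines fit native/denatured baselines as free parameters.
#' @return Object of class `sigmoid_fit`: list with `midpoint`, `width`,
#'   their standard errors, optional `baselines`, `rss`, `converged`,
#'   `fitted`, `residuals` and the input `curve`.  Non-convergence is
#'   reported through `converged = FALSE`, not an error.
#' @export
fit_sigmoid <- function(curve, baselines = !identical(curve$y_kind, "fraction")) {
  stopifnot(inherits(curve, "melting_curve"))
  x <- curve$x; y <- curve$y
  if (length(x) < 5L)
    stop_validation("need at least 5 points to fit, got ", length(x))
  falling <- stats::cor(x, y) < 0
  yy <- if (falling) {
    if (baselines) -y else 1 - y
  } else y
  ry <- range(yy)
  if (!baselines && (min(yy) > 0.25 || max(yy) < 0.75))
    warning("curve does not span both baselines; fit may be poorly determined",
            call. = FALSE)
  ## starting values: midpoint at the half-rise crossing, width from the span
  yhalf <- mean(ry)
  mid0 <- x[which.min(abs(yy - yhalf))]
  wid0 <- diff(range(x)) / 10
  df <- data.frame(x = x, yy = yy)
  fit <- tryCatch({
    if (baselines) {
      minpack.lm::nlsLM(
        yy ~ bn + (bd - bn) / (1 + exp((midpoint - x) / width)),
        data = df,
        start = list(midpoint = mid0, width = wid0, bn = ry[1L], bd = ry[2L]),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(yy ~ 1 / (1 + exp((midpoint - x) / width)), data = df,
                        start = list(midpoint = mid0, width = wid0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(midpoint = NA_real_, width = NA_real_, se = c(midpoint = NA,
                width = NA), rss = NA_real_, converged = FALSE,
                diagnostics = conditionMessage(fit), curve = curve)
    class(out) <- "sigmoid_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  fitted_y <- stats::fitted(fit)
  if (falling) fitted_y <- if (baselines) -fitted_y else 1 - fitted_y
  wid <- abs(unname(cf["width"]))
  out <- list(midpoint = unname(cf["midpoint"]), width = wid,
              se = c(midpoint = unname(se["midpoint"]),
                     width = unname(se["width"])),
              baselines = if (baselines) {
                b <- c(native = unname(cf["bn"]), denatured = unname(cf["bd"]))
                if (falling) -b[2:1] else b
              },
              rss = sum((fitted_y - y)^2), converged = TRUE,
              fitted = fitted_y, residuals = y - fitted_y,
              falling = falling, curve = curve)
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sigmoid fit: DID NOT CONVERGE (", x$diagnostics, ")\n")
    return(invisible(x))
  }
  unit <- switch(x$curve$x_kind, temperature = "degC", "M")
  cat(sprintf("Two-state sigmoid fit: midpoint %.3f +/- %.3f %s, width %.3f +/- %.3f %s\n",
              x$midpoint, x$se["midpoint"], unit, x$width, x$se["width"], unit))
  cat(sprintf("  residual sum of squares %.4g over %d points\n", x$rss,
              length(x$curve$x)))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(midpoint = object$midpoint, width = object$width, object$baselines)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x else
    if (is.list(newdata)) newdata$x else newdata
  f <- sigmoid2(x, object$midpoint, object$width)
  if (isTRUE(object$falling)) f <- 1 - f
  if (!is.null(object$baselines))
    f <- object$baselines["native"] +
      (object$baselines["denatured"] - object$baselines["native"]) * f
  unname(f)
}

#' @export
residuals.sigmoid_fit <- function(object, ...) object$residuals

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$curve$x, x$curve$y, pch = 16,
                 xlab = x$curve$x_kind, ylab = x$curve$y_kind, ...)
  xs <- seq(min(x$curve$x), max(x$curve$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2)
  graphics::abline(v = x$midpoint, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a sigmoid-fit report (key-value text or JSON)
#' @param fit a `sigmoid_fit`.
#' @param path output file; extension `.json` selects JSON.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rec <- list(midpoint = fit$midpoint, midpoint_se = unname(fit$se["midpoint"]),
              width = fit$width, width_se = unname(fit$se["width"]),
              rss = fit$rss, converged = fit$converged,
              x_kind = fit$curve$x_kind, n_points = length(fit$curve$x))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(paste0(names(rec), ": ", vapply(rec, format, character(1))),
               path)
  }
  invisible(path)
}

#' Combined chemical-shift perturbation of one residue
#'
#' The weighted-euclidean combination of amide proton and nitrogen shift
#' changes, \eqn{\Delta\delta_{AV} = \sqrt{(\Delta\delta_{1H})^2 +
#' (\Delta\delta_{15N}/5)^2}} (ppm), with the nitrogen change down-weighted
#' by its ~5-fold larger shift range.
#'
#' @param rec_native,rec_perturbed lists/rows with `residue`, `d1H_ppm`,
#'   `d15N_ppm`.
#' @return Delta-delta_AV in ppm (non-negative).
#' @export
csp <- function(rec_native, rec_perturbed) {
  if (rec_native$residue != rec_perturbed$residue)
    stop_validation("residue mismatch: ", rec_native$residue, " vs ",
                    rec_perturbed$residue)
  d1h <- rec_perturbed$d1H_ppm - rec_native$d1H_ppm
  d15n <- rec_perturbed$d15N_ppm - rec_native$d15N_ppm
  sqrt(d1h^2 + (d15n / 5)^2)
}

#' Per-residue chemical-shift-perturbation profile
#'
#' Matches the two shift tables on residue index (the intersection is used;
#' unmatched residues are reported in the `unmatched` attribute), computes
#' [csp()] per residue and flags residues whose perturbation exceeds
#' mean + k * sd.
#'
#' @param native_table,perturbed_table data frames with columns `residue`,
#'   `d1H_ppm`, `d15N_ppm`.
#' @param k outlier threshold in standard deviations above the mean
#'   (default 1).
#' @return Data frame with `residue`, `csp_ppm`, `flagged`; attributes
#'   `threshold` and `unmatched`.
#' @export
csp_profile <- function(native_table, perturbed_table, k = 1) {
  common <- intersect(native_table$residue, perturbed_table$residue)
  if (!length(common)) stop_validation("no residues in common")
  a <- native_table[match(common, native_table$residue), ]
  b <- perturbed_table[match(common, perturbed_table$residue), ]
  v <- sqrt((b$d1H_ppm - a$d1H_ppm)^2 + ((b$d15N_ppm - a$d15N_ppm) / 5)^2)
  thr <- mean(v) + k * stats::sd(v)
  out <- data.frame(residue = common, csp_ppm = v,
                    flagged = stats::sd(v) > 0 & v > thr)
  attr(out, "threshold") <- thr
  attr(out, "unmatched") <- list(
    native_only = setdiff(native_table$residue, common),
    perturbed_only = setdiff(perturbed_table$residue, common))
  out
}

#' Read/write chemical-shift tables (CSV: residue, d1H_ppm, d15N_ppm)
#' @param table data frame with `residue`, `d1H_ppm`, `d15N_ppm`.
#' @param path CSV file.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_shift_table <- function(table, path) {
  utils::write.csv(table[, c("residue", "d1H_ppm", "d15N_ppm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) utils::read.csv(path)
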