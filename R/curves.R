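#' Circadian curve templates
#'
#' The template catalogue used both for fitting and for simulation. Seven
#' shapes are fitting templates; \code{cosine_outlier} (a cosine whose series
#' receives one deliberately displaced sample) exists only for simulation,
#' since an outlier is a property of a realised series, not of a curve.
#'
#' All shapes share three parameters: amplitude \code{A} (>= 0, expression
#' units), period \code{T} (hours) and phase \code{phi} (hours, the horizontal
#' offset of the template argument -- for the plain cosine this coincides with
#' peak time, for other shapes it need not). Writing
#' \eqn{\theta = 2\pi(t - \phi)/T} and \eqn{c = \cos\theta}, the forms are:
#'
#' \itemize{
#'   \item \code{cosine}: \eqn{A c}
#'   \item \code{squared_cosine}: \eqn{A\,\mathrm{sign}(c)\,c^2} -- the
#'     sign-preserving square keeps the fundamental period \code{T} and the
#'     amplitude \code{A} while sharpening the extrema.
#'   \item \code{triangular}: \eqn{A (2/\pi) \arcsin(c)}, the triangle wave
#'     peaking at \eqn{\pm A}.
#'   \item \code{dampened_cosine}: \eqn{A e^{-\lambda (t - t_0)} c} with decay
#'     rate \code{lambda} (1/h) anchored at the first sampled time \eqn{t_0}.
#'   \item \code{cosine_linear}: \eqn{A c + b (t - t_0)} with slope \code{b}
#'     (units/h).
#'   \item \code{cosine_exponential}: \eqn{A c + c_e e^{-k (t - t_0)}} with
#'     coefficient \code{exp_coeff} (units) and rate \code{exp_rate} (1/h).
#'   \item \code{peak}: a periodic Gaussian pulse train,
#'     \eqn{A \sum_n \exp(-(t - \phi - nT)^2 / (2\sigma^2))} with pulse width
#'     \code{peak_width} = \eqn{\sigma} (hours), \eqn{n} covering the window.
#'   \item \code{cosine_outlier} (simulation only): evaluates as \code{cosine};
#'     the outlier is injected by the simulator into one sample of the series.
#' }
#'
#' Anchoring trend/damping terms at \eqn{t_0 = \min(t)} makes fits invariant
#' to translating the time axis.
#'
#' @name curve-templates
NULL

.CURVE_SHAPES <- c("cosine", "squared_cosine", "triangular", "dampened_cosine",
                   "cosine_linear", "cosine_exponential", "peak",
                   "cosine_outlier")

.FITTING_SHAPES <- setdiff(.CURVE_SHAPES, "cosine_outlier")

.CURVE_EXTRAS <- list(
  cosine             = character(0),
  squared_cosine     = character(0),
  triangular         = character(0),
  dampened_cosine    = "lambda",
  cosine_linear      = "slope",
  cosine_exponential = c("exp_coeff", "exp_rate"),
  peak               = "peak_width",
  cosine_outlier     = character(0)
)

#' All curve shape names
#' @param fitting if TRUE, only the shapes that can be fitted (excludes the
#'   simulation-only \code{cosine_outlier}).
#' @return character vector of shape names.
#' @export
curve_shapes <- function(fitting = FALSE) {
  if (fitting) .FITTING_SHAPES else .CURVE_SHAPES
}

.check_shape <- function(shape) {
  if (length(shape) != 1L || !is.character(shape) || !shape %in% .CURVE_SHAPES)
    stop("unknown curve shape: ", paste(shape, collapse = ", "), call. = FALSE)
  shape
}

#' Ordered parameter names of a fitting shape
#'
#' Always starts with \code{c("amplitude", "period", "phase")}; shape-specific
#' extras follow in a fixed order (\code{lambda}, \code{slope},
#' \code{exp_coeff}, \code{exp_rate}, \code{peak_width} as applicable).
#'
#' @param shape a fitting shape name.
#' @return character vector of parameter names.
#' @export
curve_parameter_names <- function(shape) {
  .check_shape(shape)
  if (shape == "cosine_outlier")
    stop("cosine_outlier is simulation-only and cannot be fitted", call. = FALSE)
  c("amplitude", "period", "phase", .CURVE_EXTRAS[[shape]])
}

#' Construct a curve specification
#'
#' @param shape one of \code{curve_shapes()}.
#' @param amplitude amplitude A >= 0 (expression units).
#' @param period period T > 0 (hours).
#' @param phase phase phi (hours).
#' @param ... shape-specific extras (\code{lambda}, \code{slope},
#'   \code{exp_coeff}, \code{exp_rate}, \code{peak_width}).
#' @return an object of class \code{curve_spec}.
#' @examples
#' spec <- curve_spec("cosine", amplitude = 1, period = 24, phase = 0)
#' evaluate_curve(spec, c(0, 6, 12))
#' @export
curve_spec <- function(shape, amplitude, period = 24, phase = 0, ...) {
  .check_shape(shape)
  extras <- list(...)
  pars <- c(list(amplitude = amplitude, period = period, phase = phase), extras)
  bad <- !vapply(pars, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad))
    stop("non-finite or non-scalar curve parameter(s): ",
         paste(names(pars)[bad], collapse = ", "), call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  need <- .CURVE_EXTRAS[[shape]]
  if (!setequal(names(extras), need))
    stop("shape '", shape, "' needs extras {", paste(need, collapse = ", "),
         "}, got {", paste(names(extras), collapse = ", "), "}", call. = FALSE)
  if ("peak_width" %in% names(extras) && extras$peak_width <= 0)
    stop("peak_width must be > 0", call. = FALSE)
  structure(list(shape = shape, amplitude = amplitude, period = period,
                 phase = phase, extras = extras),
            class = "curve_spec")
}

#' @export
print.curve_spec <- function(x, ...) {
  ex <- if (length(x$extras))
    paste0(", ", paste(names(x$extras), unlist(x$extras), sep = "=", collapse = ", "))
  else ""
  cat(sprintf("<curve_spec %s: A=%g, T=%g h, phi=%g h%s>\n",
              x$shape, x$amplitude, x$period, x$phase, ex))
  invisible(x)
}

# Fast evaluation path addressed by shape name and a named parameter vector,
# shared by the fitter (called thousands of times) and evaluate_curve().
# t0 anchors trend/damping terms at the first sampled time.
.eval_curve <- function(shape, par, t, t0 = min(t)) {
  A <- par[["amplitude"]]; Tt <- par[["period"]]; phi <- par[["phase"]]
  th <- 2 * pi * (t - phi) / Tt
  co <- cos(th)
  switch(shape,
    cosine         = A * co,
    cosine_outlier = A * co,
    squared_cosine = A * sign(co) * co^2,
    triangular     = A * (2 / pi) * asin(co),
    dampened_cosine = A * exp(-par[["lambda"]] * (t - t0)) * co,
    cosine_linear  = A * co + par[["slope"]] * (t - t0),
    cosine_exponential = A * co +
      par[["exp_coeff"]] * exp(-par[["exp_rate"]] * (t - t0)),
    peak = {
      sig <- par[["peak_width"]]
      # pulse train over all cycle indices reaching the sampled window;
      # +/- 1 cycle of margin so tails of adjacent pulses are included
      nlo <- floor((min(t) - phi) / Tt) - 1L
      nhi <- ceiling((max(t) - phi) / Tt) + 1L
      out <- numeric(length(t))
      for (n in nlo:nhi)
        out <- out + exp(-((t - phi - n * Tt)^2) / (2 * sig^2))
      A * out
    },
    stop("unknown curve shape: ", shape, call. = FALSE)
  )
}

#' Evaluate a curve template at given times
#'
#' @param spec a \code{\link{curve_spec}}.
#' @param t numeric vector of times (hours).
#' @param t0 time origin anchoring trend/damping terms; defaults to
#'   \code{min(t)} so fits are invariant under time translation.
#' @return numeric vector of template values at \code{t}.
#' @export
evaluate_curve <- function(spec, t, t0 = min(t)) {
  if (!inherits(spec, "curve_spec")) stop("spec must be a curve_spec", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t))) stop("t must be finite numeric", call. = FALSE)
  par <- c(amplitude = spec$amplitude, period = spec$period, phase = spec$phase,
           unlist(spec$extras))
  .eval_curve(spec$shape, as.list(par), t, t0 = t0)
}
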