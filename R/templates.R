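# Visual pigment absorbance templates.
#
# Vertebrate visual pigment absorbance spectra are well described by a
# closed-form template parameterized only by the wavelength of maximum
# absorbance (lambda-max) and the chromophore: A1 (retinal, rhodopsin-type
# pigments) or A2 (3,4-didehydroretinal, porphyropsin-type pigments, which
# are red-shifted and spectrally broader). The template is the sum of a main
# alpha band -- a reciprocal sum of exponentials in the normalized variable
# x = lambda_max / lambda -- and a Gaussian beta band (the cis absorption
# peak in the near UV). All numeric constants are shipped as a plain-text
# table (see `govardovskii_constants()`), so corrections are data edits.

# lambda-max validity range enforced for both template families; covers every
# amphibian photoreceptor class handled here. Outside it we error rather than
# extrapolate.
.LAMBDA_MAX_RANGE <- c(350, 650)
.WAVELENGTH_RANGE <- c(300, 800)

#' Visual pigment template constants
#'
#' Reads the packaged table of template constants (alpha-band reciprocal
#' sum-of-exponentials parameters and Gaussian beta-band parameters for the
#' A1 and A2 chromophores), transcribed from Govardovskii et al. (2000).
#'
#' @return A data frame with columns `chromophore`, `band`, `parameter`,
#'   `value`.
#' @references Govardovskii VI, Fyhrquist N, Reuter T, Kuzmin DG, Donner K
#'   (2000). In search of the visual pigment template. Visual Neuroscience
#'   17:509-528.
#' @export
govardovskii_constants <- function() {
  if (is.null(.visadapt_cache$gov_constants)) {
    tab <- utils::read.delim(extdata_path("govardovskii_constants.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    .visadapt_cache$gov_constants <- tab
  }
  .visadapt_cache$gov_constants
}

.template_params <- function(chromophore) {
  key <- paste0("par_", chromophore)
  if (is.null(.visadapt_cache[[key]])) {
    tab <- govardovskii_constants()
    tab <- tab[tab$chromophore == chromophore, ]
    out <- list(
      alpha = stats::setNames(tab$value[tab$band == "alpha"],
                              tab$parameter[tab$band == "alpha"]),
      beta  = stats::setNames(tab$value[tab$band == "beta"],
                              tab$parameter[tab$band == "beta"])
    )
    .visadapt_cache[[key]] <- out
  }
  .visadapt_cache[[key]]
}

#' Construct a visual pigment template specification
#'
#' @param chromophore `"A1"` or `"A2"`.
#' @param lambda_max Wavelength of maximum absorbance in nm; must lie in
#'   350--650 nm.
#' @param include_beta_band Include the Gaussian beta band (default `TRUE`)?
#'   Fits restricted to the long-wavelength limb never touch the beta band,
#'   so it can be switched off.
#' @return An object of class `"template_spec"`.
#' @export
template_spec <- function(chromophore = c("A1", "A2"), lambda_max,
                          include_beta_band = TRUE) {
  chromophore <- match.arg(chromophore)
  stopifnot_scalar_number(lambda_max, "lambda_max",
                          .LAMBDA_MAX_RANGE[1], .LAMBDA_MAX_RANGE[2])
  structure(
    list(chromophore = chromophore,
         lambda_max = as.numeric(lambda_max),
         include_beta_band = isTRUE(include_beta_band)),
    class = "template_spec"
  )
}

#' @export
print.template_spec <- function(x, ...) {
  cat(sprintf("Visual pigment template: %s, lambda-max %.1f nm (beta band %s)\n",
              x$chromophore, x$lambda_max,
              if (x$include_beta_band) "on" else "off"))
  invisible(x)
}

# Raw (un-normalized) template value; wl and the returned vector are
# numeric vectors. Peak is ~1 by construction but not exactly 1, hence the
# renormalization layer below.
.template_raw <- function(chromophore, lambda_max, wl, include_beta_band) {
  p <- .template_params(chromophore)
  a <- p$alpha
  x <- lambda_max / wl
  if (chromophore == "A1") {
    av <- a[["a0"]] + a[["a_amp"]] *
      exp(-(lambda_max - a[["a_mu"]])^2 / a[["a_denom"]])
    Av <- a[["A"]]
  } else {
    av <- a[["a0"]] + a[["a_amp"]] *
      exp((lambda_max - a[["a_mu"]]) / a[["a_scale"]])
    Av <- a[["A0"]] + a[["A_amp"]] *
      exp((lambda_max - a[["A_mu"]]) / a[["A_scale"]])
  }
  s <- 1 / (exp(Av * (av - x)) + exp(a[["B"]] * (a[["b"]] - x)) +
              exp(a[["C"]] * (a[["cc"]] - x)) + a[["D"]])
  if (include_beta_band) {
    b <- p$beta
    mu <- b[["mu0"]] + b[["mu_slope"]] * lambda_max
    bw <- b[["bw0"]] + b[["bw_slope"]] * lambda_max
    if (chromophore == "A2") bw <- bw + b[["bw_quad"]] * lambda_max^2
    s <- s + b[["amp"]] * exp(-((wl - mu) / bw)^2)
  }
  s
}

# Peak wavelength and normalization scale of the raw template, cached per
# (chromophore, lambda_max, beta) since fitting revisits the same candidates.
.template_peak <- function(chromophore, lambda_max, include_beta_band) {
  key <- sprintf("pk_%s_%.6f_%d", chromophore, lambda_max,
                 as.integer(include_beta_band))
  hit <- .visadapt_cache[[key]]
  if (!is.null(hit)) return(hit)
  opt <- stats::optimize(
    function(w) .template_raw(chromophore, lambda_max, w, include_beta_band),
    interval = c(lambda_max - 15, lambda_max + 12),
    maximum = TRUE, tol = 1e-8
  )
  out <- c(peak_wl = opt$maximum, scale = opt$objective)
  .visadapt_cache[[key]] <- out
  out
}

.check_wavelengths <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 1L ||
      anyNA(wavelengths)) {
    stop("'wavelengths' must be a numeric vector without NAs", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("'wavelengths' must be strictly ascending", call. = FALSE)
  }
  if (min(wavelengths) < .WAVELENGTH_RANGE[1] ||
      max(wavelengths) > .WAVELENGTH_RANGE[2]) {
    stop("template evaluation is defined for wavelengths in 300-800 nm",
         call. = FALSE)
  }
  invisible(wavelengths)
}

#' Evaluate a visual pigment absorbance template
#'
#' Computes peak-normalized relative absorbance of an A1 or A2 visual pigment
#' template at the given wavelengths. After summing the alpha and beta bands
#' the curve is rescaled so its global maximum is exactly 1.
#'
#' @param spec A [template_spec()].
#' @param wavelengths Strictly ascending wavelengths in nm (300--800).
#' @return Numeric vector of relative absorbances in `[0, 1]`.
#' @examples
#' spec <- template_spec("A1", 505)
#' evaluate_template(spec, 350:750)
#' @export
evaluate_template <- function(spec, wavelengths) {
  stopifnot(inherits(spec, "template_spec"))
  .check_wavelengths(wavelengths)
  pk <- .template_peak(spec$chromophore, spec$lambda_max,
                       spec$include_beta_band)
  .template_raw(spec$chromophore, spec$lambda_max, wavelengths,
                spec$include_beta_band) / pk[["scale"]]
}

# Normalized template as a function of wavelength (scalar or vector), used by
# the FWHM and mixture machinery.
.template_fun <- function(spec) {
  pk <- .template_peak(spec$chromophore, spec$lambda_max,
                       spec$include_beta_band)
  force(spec)
  function(w) {
    .template_raw(spec$chromophore, spec$lambda_max, w,
                  spec$include_beta_band) / pk[["scale"]]
  }
}

# Walk outward from the peak in `step`-nm increments until the curve drops
# below `level`, then polish the crossing by bisection (uniroot). Picks the
# crossing nearest the peak, which is the half-maximum relevant for FWHM even
# when the beta band re-crosses the level further out.
.crossing <- function(f, peak_wl, level, direction, step = 0.5, tol = 1e-3) {
  lim <- if (direction > 0) .WAVELENGTH_RANGE[2] else .WAVELENGTH_RANGE[1]
  w0 <- peak_wl
  repeat {
    w1 <- w0 + direction * step
    if ((direction > 0 && w1 > lim) || (direction < 0 && w1 < lim)) {
      stop("half-maximum crossing not bracketed within 300-800 nm",
           call. = FALSE)
    }
    if (f(w1) < level) break
    w0 <- w1
  }
  interval <- sort(c(w0, w1))
  stats::uniroot(function(w) f(w) - level, interval, tol = tol)$root
}

#' Full width at half maximum of a template
#'
#' Width of the peak-normalized template at relative absorbance 0.5, found by
#' bisection on each limb. A2 templates are broader than A1 templates at
#' matched lambda-max.
#'
#' @param spec A [template_spec()].
#' @return FWHM in nm.
#' @export
template_fwhm <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  f <- .template_fun(spec)
  pk <- .template_peak(spec$chromophore, spec$lambda_max,
                       spec$include_beta_band)
  right <- .crossing(f, pk[["peak_wl"]], 0.5, +1)
  left <- .crossing(f, pk[["peak_wl"]], 0.5, -1)
  right - left
}

#' Convex mixture of two pigment templates
#'
#' Models a photoreceptor containing both A1- and A2-based pigment built on
#' the same opsin: a convex combination of the two peak-normalized pure
#' templates, renormalized to peak 1. As `fraction_a2` rises from 0 to 1 the
#' apparent peak moves monotonically from the A1 peak to the A2 peak.
#'
#' @param spec_a1,spec_a2 [template_spec()] objects for the two components
#'   (chromophores `"A1"` and `"A2"` respectively).
#' @param fraction_a2 Proportion of A2 pigment, in `[0, 1]`.
#' @param wavelengths Strictly ascending wavelengths in nm.
#' @return Numeric vector of relative absorbances, peak-normalized to 1.
#' @export
mixture_template <- function(spec_a1, spec_a2, fraction_a2, wavelengths) {
  stopifnot(inherits(spec_a1, "template_spec"),
            inherits(spec_a2, "template_spec"))
  if (spec_a1$chromophore != "A1" || spec_a2$chromophore != "A2") {
    stop("'spec_a1' must be an A1 template and 'spec_a2' an A2 template",
         call. = FALSE)
  }
  stopifnot_scalar_number(fraction_a2, "fraction_a2", 0, 1)
  .check_wavelengths(wavelengths)
  f1 <- .template_fun(spec_a1)
  f2 <- .template_fun(spec_a2)
  mix <- function(w) (1 - fraction_a2) * f1(w) + fraction_a2 * f2(w)
  lo <- min(spec_a1$lambda_max, spec_a2$lambda_max) - 15
  hi <- max(spec_a1$lambda_max, spec_a2$lambda_max) + 12
  scale <- stats::optimize(mix, c(lo, hi), maximum = TRUE, tol = 1e-8)$objective
  mix(wavelengths) / scale
}
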