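# Region-level parameters of the four-population neural mass model.
#
# One region (ROI) contains pyramidal cells (p), excitatory interneurons (e),
# and slow and fast GABAergic interneurons (s, f). Every synaptic pathway is a
# second-order linear filter h(t) = G * w * t * exp(-w * t) whose gain G (mV)
# and reciprocal time constant w (1/s) depend only on the transmitter class:
# glutamatergic (Ge, we), slow GABA (Gs, ws), fast GABA (Gf, wf). Membrane
# potential is converted to population spike density by a logistic sigmoid.
# Eight dimensionless coupling constants C_ij (first index postsynaptic)
# wire the populations: p<-e, p<-s, p<-f, e<-p, s<-p, f<-p, f<-s, f<-f.

#' Sigmoidal potential-to-rate conversion
#'
#' Converts an average membrane potential into an average population firing
#' rate with a logistic saturation: \code{z(v) = 2*e0 / (1 + exp(r*(v0 - v)))}.
#' The lower asymptote is 0, the upper asymptote \code{2*e0}, and the value at
#' the centre \code{v0} is \code{e0} (the midpoint of the asymptotes).
#'
#' @param v membrane potential (mV); any numeric vector.
#' @param e0 half-maximum firing rate (Hz); upper saturation is \code{2*e0}.
#' @param r sigmoid slope (1/mV), must be positive.
#' @param v0 centre of the sigmoid (mV).
#' @return firing rate (Hz), same shape as \code{v}, in \code{(0, 2*e0)}.
#' @examples
#' sigmoid_rate(6, e0 = 2.5, r = 0.56, v0 = 6) # == 2.5, the midpoint
#' @export
sigmoid_rate <- function(v, e0 = 2.5, r = 0.56, v0 = 6) {
  if (!all(is.finite(v))) stop("non-finite membrane potential")
  stopifnot(e0 > 0, r > 0)
  2 * e0 / (1 + exp(r * (v0 - v)))
}

#' One Euler step of a second-order synaptic filter
#'
#' Advances the postsynaptic potential \code{y} and its derivative \code{dy}
#' of a synaptic channel with impulse response
#' \code{h(t) = gain * rate * t * exp(-rate * t)} by one step of length
#' \code{dt}, driven by the presynaptic spike density \code{z_in}:
#' \code{dy' = gain*rate*z_in - 2*rate*dy - rate^2*y}. For a constant input
#' the filter settles at \code{y = gain * z_in / rate}.
#'
#' @param y postsynaptic potential (mV).
#' @param dy its time derivative (mV/s).
#' @param z_in presynaptic spike density (Hz).
#' @param gain synaptic gain (mV).
#' @param rate reciprocal time constant (1/s), positive.
#' @param dt integration step (s), positive.
#' @return numeric vector \code{c(y, dy)} after one step.
#' @export
synapse_step <- function(y, dy, z_in, gain, rate, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (rate <= 0) stop("rate must be positive")
  ddy <- gain * rate * z_in - 2 * rate * dy - rate^2 * y
  c(y + dt * dy, dy + dt * ddy)
}

#' Parameters of one neural mass region
#'
#' Bundles the synaptic channel constants, internal couplings, sigmoid and
#' external inputs of a single four-population region. Defaults are the
#' package's calibrated values common to all rhythm presets; use
#' \code{\link{roi_preset}} for the band-specific sets.
#'
#' @param name label of the region (by convention its intrinsic band).
#' @param Ge,we glutamatergic gain (mV) and reciprocal time constant (1/s).
#' @param Gs,ws slow GABAergic gain and reciprocal time constant.
#' @param Gf,wf fast GABAergic gain and reciprocal time constant.
#' @param e0,r,v0 sigmoid parameters, see \code{\link{sigmoid_rate}}.
#' @param C named numeric vector of the eight internal couplings
#'   \code{pe, ps, pf, ep, sp, fp, fs, ff} (postsynaptic index first).
#' @param Ip external input to the pyramidal population.
#' @param If external input to the fast interneurons (0 in all experiments).
#' @return an object of class \code{roi_params}.
#' @export
roi_params <- function(name = "roi",
                       Ge = 5.17, we = 75,
                       Gs = 4.45, ws = 30,
                       Gf = 57.1, wf = 300,
                       e0 = 2.5, r = 0.56, v0 = 6,
                       C = c(pe = 35, ps = 40, pf = 10, ep = 35,
                             sp = 35, fp = 10, fs = 10, ff = 0),
                       Ip = 400, If = 0) {
  need <- c("pe", "ps", "pf", "ep", "sp", "fp", "fs", "ff")
  if (!all(need %in% names(C))) {
    stop("C must name all eight couplings: ", paste(need, collapse = ", "))
  }
  C <- C[need]
  stopifnot(all(C >= 0), Ge > 0, Gs > 0, Gf > 0,
            we > 0, ws > 0, wf > 0, e0 > 0, r > 0)
  if (If != 0) stop("If is kept at 0 in every region")
  structure(list(name = name, Ge = Ge, we = we, Gs = Gs, ws = ws,
                 Gf = Gf, wf = wf, e0 = e0, r = r, v0 = v0,
                 C = C, Ip = Ip, If = If),
            class = "roi_params")
}

#' @export
print.roi_params <- function(x, ...) {
  cat(sprintf("<roi_params '%s'>  Ge/we %.2f/%.0f  Gs/ws %.2f/%.0f  Gf/wf %.2f/%.0f\n",
              x$name, x$Ge, x$we, x$Gs, x$ws, x$Gf, x$wf))
  cat("  C:", paste(sprintf("%s=%g", names(x$C), x$C), collapse = " "), "\n")
  cat(sprintf("  sigmoid e0=%g r=%g v0=%g   Ip=%g If=%g\n",
              x$e0, x$r, x$v0, x$Ip, x$If))
  invisible(x)
}

# Calibrated per-band parameter sets (version 1). Each isolated region,
# driven at the operating input Ip = 400, oscillates inside its nominal band:
# theta 4-8, alpha 8-13, beta 13-26, gamma 26-40 Hz. The theta and alpha
# regions oscillate through the pyramidal <-> slow-GABA loop (ws sets the
# frequency), beta and gamma through the pyramidal <-> fast-GABA loop.
.roi_preset_table <- list(
  theta = list(ws = 25,
               C = c(pe = 15, ps = 53, pf = 10, ep = 15,
                     sp = 35, fp = 10, fs = 10, ff = 0)),
  alpha = list(ws = 50,
               C = c(pe = 15, ps = 73, pf = 10, ep = 15,
                     sp = 35, fp = 10, fs = 10, ff = 0)),
  beta  = list(ws = 30, wf = 200, Gf = 40,
               C = c(pe = 15, ps = 8, pf = 42, ep = 15,
                     sp = 35, fp = 35, fs = 0, ff = 0)),
  gamma = list(we = 120, ws = 30, wf = 300, r = 0.7,
               C = c(pe = 15, ps = 0, pf = 27, ep = 15,
                     sp = 35, fp = 56, fs = 0, ff = 0))
)

#' Built-in rhythm-specific region presets
#'
#' Returns the calibrated parameter set of one of the four rhythm-specific
#' regions. The presets are versioned with the package; see the methods
#' vignette for the calibration procedure.
#'
#' @param band one of \code{"theta"}, \code{"alpha"}, \code{"beta"},
#'   \code{"gamma"}.
#' @param Ip external input to the pyramidal population (default 400, the
#'   operating input of the random-network benchmark).
#' @return an object of class \code{roi_params}.
#' @examples
#' roi_preset("alpha")
#' @export
roi_preset <- function(band = c("theta", "alpha", "beta", "gamma"), Ip = 400) {
  band <- match.arg(band)
  do.call(roi_params, c(list(name = band, Ip = Ip),
                        .roi_preset_table[[band]]))
}

#' The four standard regions
#'
#' Convenience list of the four rhythm presets in canonical order
#' (theta, alpha, beta, gamma).
#'
#' @param Ip external input applied to every region (default 400).
#' @return named list of four \code{roi_params}.
#' @export
standard_rois <- function(Ip = 400) {
  bands <- c("theta", "alpha", "beta", "gamma")
  setNames(lapply(bands, roi_preset, Ip = Ip), bands)
}

#' Nominal frequency bands of the four rhythms
#'
#' @return named list of c(lo, hi) band edges in Hz.
#' @export
rhythm_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 26), gamma = c(26, 40))
}
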