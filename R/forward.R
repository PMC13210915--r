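#' Add Gaussian measurement noise at an exact signal-to-noise ratio
#'
#' The noise vector is drawn from a zero-mean Gaussian and then rescaled so
#' that the realized ratio satisfies `SNR = 10 log10(RMS(V) / RMS(N))`
#' exactly (an amplitude-ratio convention with factor 10).  The conventional
#' power reading `SNR = 20 log10(RMS(V) / RMS(N))` is available through
#' `convention = "power"`.
#'
#' @param v voltage vector.
#' @param snr_db requested SNR in dB; `Inf` returns `v` unchanged.
#' @param seed seed for the noise draw (reproducible).
#' @param convention `"amplitude10"` (factor 10 on the RMS ratio, the
#'   default) or `"power"` (factor 20).
#' @return noisy voltage vector with attributes `snr_db` and `noise`.
#' @export
add_noise <- function(v, snr_db, seed = 1L,
                      convention = c("amplitude10", "power")) {
  convention <- match.arg(convention)
  if (is.infinite(snr_db)) return(v)
  rms <- function(x) sqrt(mean(x^2))
  .with_seed(seed, {
    n0 <- rnorm(length(v))
    fac <- if (convention == "amplitude10") 10^(snr_db / 10) else 10^(snr_db / 20)
    n <- n0 * (rms(v) / fac) / rms(n0)
    out <- v + n
    attr(out, "snr_db") <- snr_db
    attr(out, "noise") <- n
    out
  })
}

#' Cyclic noise schedule over the dataset
#'
#' Training samples alternate between no noise and SNR = 30, 45, 55 dB by
#' sample index (0-based), period 4.
#'
#' @param index integer vector of 0-based sample indices.
#' @return character vector with values `"clean"`, `"30"`, `"45"`, `"55"`.
#' @export
noise_schedule <- function(index) {
  if (any(index < 0)) stop("index must be >= 0")
  c("clean", "30", "45", "55")[(index %% 4) + 1]
}

#' Numeric SNR for a schedule tag
#' @param tag character tag from [noise_schedule()].
#' @return numeric SNR in dB (`Inf` for `"clean"`).
#' @export
snr_of_tag <- function(tag) {
  out <- suppressWarnings(as.numeric(tag))
  out[tag == "clean"] <- Inf
  out
}
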