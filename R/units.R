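## Unit conversions. Internal working units are atomic units throughout
## (hartree, bohr, electron mass, a.u. of time); user-facing interfaces are
## eV, fs, cm^-1 and amu, matching how the observables are reported.

#' Physical constants and unit conversions
#'
#' Fixed conversion factors used throughout the package. All dynamics run in
#' atomic units internally; interfaces report eV, fs, cm\eqn{^{-1}} and amu.
#'
#' @format A named list with elements
#' \describe{
#'   \item{ev_per_hartree}{27.211386 eV / hartree}
#'   \item{cm_per_ev}{8065.544 cm\eqn{^{-1}} / eV}
#'   \item{au_per_fs}{41.34137 a.u. of time / fs}
#'   \item{me_per_amu}{1822.888 electron masses / amu}
#'   \item{period_const}{33356.41; period T[fs] = period_const / wavenumber[cm\eqn{^{-1}}]}
#'   \item{cm_per_hartree}{cm\eqn{^{-1}} per hartree (product of the first two)}
#' }
#' @export
hopta_constants <- list(
  ev_per_hartree = 27.211386,
  cm_per_ev      = 8065.544,
  au_per_fs      = 41.34137,
  me_per_amu     = 1822.888,
  period_const   = 33356.41,
  cm_per_hartree = 27.211386 * 8065.544
)

## internal shorthands
.EV    <- hopta_constants$ev_per_hartree
.CMEV  <- hopta_constants$cm_per_ev
.AUFS  <- hopta_constants$au_per_fs
.MEAMU <- hopta_constants$me_per_amu
.CMHA  <- hopta_constants$cm_per_hartree

ev_to_hartree <- function(e) e / .EV
hartree_to_ev <- function(e) e * .EV
fs_to_au <- function(t) t * .AUFS
au_to_fs <- function(t) t / .AUFS
amu_to_me <- function(m) m * .MEAMU
cm_to_au_freq <- function(nu) nu / .CMHA     # wavenumber -> angular freq (a.u.)
au_freq_to_cm <- function(w) w * .CMHA

#' Convert a vibrational wavenumber to an oscillation period
#'
#' \eqn{T[\mathrm{fs}] = 33356.41 / \tilde\nu[\mathrm{cm}^{-1}]}. A 600
#' cm\eqn{^{-1}} mode has a period of about 55.6 fs; 750 cm\eqn{^{-1}}
#' corresponds to about 44.5 fs.
#'
#' @param wavenumber_cm wavenumber(s) in cm\eqn{^{-1}}; must be positive.
#' @return period(s) in femtoseconds.
#' @examples
#' wavenumber_to_period(600)   # ~55.6 fs
#' wavenumber_to_period(750)   # ~44.5 fs
#' @export
wavenumber_to_period <- function(wavenumber_cm) {
  if (any(!is.finite(wavenumber_cm)) || any(wavenumber_cm <= 0)) {
    stop("wavenumber must be positive and finite")
  }
  hopta_constants$period_const / wavenumber_cm
}
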