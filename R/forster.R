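#' Spectral overlap integral
#'
#' J = integral of f_D(lambda) * eps_A(lambda) * lambda^4 d lambda, with the
#' donor emission density f_D unit-area in 1/nm and the acceptor extinction
#' eps_A in M^-1 cm^-1, giving J in M^-1 cm^-1 nm^4. Trapezoidal integration
#' over the records' common working grid. Disjoint spectral support yields 0.
#'
#' @param donor,acceptor `fluorophore` records on the same grid.
#' @return J (M^-1 cm^-1 nm^4).
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"))
  if (!isTRUE(all.equal(donor$wavelengths, acceptor$wavelengths)))
    stop("donor and acceptor must be resampled to a common grid")
  wl <- donor$wavelengths
  trapz_int(wl, donor$emission_shape * acceptor$extinction * wl^4)
}

# Lakowicz constant for R0 in nm with J in M^-1 cm^-1 nm^4:
# R0[A] = 0.211 (kappa2 n^-4 Q J)^(1/6)  ->  0.0211 nm, refined to 0.02108
FORSTER_CONST_NM <- 0.02108

#' Forster radius
#'
#' R0 = 0.02108 * (kappa2 * n^-4 * Q_D * J)^(1/6) nm, with J in
#' M^-1 cm^-1 nm^4. R0 is the donor-acceptor distance at which transfer
#' efficiency is 1/2 for a 1:1 pair.
#'
#' @param J Overlap integral (M^-1 cm^-1 nm^4), non-negative.
#' @param Q_D Donor quantum yield in \[0, 1\].
#' @param kappa2 Orientation factor, default 2/3 (isotropic average).
#' @param n Refractive index of the medium, default 1.4.
#' @return R0 in nm.
#' @export
forster_radius <- function(J, Q_D, kappa2 = 2 / 3, n = 1.4) {
  if (J < 0 || Q_D < 0 || Q_D > 1) stop("J must be >= 0 and Q_D in [0, 1]")
  if (kappa2 <= 0 || kappa2 > 4) stop("kappa2 must be in (0, 4]")
  if (n < 1) stop("refractive index must be >= 1")
  FORSTER_CONST_NM * (kappa2 * n^-4 * Q_D * J)^(1 / 6)
}

#' Construct a FRET pair
#'
#' Resamples both fluorophores onto the common working grid, computes the
#' overlap integral and Forster radius.
#'
#' @inheritParams overlap_integral
#' @inheritParams forster_radius
#' @return A `fret_pair` with `donor`, `acceptor`, `kappa2`,
#'   `refractive_index`, `overlap` (J) and `forster_radius` (R0, nm).
#' @export
fret_pair <- function(donor, acceptor, kappa2 = 2 / 3, n = 1.4) {
  g <- working_grid()
  d <- resample(donor, g)
  a <- resample(acceptor, g)
  J <- overlap_integral(d, a)
  structure(
    list(donor = d, acceptor = a, kappa2 = kappa2, refractive_index = n,
         overlap = J,
         forster_radius = forster_radius(J, d$quantum_yield, kappa2, n)),
    class = "fret_pair"
  )
}

#' @export
print.fret_pair <- function(x, ...) {
  cat(sprintf(
    "<fret_pair> %s -> %s  J = %.4g M^-1 cm^-1 nm^4  R0 = %.2f nm (r10%% = %.1f nm)\n",
    x$donor$name, x$acceptor$name, x$overlap, x$forster_radius,
    distance_at_efficiency(0.1, x$forster_radius)))
  invisible(x)
}

#' FRET efficiency at a given distance
#'
#' For a donor with N equidistant, identical acceptors,
#' E = N (R0/r)^6 / (1 + N (R0/r)^6). With N = 1, E(R0) = 1/2 by the
#' definition of the Forster radius.
#'
#' @param r Donor-acceptor distance (nm), positive.
#' @param R0 Forster radius (nm), non-negative.
#' @param N Acceptors per donor (positive integer), default 1.
#' @return E in \[0, 1).
#' @export
fret_efficiency <- function(r, R0, N = 1) {
  if (any(r <= 0)) stop("distance r must be positive")
  if (any(R0 < 0)) stop("R0 must be non-negative")
  check_stoichiometry(N)
  u <- N * (R0 / r)^6
  u / (1 + u)
}

#' Distance at a target FRET efficiency
#'
#' Inverts the efficiency-distance relation:
#' r = R0 * (N (1 - E) / E)^(1/6). With E = 0.1 and N = 1 this gives the
#' 10 percent-efficiency range r10 = R0 * 9^(1/6), the operational detection
#' limit of a FRET pair.
#'
#' @param E Target efficiency, strictly inside (0, 1).
#' @inheritParams fret_efficiency
#' @return Distance r (nm).
#' @export
distance_at_efficiency <- function(E, R0, N = 1) {
  if (any(E <= 0) || any(E >= 1)) stop("target efficiency must be in (0, 1)")
  if (any(R0 < 0)) stop("R0 must be non-negative")
  check_stoichiometry(N)
  R0 * (N * (1 - E) / E)^(1 / 6)
}

check_stoichiometry <- function(N) {
  if (any(N < 1) || any(abs(N - round(N)) > 1e-9))
    stop("acceptors per donor N must be a positive integer")
  invisible(TRUE)
}
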