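#' Three-fluorophore cascade geometry
#'
#' Collinear arrangement of donor (D), intermediate acceptor (A1) and terminal
#' acceptor (A2): A1 sits at distance `x_A1` from the donor along the
#' donor-terminal axis, with the terminal acceptor at `r_DA2`. The three
#' Forster radii parameterise the D-A1, A1-A2 and D-A2 couplings.
#'
#' @param r_DA2 Donor to terminal-acceptor distance (nm), positive.
#' @param x_A1 Intermediate position, 0 < x_A1 < r_DA2 (nm).
#' @param R0_DA1,R0_A1A2,R0_DA2 Forster radii of the three pairs (nm).
#' @return A `cascade_geometry`.
#' @export
cascade_geometry <- function(r_DA2, x_A1, R0_DA1, R0_A1A2, R0_DA2) {
  if (r_DA2 <= 0) stop("r_DA2 must be positive")
  if (x_A1 <= 0 || x_A1 >= r_DA2)
    stop("x_A1 must lie strictly between donor and terminal acceptor")
  if (R0_DA1 < 0 || R0_A1A2 < 0 || R0_DA2 < 0) stop("R0 values must be >= 0")
  structure(
    list(r_DA2 = r_DA2, x_A1 = x_A1,
         R0_DA1 = R0_DA1, R0_A1A2 = R0_A1A2, R0_DA2 = R0_DA2),
    class = "cascade_geometry"
  )
}

#' Cascade transfer efficiencies
#'
#' Competing-rate model of the three-fluorophore energy flow. Relative to the
#' donor's unit intrinsic decay rate, transfer to the intermediate proceeds at
#' u1 = (R0_DA1/x_A1)^6 and directly to the terminal acceptor at
#' u2 = (R0_DA2/r_DA2)^6, so
#'
#'   e_to_A1     = u1 / (1 + u1 + u2)
#'   e_direct    = u2 / (1 + u1 + u2)
#'
#' The second hop has efficiency v/(1+v) with v = (R0_A1A2/(r_DA2-x_A1))^6,
#' and the total fraction of donor excitations that reach the terminal
#' acceptor is e_total = e_direct + e_to_A1 * v/(1+v). Back-transfer and
#' photon re-absorption are neglected (standard Forster kinetics).
#'
#' @param geom A [cascade_geometry()].
#' @return A `cascade_result` list with `e_total_to_A2`, `e_to_A1`,
#'   `e_direct_to_A2`, `e_A1_to_A2` (second-hop efficiency) and
#'   `donor_retained` (fraction decaying on the donor).
#' @export
cascade_efficiencies <- function(geom) {
  stopifnot(inherits(geom, "cascade_geometry"))
  u1 <- (geom$R0_DA1 / geom$x_A1)^6
  u2 <- (geom$R0_DA2 / geom$r_DA2)^6
  denom <- 1 + u1 + u2
  e1 <- u1 / denom
  ed <- u2 / denom
  v <- (geom$R0_A1A2 / (geom$r_DA2 - geom$x_A1))^6
  e2 <- v / (1 + v)
  structure(
    list(e_total_to_A2 = ed + e1 * e2, e_to_A1 = e1, e_direct_to_A2 = ed,
         e_A1_to_A2 = e2, donor_retained = 1 / denom),
    class = "cascade_result"
  )
}

# mean total transfer efficiency to A2 at donor-terminal distance r for a set
# of relative intermediate placements frac in (0,1); for 3-D placement the
# off-axis offset is drawn per sample and the two hop distances recomputed.
cascade_mean_total <- function(r, frac, R0_triple, offset_frac = NULL) {
  x <- frac * r
  if (is.null(offset_frac)) {
    d1 <- x
    d2 <- r - x
  } else {
    h <- offset_frac * r
    d1 <- sqrt(x^2 + h^2)
    d2 <- sqrt((r - x)^2 + h^2)
  }
  u1 <- (R0_triple[1] / d1)^6
  u2 <- (R0_triple[3] / r)^6
  denom <- 1 + u1 + u2
  v <- (R0_triple[2] / d2)^6
  mean(u2 / denom + (u1 / denom) * v / (1 + v))
}

#' Effective cascade range at a target efficiency
#'
#' Finds the donor-terminal distance r at which the cascade's total transfer
#' to the terminal acceptor equals `E_target`, with the intermediate either at
#' the midpoint or averaged over random placements. Random placement is
#' uniform on the 1-D segment between donor and terminal acceptor; the same
#' relative placements are reused at every bracketing step (common random
#' numbers) so the objective stays monotone in r. A 3-D variant
#' (`placement = "random3d"`) additionally draws an off-axis offset uniform in
#' \[0, r/2\] per sample.
#'
#' @param R0_triple Numeric length 3: R0 for D-A1, A1-A2, D-A2 (nm).
#' @param placement `"midpoint"`, `"random"` or `"random3d"`.
#' @param E_target Target total efficiency in (0, 1), default 0.1.
#' @param n_samples Number of random placements (random modes), default 1000.
#' @param seed RNG seed; required for the random modes.
#' @param bracket Search interval in nm, default c(0.5, 50).
#' @param tol Bisection tolerance in nm, default 1e-4.
#' @return Distance r (nm).
#' @export
cascade_range <- function(R0_triple, placement = c("midpoint", "random", "random3d"),
                          E_target = 0.1, n_samples = 1000, seed = NULL,
                          bracket = c(0.5, 50), tol = 1e-4) {
  placement <- match.arg(placement)
  stopifnot(length(R0_triple) == 3, all(R0_triple >= 0))
  if (E_target <= 0 || E_target >= 1) stop("E_target must be in (0, 1)")

  if (placement == "midpoint") {
    frac <- 0.5
    offset <- NULL
  } else {
    if (is.null(seed)) stop("seed is required for random placement")
    if (n_samples < 1) stop("n_samples must be >= 1")
    draws <- with_seed(seed, {
      f <- stats::runif(n_samples)
      o <- if (placement == "random3d") stats::runif(n_samples, 0, 0.5) else NULL
      list(f = f, o = o)
    })
    frac <- draws$f
    offset <- draws$o
  }

  obj <- function(r) cascade_mean_total(r, frac, R0_triple, offset) - E_target
  lo <- bracket[1]; hi <- bracket[2]
  flo <- obj(lo); fhi <- obj(hi)
  if (flo < 0 || fhi > 0)
    stop(sprintf(
      "E_target = %g not bracketed on [%g, %g] nm (E = %.4g at %g nm, %.4g at %g nm)",
      E_target, lo, hi, flo + E_target, lo, fhi + E_target, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (obj(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
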