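#' Spectral scene
#'
#' A mixture of fluorophores at given relative molar amounts, a pairwise
#' transfer-efficiency matrix, and a single excitation line. Transfer is only
#' allowed "downhill" (from shorter- to longer-wavelength emitters); per donor
#' the total outgoing transfer must not exceed 1.
#'
#' @param members List of `fluorophore` records, ordered or not; energy flow
#'   is resolved in order of increasing emission peak wavelength.
#' @param abundances Positive relative molar amounts, one per member.
#' @param transfer Square matrix of transfer efficiencies E_ij (row donor ->
#'   column acceptor), or `NULL` for no transfer. Dimnames, if present, must
#'   match member names.
#' @param excitation Excitation wavelength (nm).
#' @param gain Global intensity gain (a.u.), default 1.
#' @return A `spectral_scene`.
#' @export
spectral_scene <- function(members, abundances, transfer = NULL,
                           excitation, gain = 1) {
  stopifnot(is.list(members), all(vapply(members, inherits, TRUE, "fluorophore")))
  k <- length(members)
  if (length(abundances) != k || any(abundances <= 0))
    stop("abundances must be positive, one per member")
  if (is.null(transfer)) transfer <- matrix(0, k, k)
  transfer <- as.matrix(transfer)
  if (!all(dim(transfer) == c(k, k)))
    stop("transfer matrix must be ", k, " x ", k)
  if (any(transfer < 0) || any(transfer > 1))
    stop("transfer efficiencies must be in [0, 1]")
  if (any(rowSums(transfer) > 1 + 1e-12))
    stop("total outgoing transfer per donor must be <= 1")
  peaks <- vapply(members, function(m) m$wavelengths[which.max(m$emission_shape)],
                  numeric(1))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (transfer[i, j] > 0 && peaks[j] <= peaks[i])
      stop("uphill transfer is forbidden: ", members[[i]]$name, " -> ",
           members[[j]]$name)
  }
  names(members) <- vapply(members, `[[`, character(1), "name")
  dimnames(transfer) <- list(names(members), names(members))
  structure(
    list(members = members, abundances = stats::setNames(abundances, names(members)),
         transfer = transfer, excitation = excitation, gain = gain,
         emission_peaks = stats::setNames(peaks, names(members))),
    class = "spectral_scene"
  )
}

#' Transfer matrix from a cascade geometry
#'
#' Maps a three-fluorophore [cascade_geometry()] to the pairwise transfer
#' matrix of a [spectral_scene()]: E(D->A1) = e_to_A1, E(D->A2) = direct
#' fraction, E(A1->A2) = second-hop efficiency.
#'
#' @param geom A [cascade_geometry()].
#' @param names Member names (donor, intermediate, terminal).
#' @return 3 x 3 transfer matrix.
#' @export
transfer_from_geometry <- function(geom, names = c("mTRQ2", "mVEN", "mRFP")) {
  ce <- cascade_efficiencies(geom)
  m <- matrix(0, 3, 3, dimnames = list(names, names))
  m[1, 2] <- ce$e_to_A1
  m[1, 3] <- ce$e_direct_to_A2
  m[2, 3] <- ce$e_A1_to_A2
  m
}

#' Simulate an emission spectrum for a scene
#'
#' Forward model of single-line excitation with cross-excitation, FRET
#' redistribution and bleed-through. Member i absorbs
#' X_i = abundance_i * eps_i(lambda_ex) quanta directly. Processing members
#' in order of increasing emission peak (decreasing energy), the excited
#' quanta N_i = X_i + (quanta received by FRET) are split: fraction E_ij is
#' transferred to member j, and the remainder emits with yield Q_i and
#' spectral shape f_i(lambda). When `relay_cross_excitation = FALSE`,
#' directly excited quanta of non-donor members do not undergo FRET (they
#' emit with full yield); this isolates the cross-excitation-then-transfer
#' pathway for sensitivity analysis.
#'
#' @param scene A [spectral_scene()].
#' @param grid Wavelength grid for the output, default the working grid.
#' @param relay_cross_excitation Allow directly excited acceptors to relay
#'   energy onward (default TRUE).
#' @return An `emission_spectrum`: list with `wavelengths`, `total`,
#'   `components` (matrix, wavelength x member), and `quanta` (data frame of
#'   absorbed / received / transferred-out / emitted quanta per member).
#' @export
simulate_emission <- function(scene, grid = working_grid(),
                              relay_cross_excitation = TRUE) {
  stopifnot(inherits(scene, "spectral_scene"))
  wl <- grid$wavelengths
  nm <- names(scene$members)
  k <- length(nm)
  ord <- order(scene$emission_peaks)

  eps_ex <- vapply(scene$members, function(m)
    interp_zero(m$wavelengths, m$extinction, scene$excitation), numeric(1))
  direct <- scene$abundances * eps_ex
  if (all(direct == 0))
    warning("excitation at ", scene$excitation,
            " nm is outside all extinction supports; spectrum is zero")

  received <- stats::setNames(numeric(k), nm)
  transferred_out <- stats::setNames(numeric(k), nm)
  emitted <- stats::setNames(numeric(k), nm)
  components <- matrix(0, length(wl), k, dimnames = list(NULL, nm))

  is_first <- stats::setNames(seq_len(k) == ord[1], nm)[nm]
  for (i in ord) {
    name <- nm[i]
    relayable <- received[i] +
      if (relay_cross_excitation || is_first[name]) direct[i] else 0
    passive <- (direct[i] + received[i]) - relayable
    e_out <- scene$transfer[i, ]
    transferred_out[i] <- relayable * sum(e_out)
    for (j in seq_len(k)) {
      if (e_out[j] > 0) received[j] <- received[j] + relayable * e_out[j]
    }
    emitted[i] <- (relayable * (1 - sum(e_out)) + passive) *
      scene$members[[i]]$quantum_yield
    shape <- interp_zero(scene$members[[i]]$wavelengths,
                         scene$members[[i]]$emission_shape, wl)
    components[, i] <- scene$gain * emitted[i] * shape
  }

  structure(
    list(wavelengths = wl, total = rowSums(components), components = components,
         quanta = data.frame(member = nm, absorbed = direct,
                             received = received,
                             transferred_out = transferred_out,
                             emitted_photons = emitted, row.names = NULL)),
    class = "emission_spectrum"
  )
}

#' Spectra across a series of stoichiometries
#'
#' Re-simulates a scene for each abundance vector in `ratios`, keeping the
#' transfer matrix and excitation fixed. With zero transfer, the donor
#' component is invariant and each acceptor component scales linearly with
#' its abundance.
#'
#' @param scene A [spectral_scene()].
#' @param ratios List of positive abundance vectors (one value per member).
#' @param ... Passed to [simulate_emission()].
#' @return List of `emission_spectrum` objects, one per ratio.
#' @export
stoichiometry_series <- function(scene, ratios, ...) {
  if (length(ratios) == 0) stop("ratios must be a non-empty list")
  lapply(ratios, function(ab) {
    if (length(ab) != length(scene$members) || any(ab <= 0))
      stop("each ratio must be a positive vector of length ",
           length(scene$members))
    s <- scene
    s$abundances <- stats::setNames(ab, names(scene$members))
    simulate_emission(s, ...)
  })
}

#' Detector dialect
#'
#' Binning grid and sequential-excitation channel definitions of a named
#' confocal configuration. `"leica"`: lambda-stacks 460-625 nm at 7.5 nm
#' (22 bins), channels excited at 458 / 514 / 561 nm detected in 465-505 /
#' 525-565 / 605-650 nm with relative excitation powers 1 / 0.5 / 0.75
#' (mirroring 40 / 20 / 30 percent laser settings). `"zeiss"`: lambda-stacks
#' 460-650 nm at 4.5 nm with the same channel set.
#'
#' @param name `"leica"` or `"zeiss"`.
#' @return A `detector_dialect` with `name`, `grid` and `channels` (data
#'   frame: `excitation_nm`, `band_lo_nm`, `band_hi_nm`, `power`).
#' @export
detector_dialect <- function(name = c("leica", "zeiss")) {
  name <- match.arg(name)
  grid <- switch(name,
    leica = wavelength_grid(460, 625, 7.5),
    zeiss = wavelength_grid(460, 650, 4.5))
  channels <- data.frame(
    channel = c("donor", "intermediate", "terminal"),
    excitation_nm = c(458, 514, 561),
    band_lo_nm = c(465, 525, 605),
    band_hi_nm = c(505, 565, 650),
    power = c(1, 0.5, 0.75))
  structure(list(name = name, grid = grid, channels = channels),
            class = "detector_dialect")
}

#' Bin a spectrum into a lambda-stack
#'
#' Integrates the spectrum over each detector bin `[start, start + step)` of
#' the dialect's grid. The sum of all bins equals the integral over the grid
#' span.
#'
#' @param spectrum An `emission_spectrum` (from [simulate_emission()]) or a
#'   list with `wavelengths` and `total`.
#' @param dialect A [detector_dialect()].
#' @return A `lambda_stack` data frame with `bin_start_nm` and `intensity`,
#'   with the dialect name as attribute `dialect`.
#' @export
bin_spectrum <- function(spectrum, dialect) {
  stopifnot(inherits(dialect, "detector_dialect"))
  g <- dialect$grid
  edges <- g$wavelengths
  n_bins <- length(edges) - 1L
  vals <- vapply(seq_len(n_bins), function(b)
    integrate_band(spectrum$wavelengths, spectrum$total,
                   edges[b], edges[b + 1]), numeric(1))
  structure(data.frame(bin_start_nm = edges[-length(edges)], intensity = vals),
            dialect = dialect$name, class = c("lambda_stack", "data.frame"))
}

#' Reference lambda-stack of a pure fluorophore
#'
#' Bins the fluorophore's unit-area emission density on the dialect grid and
#' normalises the bins to unit sum. These binned pure-member shapes are the
#' reference set for spectral unmixing (binning the continuum and unmixing
#' un-binned shapes would introduce binning bias).
#'
#' @param record A `fluorophore`.
#' @param dialect A [detector_dialect()].
#' @return Numeric vector of bin weights summing to 1.
#' @export
reference_stack <- function(record, dialect) {
  spec <- list(wavelengths = record$wavelengths, total = record$emission_shape)
  v <- bin_spectrum(spec, dialect)$intensity
  s <- sum(v)
  if (s <= 0) stop("fluorophore '", record$name,
                   "' has no emission inside the dialect grid")
  v / s
}

#' Sequential-excitation channel intensities
#'
#' For each channel of the dialect the scene is re-simulated at that
#' channel's excitation line (scaled by the channel's relative excitation
#' power) and the resulting total emission is averaged over the channel's
#' detection band (band integral divided by band width, the per-ROI analogue
#' of a mean pixel intensity); bleed-through of every member into the band
#' is therefore included. Per-member contributions are returned as the
#' `"members"` attribute.
#'
#' @param scene A [spectral_scene()].
#' @param dialect A [detector_dialect()].
#' @return Named numeric vector of channel intensities (a.u.), with attribute
#'   `members` (matrix channel x member of contributions).
#' @export
channel_intensities <- function(scene, dialect) {
  stopifnot(inherits(scene, "spectral_scene"), inherits(dialect, "detector_dialect"))
  ch <- dialect$channels
  nm <- names(scene$members)
  contrib <- matrix(0, nrow(ch), length(nm),
                    dimnames = list(ch$channel, nm))
  for (c_i in seq_len(nrow(ch))) {
    s <- scene
    s$excitation <- ch$excitation_nm[c_i]
    sim <- suppressWarnings(simulate_emission(s))
    width <- ch$band_hi_nm[c_i] - ch$band_lo_nm[c_i]
    contrib[c_i, ] <- ch$power[c_i] / width * vapply(nm, function(m)
      integrate_band(sim$wavelengths, sim$components[, m],
                     ch$band_lo_nm[c_i], ch$band_hi_nm[c_i]), numeric(1))
  }
  structure(stats::setNames(rowSums(contrib), ch$channel), members = contrib)
}

#' Per-channel response of each pure member
#'
#' Simulates each member alone at unit abundance through every channel,
#' giving the response (bleed-through) matrix used to invert channel
#' intensities into member abundances.
#'
#' @param members List of `fluorophore` records.
#' @param dialect A [detector_dialect()].
#' @return Matrix (channel x member) of channel intensities per unit
#'   abundance.
#' @export
channel_response_matrix <- function(members, dialect) {
  nm <- vapply(members, `[[`, character(1), "name")
  resp <- matrix(0, nrow(dialect$channels), length(members),
                 dimnames = list(dialect$channels$channel, nm))
  for (i in seq_along(members)) {
    sc <- spectral_scene(members[i], 1, NULL, excitation = 458)
    resp[, i] <- suppressWarnings(channel_intensities(sc, dialect))
  }
  resp
}
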