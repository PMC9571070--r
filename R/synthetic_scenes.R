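#' Named ground-truth scenario presets
#'
#' Each preset fixes the fluorophore members, their couplings and the
#' ground-truth donor decay of one experimental condition of the
#' three-fluorophore study, in the photophysical regime of the mTRQ2 / mVEN /
#' mRFP triple (Forster radii 5.7 / 5.2 / 5.1 nm):
#'
#' * `donor_only` — donor alone, mono-exponential 3.99 ns.
#' * `donor_A1` — donor + intermediate acceptor at 7 nm; donor partially
#'   complexed so the intensity-weighted lifetime is 3.54 ns.
#' * `donor_A2` — donor + terminal acceptor at 7 nm; target 3.54 ns.
#' * `donor_A1_uncoupledA2` — all three present, but the terminal acceptor
#'   uncoupled (FLS2-like bystander); lifetime as `donor_A1` (3.54 ns).
#' * `ternary_cascade` — all three in the equidistant 7 nm linear
#'   arrangement (donor-terminal distance 14 nm); target 3.40 ns.
#' * `negative_control_FLS2like` — all three present, every coupling zero;
#'   lifetime 3.90 ns.
#'
#' The targeted average lifetimes are reached by mixing unquenched donors
#' (3.99 ns) with donors quenched at the preset's geometry; the quenched
#' fraction is solved so the intensity-weighted average equals the target.
#'
#' @param name Preset name (see above).
#' @param distance Nearest-neighbour fluorophore spacing (nm), default 7.
#' @param R0_triple Forster radii (D-A1, A1-A2, D-A2) in nm, default
#'   c(5.7, 5.2, 5.1).
#' @return A `scenario_preset`: members, abundances, transfer matrix,
#'   geometry (or NULL), decay model (lifetimes + amplitudes), target
#'   `tau_avg`, and noise defaults (`spectral_sigma` = 0.02 of peak with
#'   8-bit saturation, `n_photons` = 5e5, `tau_jitter_sd` = 0.05 ns
#'   ROI-to-ROI, `abundance_jitter_sdlog` = 0.15).
#' @export
scenario_preset <- function(name = c("donor_only", "donor_A1", "donor_A2",
                                     "donor_A1_uncoupledA2", "ternary_cascade",
                                     "negative_control_FLS2like"),
                            distance = 7, R0_triple = c(5.7, 5.2, 5.1)) {
  presets <- c("donor_only", "donor_A1", "donor_A2", "donor_A1_uncoupledA2",
               "ternary_cascade", "negative_control_FLS2like")
  if (!is.character(name) || !(name[1] %in% presets))
    stop("unknown preset '", name[1], "'; available: ",
         paste(presets, collapse = ", "))
  name <- name[1]

  donor <- synthetic_fluorophore("mTRQ2")
  a1 <- synthetic_fluorophore("mVEN")
  a2 <- synthetic_fluorophore("mRFP")
  tau_d <- donor$lifetime  # 3.99 ns

  geom <- NULL
  members <- list(donor)
  transfer <- NULL
  e_donor_out <- 0  # total transfer out of a complexed donor
  tau_target <- tau_d

  if (name == "donor_A1") {
    members <- list(donor, a1)
    e <- fret_efficiency(distance, R0_triple[1])
    transfer <- matrix(c(0, e, 0, 0), 2, 2, byrow = TRUE)
    e_donor_out <- e
    tau_target <- 3.54
  } else if (name == "donor_A2") {
    members <- list(donor, a2)
    e <- fret_efficiency(distance, R0_triple[3])
    transfer <- matrix(c(0, e, 0, 0), 2, 2, byrow = TRUE)
    e_donor_out <- e
    tau_target <- 3.54
  } else if (name == "donor_A1_uncoupledA2") {
    members <- list(donor, a1, a2)
    e <- fret_efficiency(distance, R0_triple[1])
    transfer <- matrix(0, 3, 3)
    transfer[1, 2] <- e
    e_donor_out <- e
    tau_target <- 3.54
  } else if (name == "ternary_cascade") {
    members <- list(donor, a1, a2)
    geom <- cascade_geometry(2 * distance, distance,
                             R0_triple[1], R0_triple[2], R0_triple[3])
    transfer <- transfer_from_geometry(geom)
    ce <- cascade_efficiencies(geom)
    e_donor_out <- ce$e_to_A1 + ce$e_direct_to_A2
    tau_target <- 3.40
  } else if (name == "negative_control_FLS2like") {
    members <- list(donor, a1, a2)
    transfer <- matrix(0, 3, 3)
    tau_target <- 3.90
  }

  # decay model: unquenched 3.99 ns component plus, when the donor is
  # coupled, a quenched component tau_d * (1 - E_out); amplitude ratio
  # solved so the intensity-weighted average hits tau_target
  if (e_donor_out > 0) {
    tau_q <- tau_d * (1 - e_donor_out)
    x <- (tau_d^2 - tau_target * tau_d) / (tau_target * tau_q - tau_q^2)
    lifetimes <- c(tau_d, tau_q)
    amplitudes <- c(1, x) / (1 + x)
  } else {
    lifetimes <- tau_target
    amplitudes <- 1
  }

  structure(
    list(name = name, members = members,
         abundances = rep(1, length(members)), transfer = transfer,
         geometry = geom, lifetimes = lifetimes, amplitudes = amplitudes,
         tau_avg = sum(amplitudes * lifetimes^2) / sum(amplitudes * lifetimes),
         spectral_sigma = 0.02, saturation = 255, n_photons = 5e5,
         tau_jitter_sd = 0.05, abundance_jitter_sdlog = 0.15,
         excitation = 458),
    class = "scenario_preset"
  )
}

#' Generate a complete synthetic dataset from a preset
#'
#' Forward-simulates `n_roi` independent noisy regions of interest: a
#' lambda-stack (additive Gaussian noise at `spectral_sigma` of the peak,
#' quantised to the 8-bit 0-255 a.u. scale with saturation), the three
#' sequential-excitation channel intensities (same noise model), and a TCSPC
#' decay histogram (ROI lifetimes jittered by `tau_jitter_sd`, multinomial
#' counting noise at the preset's photon budget). Deterministic given the
#' seed.
#'
#' @param preset A [scenario_preset()] or a preset name.
#' @param n_roi Number of regions of interest, default 20.
#' @param seed RNG seed (required).
#' @param dialect A [detector_dialect()], default `"leica"`.
#' @param n_bins_decay Time bins per decay histogram, default 256.
#' @param gain Intensity gain mapping emitted quanta to the 8-bit
#'   lambda-stack scale; the default 0.064 puts the donor-only emission peak
#'   near 150 a.u.
#' @param channel_gain Gain of the sequential-excitation channel readings;
#'   the default 0.48 puts pure-member channel means near 120-200 a.u.
#' @return A `scenario_bundle`: `stacks` (n_roi x bins matrix),
#'   `channel_values` (n_roi x 3), `decays` (list of [decay_histogram()]s),
#'   `truth` (generating parameters incl. per-ROI lifetimes), `dialect`,
#'   `preset`.
#' @export
make_scenario <- function(preset, n_roi = 20, seed,
                          dialect = detector_dialect("leica"),
                          n_bins_decay = 256, gain = 0.064,
                          channel_gain = 0.48) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_roi < 1) stop("n_roi must be >= 1")

  scene0 <- spectral_scene(preset$members, preset$abundances, preset$transfer,
                           excitation = preset$excitation, gain = gain)
  k <- length(preset$members)
  n_bins <- length(dialect$grid$wavelengths) - 1L

  with_seed(seed, {
    stacks <- matrix(0, n_roi, n_bins)
    chans <- matrix(0, n_roi, nrow(dialect$channels),
                    dimnames = list(NULL, dialect$channels$channel))
    decays <- vector("list", n_roi)
    roi_tau <- numeric(n_roi)
    roi_abund <- matrix(0, n_roi, k,
                        dimnames = list(NULL, names(scene0$members)))

    for (r in seq_len(n_roi)) {
      sc <- scene0
      ab <- preset$abundances *
        exp(stats::rnorm(k, 0, preset$abundance_jitter_sdlog))
      sc$abundances <- stats::setNames(ab, names(scene0$members))
      roi_abund[r, ] <- ab

      clean <- bin_spectrum(simulate_emission(sc), dialect)$intensity
      sigma <- preset$spectral_sigma * max(clean)
      noisy <- clean + stats::rnorm(n_bins, 0, sigma)
      stacks[r, ] <- pmin(pmax(round(noisy), 0), preset$saturation)

      cv <- channel_intensities(sc, dialect) * channel_gain / gain
      cv <- cv + stats::rnorm(length(cv), 0, preset$spectral_sigma * max(cv))
      chans[r, ] <- pmin(pmax(round(cv), 0), preset$saturation)

      jit <- stats::rnorm(1, 0, preset$tau_jitter_sd)
      scale <- (preset$tau_avg + jit) / preset$tau_avg
      roi_tau[r] <- preset$tau_avg + jit
      decays[[r]] <- simulate_decay(
        lifetimes = preset$lifetimes * scale,
        amplitudes = preset$amplitudes,
        n_photons = preset$n_photons, n_bins = n_bins_decay,
        seed = NULL)
    }

    structure(
      list(stacks = stacks, channel_values = chans, decays = decays,
           truth = list(preset_name = preset$name, seed = seed,
                        lifetimes = preset$lifetimes,
                        amplitudes = preset$amplitudes,
                        tau_avg = preset$tau_avg, roi_tau_avg = roi_tau,
                        abundances = roi_abund, transfer = preset$transfer,
                        gain = gain, n_photons = preset$n_photons,
                        spectral_sigma = preset$spectral_sigma),
           dialect = dialect, preset = preset),
      class = "scenario_bundle"
    )
  })
}

#' Write a scenario bundle to plain-text files
#'
#' Writes one lambda-stack CSV per ROI (`roi_<i>_stack.csv`, header
#' `bin_start_nm,intensity`), one decay + IRF CSV pair per ROI, a channel
#' intensity table, and `truth.json` with all generating parameters.
#'
#' @param bundle A `scenario_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  starts <- bundle$dialect$grid$wavelengths
  starts <- starts[-length(starts)]
  for (r in seq_len(nrow(bundle$stacks))) {
    utils::write.csv(
      data.frame(bin_start_nm = starts, intensity = bundle$stacks[r, ]),
      file.path(dir, sprintf("roi_%02d_stack.csv", r)), row.names = FALSE)
    d <- bundle$decays[[r]]
    utils::write.csv(data.frame(time_ns = d$bin_times, counts = d$counts),
                     file.path(dir, sprintf("roi_%02d_decay.csv", r)),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_ns = d$bin_times, irf = d$irf),
                     file.path(dir, sprintf("roi_%02d_irf.csv", r)),
                     row.names = FALSE)
  }
  utils::write.csv(
    cbind(data.frame(roi = seq_len(nrow(bundle$channel_values))),
          as.data.frame(bundle$channel_values)),
    file.path(dir, "channel_values.csv"), row.names = FALSE)
  truth <- bundle$truth
  truth$abundances <- as.data.frame(truth$abundances)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Fitted donor lifetimes of a scenario bundle
#'
#' Fits every decay in the bundle by iterative reconvolution and returns the
#' intensity-weighted average lifetimes. Following the acquisition protocol,
#' donor-only decays are fitted mono-exponentially and every coupled (FRET)
#' condition biexponentially; `n_components` overrides this default.
#'
#' @param bundle A `scenario_bundle`.
#' @param n_components 1 or 2; default chosen from the preset.
#' @return Numeric vector of tau_avg (ns), one per ROI.
#' @export
bundle_lifetimes <- function(bundle, n_components = NULL) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  if (is.null(n_components))
    n_components <- if (length(bundle$truth$lifetimes) > 1) 2 else 1
  vapply(bundle$decays, function(d) fit_decay(d, n_components)$tau_avg,
         numeric(1))
}

#' One simulated ternary-complex experiment
#'
#' Generates donor-only, both binary (donor + one acceptor) reference
#' conditions and the given test condition with seeds derived from `seed`,
#' fits all decays, and applies the excess-quenching decision rule to the
#' test condition's lifetimes.
#'
#' @param test_preset Preset name of the condition under test, e.g.
#'   `"ternary_cascade"`, `"donor_A1_uncoupledA2"`,
#'   `"negative_control_FLS2like"`.
#' @param n_roi ROIs per condition, default 6.
#' @param seed Experiment seed; condition seeds are derived from it.
#' @param ... Passed to [make_scenario()].
#' @return The [ternary_excess_quenching()] decision record, with the
#'   fitted lifetime sets attached.
#' @export
simulate_ternary_experiment <- function(test_preset, n_roi = 6, seed, ...) {
  seeds <- seed * 10 + 0:3
  tau_d <- bundle_lifetimes(make_scenario("donor_only", n_roi, seeds[1], ...))
  tau_b1 <- bundle_lifetimes(make_scenario("donor_A1", n_roi, seeds[2], ...))
  tau_b2 <- bundle_lifetimes(make_scenario("donor_A2", n_roi, seeds[3], ...))
  tau_t <- bundle_lifetimes(make_scenario(test_preset, n_roi, seeds[4], ...))
  ternary_excess_quenching(tau_t, tau_b1, tau_b2, tau_d)
}
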