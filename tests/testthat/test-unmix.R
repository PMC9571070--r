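dial <- detector_dialect("leica")

test_that("a scaled pure component is recovered exactly", {
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial),
               mRFP = reference_stack(tr$a2, dial))
  res <- unmix(37 * refs$mVEN, refs, fit_background = FALSE)
  expect_equal(unname(res$coefficients["mVEN"]), 37, tolerance = 1e-9)
  expect_equal(unname(res$coefficients[c("mTRQ2", "mRFP")]), c(0, 0))
  expect_lt(res$residual_norm, 1e-9)
  expect_equal(sum(res$proportions), 1)
})

test_that("unmixing round-trips simulated scenes without noise", {
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial),
               mRFP = reference_stack(tr$a2, dial))
  geom <- cascade_geometry(14, 7, 5.7, 5.2, 5.1)
  for (ab in list(c(1, 1, 1), c(1, 4, 1), c(2, 1, 0.5))) {
    sc <- spectral_scene(list(tr$d, tr$a1, tr$a2), ab,
                         transfer_from_geometry(geom), excitation = 458)
    sim <- simulate_emission(sc)
    st <- bin_spectrum(sim, dial)
    truth <- component_bin_totals(sim, dial)
    res <- unmix(st, refs, fit_background = FALSE)
    expect_equal(unname(res$coefficients), unname(truth), tolerance = 1e-6)
  }
})

test_that("proportions are invariant to global intensity scaling", {
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial))
  sc <- spectral_scene(list(tr$d, tr$a1), c(1, 2), NULL, excitation = 458)
  st <- bin_spectrum(simulate_emission(sc), dial)$intensity
  p1 <- unmix(st, refs)$proportions
  p2 <- unmix(1000 * st, refs)$proportions
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("noisy proportions are recovered within 0.02 absolute", {
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial),
               mRFP = reference_stack(tr$a2, dial))
  sc <- spectral_scene(list(tr$d, tr$a1, tr$a2), c(1, 1, 1), NULL,
                       excitation = 458)
  sim <- simulate_emission(sc)
  clean <- bin_spectrum(sim, dial)$intensity
  truth <- component_bin_totals(sim, dial)
  p_true <- truth / sum(truth)
  set.seed(101)
  for (i in 1:25) {
    noisy <- clean + rnorm(length(clean), 0, 0.02 * max(clean))
    res <- unmix(noisy, refs)
    expect_lt(max(abs(res$proportions - p_true)), 0.02)
  }
})

test_that("rank-deficient reference sets are rejected naming the collinear pair", {
  tr <- triple()
  r <- reference_stack(tr$d, dial)
  expect_error(unmix(r, list(a = r, b = 2 * r)), "collinear pair")
})

test_that("donor-to-acceptor ratio inverts the bleed-through response", {
  # identity response: channels (120, 480, 0) give a 1:4 donor:acceptor ratio
  expect_equal(donor_acceptor_ratio(c(120, 480, 0), diag(3)), 0.25)
  expect_warning(r <- donor_acceptor_ratio(c(120, 0, 0), diag(3)), "infinite")
  expect_true(is.infinite(r))
  expect_error(donor_acceptor_ratio(c(1, 1), diag(3)), "square")
  expect_error(donor_acceptor_ratio(c(1, 1, 1), matrix(1, 3, 3)),
               "not invertible")
})

test_that("ratio recovery is self-consistent with the simulated response matrix", {
  tr <- triple()
  members <- list(tr$d, tr$a1, tr$a2)
  M <- channel_response_matrix(members, dial)
  sc <- spectral_scene(members, c(1.3, 5.2, 0.7), NULL, excitation = 458)
  cv <- channel_intensities(sc, dial)
  expect_equal(donor_acceptor_ratio(cv, M), 1.3 / 5.2, tolerance = 1e-9)
  expect_equal(donor_acceptor_ratio(cv, M, acceptor = "mRFP"), 1.3 / 0.7,
               tolerance = 1e-9)
})

make_tagged <- function(label, da_ratio, a1_prop) {
  # minimal unmix_result stand-in built through the real constructor path
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial))
  stack <- (1 - a1_prop) * refs$mTRQ2 + a1_prop * refs$mVEN
  ratio_tagged_sample(unmix(stack, refs, fit_background = FALSE),
                      da_ratio, label)
}

test_that("identical groups show no proportion difference", {
  set.seed(7)
  samples <- c(
    lapply(1:5, function(i) make_tagged("a", 0.25 * runif(1, 0.9, 1.1), 0.4)),
    lapply(1:5, function(i) make_tagged("b", 0.25 * runif(1, 0.9, 1.1), 0.4)))
  cmp <- ratio_matched_compare(samples, "a", "b", acceptor = "mVEN")
  expect_equal(cmp$difference, 0, tolerance = 1e-6)
  expect_gte(cmp$n_a, 3); expect_gte(cmp$n_b, 3)
})

test_that("groups with disjoint ratio ranges are rejected", {
  samples <- c(
    lapply(1:4, function(i) make_tagged("a", 0.25 + 0.01 * i, 0.4)),
    lapply(1:4, function(i) make_tagged("b", 2.5 + 0.1 * i, 0.4)))
  expect_error(ratio_matched_compare(samples, "a", "b", acceptor = "mVEN"),
               "no overlapping")
})

test_that("a FRET-induced acceptor-proportion shift is detected at matched ratios", {
  tr <- triple()
  refs <- list(mTRQ2 = reference_stack(tr$d, dial),
               mVEN = reference_stack(tr$a1, dial))
  sim_sample <- function(e, label, seed) {
    m <- matrix(0, 2, 2); m[1, 2] <- e
    set.seed(seed)
    ab <- c(1, 4) * exp(rnorm(2, 0, 0.05))
    sc <- spectral_scene(list(tr$d, tr$a1), ab, m, excitation = 458)
    clean <- bin_spectrum(simulate_emission(sc), dial)$intensity
    noisy <- clean + rnorm(length(clean), 0, 0.02 * max(clean))
    ratio_tagged_sample(unmix(noisy, refs), ab[1] / ab[2], label)
  }
  detected <- vapply(1:40, function(rep) {
    samples <- c(
      lapply(1:6, function(i) sim_sample(0.15, "fret", rep * 100 + i)),
      lapply(1:6, function(i) sim_sample(0, "ctrl", rep * 100 + 50 + i)))
    cmp <- ratio_matched_compare(samples, "fret", "ctrl", acceptor = "mVEN")
    cmp$difference > 0
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("the three-chromophore signature is raised only for cascade scenes", {
  tr <- triple()
  members <- list(tr$d, tr$a1, tr$a2)
  geom <- cascade_geometry(14, 7, 5.7, 5.2, 5.1)
  mk_stack <- function(transfer, memb = members, ab = rep(1, length(memb))) {
    sc <- spectral_scene(memb, ab, transfer, excitation = 458)
    bin_spectrum(simulate_emission(sc), dial)
  }
  e12 <- cascade_efficiencies(geom)$e_to_A1
  t_binary <- matrix(0, 2, 2); t_binary[1, 2] <- e12
  t_uncoupled <- matrix(0, 3, 3); t_uncoupled[1, 2] <- e12

  stacks <- list(
    donor_only = mk_stack(NULL, list(tr$d), 1),
    d_a1 = mk_stack(t_binary, list(tr$d, tr$a1), c(1, 1)),
    ternary = mk_stack(transfer_from_geometry(geom)),
    uncoupled = mk_stack(t_uncoupled))
  flags <- sensitized_emission_flag(stacks, dial, baseline = "donor_only",
                                    di_reference = "d_a1")
  get <- function(cond, col) flags[flags$condition == cond, col]
  expect_false(get("donor_only", "sensitized"))
  expect_true(get("ternary", "sensitized"))
  expect_true(get("ternary", "cascade_signature"))
  expect_false(get("uncoupled", "sensitized"))
  expect_false(get("uncoupled", "cascade_signature"))
  expect_error(sensitized_emission_flag(stacks, dial, baseline = "missing"),
               "missing")
})

test_that("signature calls are stable under measurement noise", {
  # condition spectra are averages over 6 noisy ROIs, as in the acquisition
  # protocol the generator emulates
  tr <- triple()
  geom <- cascade_geometry(14, 7, 5.7, 5.2, 5.1)
  e12 <- cascade_efficiencies(geom)$e_to_A1
  t_binary <- matrix(0, 2, 2); t_binary[1, 2] <- e12
  t_uncoupled <- matrix(0, 3, 3); t_uncoupled[1, 2] <- e12
  condition_stack <- function(memb, ab, transfer, n_roi = 6) {
    sc <- spectral_scene(memb, ab, transfer, excitation = 458, gain = 0.064)
    v <- bin_spectrum(simulate_emission(sc), dial)$intensity
    rois <- replicate(n_roi,
      pmin(pmax(round(v + rnorm(length(v), 0, 0.02 * max(v))), 0), 255))
    rowMeans(rois)
  }
  members <- list(tr$d, tr$a1, tr$a2)
  set.seed(2024)
  calls <- t(vapply(1:60, function(i) {
    stacks <- list(
      donor_only = condition_stack(list(tr$d), 1, NULL),
      d_a1 = condition_stack(list(tr$d, tr$a1), c(1, 1), t_binary),
      ternary = condition_stack(members, c(1, 1, 1),
                                transfer_from_geometry(geom)),
      uncoupled = condition_stack(members, c(1, 1, 1), t_uncoupled))
    f <- sensitized_emission_flag(stacks, dial, "donor_only", "d_a1")
    c(tern = f$cascade_signature[f$condition == "ternary"],
      unc = f$cascade_signature[f$condition == "uncoupled"])
  }, logical(2)))
  expect_gte(mean(calls[, "tern"]), 0.95)
  expect_lte(mean(calls[, "unc"]), 0.05)
})
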