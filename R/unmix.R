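#' Linear spectral unmixing of a lambda-stack
#'
#' Decomposes a binned emission spectrum into a non-negative combination of
#' reference component stacks (plus an optional flat background offset) by
#' non-negative least squares (Lawson-Hanson). Coefficients are in the same
#' arbitrary units as the stack; `proportions` are the coefficients
#' normalised to unit sum (background excluded), hence invariant to global
#' intensity scaling.
#'
#' @param stack A `lambda_stack` (from [bin_spectrum()]) or a numeric vector
#'   of binned intensities.
#' @param references Named list (or matrix, bins x members) of reference
#'   stacks on the same dialect grid, e.g. from [reference_stack()].
#' @param fit_background Include a flat non-negative offset, default TRUE.
#' @return An `unmix_result`: `coefficients` (named, >= 0), `background`,
#'   `residual_norm` (RMS residual, a.u.), `proportions`, `fitted`.
#' @export
unmix <- function(stack, references, fit_background = TRUE) {
  y <- if (is.data.frame(stack)) stack$intensity else as.numeric(stack)
  A <- if (is.matrix(references)) references else do.call(cbind, references)
  if (is.null(colnames(A))) colnames(A) <- paste0("ref", seq_len(ncol(A)))
  if (ncol(A) < 1) stop("at least one reference is required")
  if (nrow(A) != length(y))
    stop("references and stack must be binned on the same grid (",
         nrow(A), " vs ", length(y), " bins)")

  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    cn <- stats::cor(A)
    diag(cn) <- 0
    worst <- which(abs(cn) == max(abs(cn)), arr.ind = TRUE)[1, ]
    stop("reference set is rank deficient; most collinear pair: ",
         colnames(A)[worst[1]], " and ", colnames(A)[worst[2]])
  }

  D <- if (fit_background) cbind(A, background = 1) else A
  fit <- pracma::lsqnonneg(D, y)
  x <- fit$x
  coef <- stats::setNames(x[seq_len(ncol(A))], colnames(A))
  bg <- if (fit_background) x[ncol(A) + 1] else 0
  fitted <- as.numeric(D %*% x)
  total <- sum(coef)
  structure(
    list(coefficients = coef, background = bg,
         residual_norm = sqrt(mean((y - fitted)^2)),
         proportions = if (total > 0) coef / total else coef * 0,
         fitted = fitted),
    class = "unmix_result"
  )
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result>\n  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf("\n  background = %.4g  RMS residual = %.4g\n",
              x$background, x$residual_norm))
  invisible(x)
}

#' Donor-to-acceptor ratio from sequential-excitation channels
#'
#' Solves member abundances from per-channel intensities through the channel
#' response (bleed-through) matrix and returns the donor-to-acceptor
#' abundance ratio. Negative solved abundances are clamped to zero with a
#' warning; a zero acceptor abundance yields `Inf` with a warning (degenerate
#' sample).
#'
#' @param channel_values Numeric vector of channel intensities (>= 0), one
#'   per channel.
#' @param bleedthrough_matrix Square response matrix (channel x member), e.g.
#'   from [channel_response_matrix()]; must be invertible.
#' @param donor,acceptor Member column index or name, defaults 1 and 2.
#' @return da_ratio (dimensionless).
#' @export
donor_acceptor_ratio <- function(channel_values, bleedthrough_matrix,
                                 donor = 1, acceptor = 2) {
  M <- as.matrix(bleedthrough_matrix)
  if (nrow(M) != ncol(M) || nrow(M) != length(channel_values))
    stop("bleed-through matrix must be square and match the channel count")
  if (any(channel_values < 0)) stop("channel values must be >= 0")
  if (abs(det(M)) < 1e-12 * prod(pmax(abs(diag(M)), 1)))
    stop("bleed-through matrix is not invertible")
  ab <- solve(M, channel_values)
  if (any(ab < 0)) {
    warning("negative solved abundance clamped to 0")
    ab <- pmax(ab, 0)
  }
  if (!is.null(colnames(M))) names(ab) <- colnames(M)
  d <- ab[[donor]]; a <- ab[[acceptor]]
  if (a == 0) {
    warning("acceptor abundance is zero; donor-to-acceptor ratio is infinite")
    return(Inf)
  }
  d / a
}

#' Ratio-tagged unmixing sample
#'
#' Pairs an [unmix()] result with the sample's donor-to-acceptor protein
#' ratio and condition label. Comparing FRET-induced acceptor proportions is
#' only meaningful between samples of matching donor-to-acceptor ratio, so
#' every sample carries its ratio.
#'
#' @param unmix An `unmix_result`.
#' @param da_ratio Positive donor-to-acceptor ratio.
#' @param label Condition identifier.
#' @return A `ratio_tagged_sample`.
#' @export
ratio_tagged_sample <- function(unmix, da_ratio, label) {
  stopifnot(inherits(unmix, "unmix_result"))
  if (!is.finite(da_ratio) || da_ratio <= 0) stop("da_ratio must be positive")
  structure(list(unmix = unmix, da_ratio = da_ratio, label = label),
            class = "ratio_tagged_sample")
}

#' Ratio-matched comparison of acceptor proportions
#'
#' Compares the mean acceptor emission proportion between two conditions,
#' restricted to samples whose donor-to-acceptor ratio lies in the band
#' common to both groups (the overlap of the groups' ratio ranges, widened by
#' `ratio_tolerance` relative on each side). Requires at least 3 matched
#' samples per group. Significance testing is delegated to a standard Welch
#' t-test, reported pass-through alongside the raw per-sample arrays.
#'
#' @param samples List of [ratio_tagged_sample()] objects.
#' @param group_a,group_b Condition labels to compare.
#' @param acceptor Name or index of the acceptor entry in each sample's
#'   unmixing proportions.
#' @param ratio_tolerance Relative widening of the common ratio band,
#'   default 0.25 (so "about 1:4" and "about 1:10" populations stay
#'   separate).
#' @return List with per-group means, `difference` (a minus b), sample
#'   sizes, per-sample proportion arrays, the matched ratio band and the
#'   delegated t-test p-value.
#' @export
ratio_matched_compare <- function(samples, group_a, group_b, acceptor = 2,
                                  ratio_tolerance = 0.25) {
  labs <- vapply(samples, `[[`, character(1), "label")
  ratios <- vapply(samples, `[[`, numeric(1), "da_ratio")
  ia <- labs == group_a; ib <- labs == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be present in samples")

  band_lo <- max(min(ratios[ia]), min(ratios[ib])) / (1 + ratio_tolerance)
  band_hi <- min(max(ratios[ia]), max(ratios[ib])) * (1 + ratio_tolerance)
  if (band_lo > band_hi)
    stop("no overlapping donor-to-acceptor ratio band between the groups")
  keep <- ratios >= band_lo & ratios <= band_hi
  ka <- ia & keep; kb <- ib & keep
  if (sum(ka) < 3 || sum(kb) < 3)
    stop("fewer than 3 ratio-matched samples in a group (",
         sum(ka), " and ", sum(kb), ")")

  prop <- vapply(samples, function(s) s$unmix$proportions[[acceptor]],
                 numeric(1))
  pa <- prop[ka]; pb <- prop[kb]
  tt <- tryCatch(stats::t.test(pa, pb),
                 error = function(e) list(p.value = NA_real_))
  list(
    mean_a = mean(pa), mean_b = mean(pb), difference = mean(pa) - mean(pb),
    n_a = sum(ka), n_b = sum(kb),
    proportions_a = pa, proportions_b = pb,
    ratio_band = c(band_lo, band_hi),
    p_value = tt$p.value
  )
}

#' Sensitized-emission / three-chromophore signature flags
#'
#' Given one lambda-stack per condition (all on one dialect, donor-band
#' normalised internally), reports the baseline-subtracted terminal-acceptor
#' band signal and the change of the intermediate band, and flags (i)
#' sensitized terminal emission — the terminal band exceeding the donor-only
#' baseline by more than `min_a2_excess` (in donor-band-normalised units;
#' the baseline terminal band is near zero, so an absolute criterion is
#' stable where a relative one is not) — and (ii) the three-chromophore
#' cascade signature: terminal band up versus baseline AND intermediate band
#' down by more than `min_a1_drop` relative versus the donor + intermediate
#' reference condition.
#'
#' @param stacks Named list of `lambda_stack`s or numeric bin vectors, one
#'   per condition; must include `baseline`.
#' @param dialect The common [detector_dialect()].
#' @param baseline Name of the donor-only condition.
#' @param di_reference Name of the donor + intermediate condition, or `NULL`
#'   (then the cascade signature is `NA`).
#' @param donor_band,a1_band,a2_band Integration bands (nm): donor band used
#'   for normalisation, intermediate (~525 nm) and terminal (~610 nm) bands.
#' @param min_a2_excess Minimum donor-band-normalised terminal-band excess,
#'   default 0.02.
#' @param min_a1_drop Minimum relative intermediate-band decrease, default
#'   0.05.
#' @return Data frame per condition: normalised band integrals, baseline
#'   excess of the terminal band, intermediate-band change, and logical
#'   columns `sensitized` and `cascade_signature`.
#' @export
sensitized_emission_flag <- function(stacks, dialect, baseline = "donor_only",
                                     di_reference = NULL,
                                     donor_band = c(465, 505),
                                     a1_band = c(515, 535),
                                     a2_band = c(595, 625),
                                     min_a2_excess = 0.02,
                                     min_a1_drop = 0.05) {
  stopifnot(inherits(dialect, "detector_dialect"))
  if (!baseline %in% names(stacks))
    stop("donor-only baseline '", baseline, "' is missing from stacks")
  edges <- dialect$grid$wavelengths
  starts <- edges[-length(edges)]
  step <- dialect$grid$step

  band_sum <- function(v, band) {
    w <- pmax(0, pmin(starts + step, band[2]) - pmax(starts, band[1])) / step
    sum(v * w)
  }
  norm_bands <- function(s) {
    v <- if (is.data.frame(s)) s$intensity else as.numeric(s)
    d <- band_sum(v, donor_band)
    if (d <= 0) stop("a stack has no signal in the donor band")
    c(donor = 1, a1 = band_sum(v, a1_band) / d, a2 = band_sum(v, a2_band) / d)
  }

  b <- lapply(stacks, norm_bands)
  base <- b[[baseline]]
  ref_a1 <- if (!is.null(di_reference)) {
    if (!di_reference %in% names(stacks))
      stop("di_reference '", di_reference, "' is missing from stacks")
    b[[di_reference]]["a1"]
  } else NA_real_
  out <- do.call(rbind, lapply(names(stacks), function(cn) {
    x <- b[[cn]]
    a2_excess <- x["a2"] - base["a2"]
    sens <- a2_excess > min_a2_excess
    casc <- if (is.na(ref_a1)) NA else
      sens && x["a1"] < ref_a1 * (1 - min_a1_drop)
    data.frame(condition = cn, a1_norm = unname(x["a1"]),
               a2_norm = unname(x["a2"]), a2_excess = unname(a2_excess),
               a1_change_vs_reference = unname(x["a1"] - ref_a1),
               sensitized = unname(sens), cascade_signature = unname(casc))
  }))
  rownames(out) <- NULL
  out
}
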