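#' Point-spread-function widths for the two imaging modalities
#'
#' Gaussian sigmas (nm) chosen so that FWHM matches the nominal resolutions:
#' conventional widefield 250 nm lateral and 200 nm axial; structured
#' illumination halves both (125 nm lateral from a doubled resolution limit,
#' 120 nm axial). FWHM = 2*sqrt(2*log(2)) * sigma.
#'
#' @param modality `"conventional"` or `"sim"` (structured illumination).
#' @return Named numeric triple `c(x, y, z)` of sigmas in nm.
#' @export
psf_sigma_nm <- function(modality = c("conventional", "sim")) {
  modality <- match.arg(modality)
  k <- 2 * sqrt(2 * log(2))
  fwhm <- switch(modality,
                 conventional = c(x = 250, y = 250, z = 200),
                 sim          = c(x = 125, y = 125, z = 120))
  fwhm / k
}

#' Simulation parameters for nucleus image stacks
#'
#' Describes how simulated nuclei are imaged: stack geometry, voxel size,
#' modality-dependent PSF, photon budget and noise. Defaults emulate 3D FISH
#' on tissue sections: 100 nm lateral sampling, a 120 nm z-step, and a photon
#' budget in the regime where centroid precision is limited by background
#' rather than photon shot noise (see the methods vignette for calibration).
#'
#' @param n_nuclei Number of nuclei to simulate.
#' @param alleles_per_nucleus Alleles (probe pairs) per nucleus, default 2.
#' @param voxel_size_nm Voxel size `c(x, y, z)` in nm.
#' @param modality `"conventional"` or `"sim"`; sets the PSF unless
#'   `psf_sigma_nm` is given explicitly.
#' @param psf_sigma_nm Optional explicit PSF sigmas `c(x, y, z)` in nm.
#' @param photons_per_spot Expected photons collected per probe spot.
#' @param background_level Mean background photons per voxel.
#' @param background_sd_frac Relative amplitude of the structured nuclear
#'   background: the mean background is modulated by a smooth random field
#'   with this standard deviation (fraction of `background_level`).
#'   Tissue-section nuclei show strong non-uniform background
#'   (autofluorescence, off-target probe binding); this is what makes
#'   centroids measured with a wide PSF less accurate than with a narrow
#'   one. Set to 0 for flat background.
#' @param background_corr_nm Correlation length of the structured
#'   background field, nm.
#' @param read_noise_sd Gaussian camera read noise, sd in counts.
#' @param stack_dim Stack size in voxels `c(nx, ny, nz)`.
#' @param seed Optional integer seed; [simulate_fish_stacks()] seeds R's RNG
#'   with it so identical parameters reproduce stacks and truth exactly.
#' @return Object of class `nucleus_sim_params`.
#' @export
nucleus_sim_params <- function(n_nuclei,
                               alleles_per_nucleus = 2L,
                               voxel_size_nm = c(100, 100, 120),
                               modality = c("conventional", "sim"),
                               psf_sigma_nm = NULL,
                               photons_per_spot = 500,
                               background_level = 20,
                               background_sd_frac = 0.5,
                               background_corr_nm = 400,
                               read_noise_sd = 2,
                               stack_dim = c(36L, 36L, 18L),
                               seed = NULL) {
  modality <- match.arg(modality)
  if (is.null(psf_sigma_nm)) psf_sigma_nm <- psf_sigma_nm(modality)
  stopifnot(n_nuclei >= 1, alleles_per_nucleus >= 1,
            length(voxel_size_nm) == 3L, all(voxel_size_nm > 0),
            length(psf_sigma_nm) == 3L, all(psf_sigma_nm > 0),
            photons_per_spot >= 0, background_level >= 0,
            background_sd_frac >= 0, background_corr_nm > 0,
            read_noise_sd >= 0,
            length(stack_dim) == 3L, all(stack_dim >= 1))
  structure(
    list(n_nuclei = as.integer(n_nuclei),
         alleles_per_nucleus = as.integer(alleles_per_nucleus),
         voxel_size_nm = as.numeric(voxel_size_nm),
         modality = modality,
         psf_sigma_nm = as.numeric(psf_sigma_nm),
         photons_per_spot = photons_per_spot,
         background_level = background_level,
         background_sd_frac = background_sd_frac,
         background_corr_nm = background_corr_nm,
         read_noise_sd = read_noise_sd,
         stack_dim = as.integer(stack_dim),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "nucleus_sim_params")
}

#' @export
print.nucleus_sim_params <- function(x, ...) {
  cat(sprintf("nucleus_sim_params: %d nuclei x %d alleles, %s modality\n",
              x$n_nuclei, x$alleles_per_nucleus, x$modality))
  cat(sprintf("  stack %dx%dx%d voxels of %gx%gx%g nm; psf sigma %.0f/%.0f/%.0f nm\n",
              x$stack_dim[1], x$stack_dim[2], x$stack_dim[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3],
              x$psf_sigma_nm[1], x$psf_sigma_nm[2], x$psf_sigma_nm[3]))
  cat(sprintf("  %g photons/spot over background %g (read noise %g); expected peak SNR %.1f\n",
              x$photons_per_spot, x$background_level, x$read_noise_sd,
              expected_peak_snr(x)))
  invisible(x)
}

# fraction of a centred spot's photons falling in the central voxel
central_voxel_fraction <- function(params) {
  v <- params$voxel_size_nm
  s <- params$psf_sigma_nm
  prod(2 * stats::pnorm(v / 2 / s) - 1)
}

#' Expected peak signal-to-noise ratio of a simulated spot
#'
#' Peak signal above background for a voxel-centred spot, divided by the
#' noise sd at that voxel (Poisson on signal plus background, plus read
#' noise).
#'
#' @param params A [nucleus_sim_params()].
#' @return Scalar SNR.
#' @export
expected_peak_snr <- function(params) {
  peak <- params$photons_per_spot * central_voxel_fraction(params)
  peak / sqrt(peak + params$background_level + params$read_noise_sd^2)
}

#' Photon budget needed for a target peak SNR
#'
#' Inverts [expected_peak_snr()] for the same PSF/voxel/noise settings.
#'
#' @param snr Target peak SNR.
#' @param params A [nucleus_sim_params()] providing PSF, voxel and noise.
#' @return Photons per spot achieving `snr`.
#' @export
photons_for_snr <- function(snr, params) {
  c0 <- params$background_level + params$read_noise_sd^2
  peak <- (snr^2 + sqrt(snr^4 + 4 * snr^2 * c0)) / 2
  peak / central_voxel_fraction(params)
}

#' Simulate ground-truth probe-pair geometry
#'
#' For each allele draws a true separation from `model`, an orientation
#' uniform on the sphere, and a placement inside the stack with enough
#' margin that both spots render fully; placements that would leave the
#' stack are resampled (bounded retries). Alleles within a nucleus are kept
#' at least `min_allele_sep_nm` apart so that pairing is unambiguous, as for
#' the two homologous alleles of a diploid nucleus.
#'
#' @param params A [nucleus_sim_params()].
#' @param model A [distance_model()].
#' @param min_allele_sep_nm Minimum distance between allele midpoints, nm.
#' @return A `data.frame` (class `sim_truth`) with one row per allele:
#'   nucleus, allele, channel-1 and channel-2 centroids (nm), true distance
#'   `d_nm` and `coloc` flag (`d_nm < 200`).
#' @export
simulate_truth <- function(params, model, min_allele_sep_nm = 1200) {
  stopifnot(inherits(params, "nucleus_sim_params"), inherits(model, "distance_model"))
  size_nm <- params$stack_dim * params$voxel_size_nm   # physical (x, y, z)
  pad <- 4 * params$psf_sigma_nm + params$voxel_size_nm
  rows <- vector("list", params$n_nuclei * params$alleles_per_nucleus)
  k <- 0L
  for (nuc in seq_len(params$n_nuclei)) {
    mids <- matrix(numeric(0), ncol = 3)
    for (al in seq_len(params$alleles_per_nucleus)) {
      ok <- FALSE
      for (try in 1:200) {
        d <- sample_pair_distance(model, 1L)
        u <- random_unit_vector()
        lo <- pad + d / 2 * abs(u)
        hi <- size_nm - pad - d / 2 * abs(u)
        if (any(hi <= lo)) next   # pair cannot fit at this d/orientation: resample
        mid <- stats::runif(3, lo, hi)
        if (nrow(mids) > 0 &&
            min(sqrt(colSums((t(mids) - mid)^2))) < min_allele_sep_nm) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place allele within the stack after bounded ",
                    "retries; enlarge 'stack_dim' or reduce 'min_allele_sep_nm'")
      c1 <- mid - d / 2 * u
      c2 <- mid + d / 2 * u
      mids <- rbind(mids, mid)
      k <- k + 1L
      rows[[k]] <- data.frame(
        nucleus = nuc, allele = al,
        x1 = c1[1], y1 = c1[2], z1 = c1[3],
        x2 = c2[1], y2 = c2[2], z2 = c2[3],
        d_nm = d, coloc = d < 200)
    }
  }
  truth <- do.call(rbind, rows)
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# expected photon counts of one spot integrated over the voxel grid;
# separable product of per-axis Gaussian integrals, returned as (z, y, x)
render_spot <- function(centroid_nm, params) {
  v <- params$voxel_size_nm
  s <- params$psf_sigma_nm
  n <- params$stack_dim
  px <- diff(stats::pnorm(((0:n[1]) * v[1] - centroid_nm[1]) / s[1]))
  py <- diff(stats::pnorm(((0:n[2]) * v[2] - centroid_nm[2]) / s[2]))
  pz <- diff(stats::pnorm(((0:n[3]) * v[3] - centroid_nm[3]) / s[3]))
  params$photons_per_spot * ((pz %o% py) %o% px)
}

# smooth multiplicative modulation of the nuclear background: white noise
# blurred to the configured correlation length, rescaled to the requested
# relative sd around 1, clamped non-negative; drawn independently per channel
background_field <- function(params) {
  dims <- params$stack_dim[c(3, 2, 1)]
  g <- array(stats::rnorm(prod(dims)), dim = dims)
  sig_vox <- params$background_corr_nm / params$voxel_size_nm[c(3, 2, 1)]
  g <- gauss_blur3(g, sig_vox)
  s <- stats::sd(g)
  if (s == 0) return(array(1, dims))
  pmax(1 + params$background_sd_frac * (g - mean(g)) / s, 0)
}

#' Render image stacks for a given ground truth
#'
#' Each allele contributes one anisotropic-Gaussian spot per channel
#' (channel 1 at its first centroid, channel 2 at its second). Expected
#' counts are background plus the spot photons integrated over each voxel;
#' observed counts are Poisson draws plus Gaussian read noise. Set
#' `noise = FALSE` for the noiseless expectation (used by localisation
#' oracles). Draws from R's global RNG.
#'
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param params The [nucleus_sim_params()] used to image it (the PSF may
#'   differ from the one the truth was built for, e.g. to image identical
#'   truth under both modalities).
#' @param noise Add Poisson + read noise? Default `TRUE`.
#' @return List of [image_stack()] objects, one per nucleus per channel.
#' @export
render_stacks <- function(truth, params, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list()
  for (nuc in unique(truth$nucleus)) {
    rows <- truth[truth$nucleus == nuc, , drop = FALSE]
    for (ch in 1:2) {
      arr <- array(params$background_level,
                   dim = params$stack_dim[c(3, 2, 1)])
      if (noise && params$background_sd_frac > 0 &&
          params$background_level > 0)
        arr <- arr * background_field(params)
      for (i in seq_len(nrow(rows))) {
        cen <- if (ch == 1) c(rows$x1[i], rows$y1[i], rows$z1[i])
               else         c(rows$x2[i], rows$y2[i], rows$z2[i])
        arr <- arr + render_spot(cen, params)
      }
      if (noise) {
        arr <- array(stats::rpois(length(arr), arr), dim = dim(arr))
        if (params$read_noise_sd > 0)
          arr <- arr + array(stats::rnorm(length(arr), 0, params$read_noise_sd),
                             dim = dim(arr))
      }
      out[[length(out) + 1L]] <-
        image_stack(arr, params$voxel_size_nm, channel = ch, nucleus = nuc)
    }
  }
  out
}

#' Simulate two-colour FISH image stacks with known ground truth
#'
#' Composes [simulate_truth()] and [render_stacks()]. If `params$seed` is
#' set, the RNG is seeded on entry, so a fixed seed reproduces both the
#' truth table and the stacks bit-identically.
#'
#' @param params A [nucleus_sim_params()].
#' @param model A [distance_model()] for the true probe separations.
#' @return List with elements `stacks` (list of [image_stack()]), `truth`
#'   (`sim_truth` data frame) and `params`.
#' @examples
#' p <- nucleus_sim_params(n_nuclei = 2, seed = 1)
#' sim <- simulate_fish_stacks(p, distance_model(0.5, 120, 800, 250))
#' sim$truth$d_nm
#' @export
simulate_fish_stacks <- function(params, model) {
  if (!is.null(params$seed)) set.seed(params$seed)
  truth <- simulate_truth(params, model)
  stacks <- render_stacks(truth, params)
  list(stacks = stacks, truth = truth, params = params)
}
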