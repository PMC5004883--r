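#' A single-channel 3D image stack
#'
#' Thin container for voxel intensities with physical calibration. The
#' intensity array is stored `[z, y, x]` (slice, row, column); physical
#' coordinates are in nm with the origin at the outer corner of voxel
#' (1,1,1), so the centre of voxel `i` along an axis is at
#' `(i - 0.5) * voxel_size`.
#'
#' @param intensities 3D numeric array, dim `(nz, ny, nx)`.
#' @param voxel_size_nm Voxel size `c(x, y, z)` in nm.
#' @param channel Channel identifier (1 or 2 for a two-colour pair).
#' @param nucleus Nucleus identifier.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel_size_nm, channel = 1L, nucleus = NA) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            all(dim(intensities) >= 1L),
            length(voxel_size_nm) == 3L, all(voxel_size_nm > 0))
  structure(list(intensities = intensities,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 channel = channel, nucleus = nucleus),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d x %d x %d voxels (x,y,z), voxel %gx%gx%g nm, channel %s, nucleus %s\n",
              d[3], d[2], d[1], x$voxel_size_nm[1], x$voxel_size_nm[2],
              x$voxel_size_nm[3], format(x$channel), format(x$nucleus)))
  invisible(x)
}

# separable Gaussian blur; sigma_vox given per array dimension (z, y, x);
# edges handled by renormalising truncated kernels (no intensity leakage)
gauss_blur3 <- function(arr, sigma_vox) {
  for (d in 1:3) {
    if (sigma_vox[d] <= 0) next
    n <- dim(arr)[d]
    r <- max(1L, as.integer(ceiling(3 * sigma_vox[d])))
    k <- stats::dnorm(-r:r, 0, sigma_vox[d])
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(d, setdiff(1:3, d))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- K %*% matrix(a, nrow = dm[1])
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Detect diffraction-limited spots in a 3D stack
#'
#' Band-pass filters the stack with a difference of Gaussians at the
#' expected spot scale, normalises to SNR units against a robust background
#' (median / MAD of the filtered volume), keeps local maxima above
#' `min_snr`, applies non-maximum suppression within `min_separation_nm`,
#' and refines each surviving maximum with [refine_centroid()].
#'
#' @param stack An [image_stack()].
#' @param min_snr Detection threshold in robust SNR units.
#' @param min_separation_nm Non-maximum suppression radius, nm.
#' @param spot_sigma_nm Expected spot sigma `c(x, y, z)` in nm (the imaging
#'   PSF); default 120 nm isotropic.
#' @param refine_radius_nm Radius of the refinement neighbourhood, nm;
#'   default `2.5 * max(spot_sigma_nm)`.
#' @param surround_factor Scale ratio of the DoG surround to the centre
#'   Gaussian (default 1.6, the usual Laplacian-of-Gaussian
#'   approximation); keeping the surround tight keeps the passband narrow,
#'   which matters when the background itself is structured.
#' @param min_rel_intensity Spots with background-subtracted integrated
#'   intensity below this fraction of the brightest spot in the stack are
#'   discarded — the usual exclusion of weak, unreliable probe signals.
#'   Set to 0 to keep everything.
#' @param max_spots Keep at most this many spots, brightest first
#'   (default `Inf`). A diploid nucleus carries two alleles, so pipelines
#'   cap detections per channel at the expected allele count.
#' @return `data.frame` with one row per spot: `x_nm, y_nm, z_nm`,
#'   `intensity` (background-subtracted integrated intensity), `snr`.
#'   Zero rows is a valid result for a blank stack.
#' @export
detect_spots <- function(stack, min_snr = 5, min_separation_nm = 400,
                         spot_sigma_nm = c(120, 120, 120),
                         refine_radius_nm = NULL, surround_factor = 1.6,
                         min_rel_intensity = 0.25, max_spots = Inf) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(refine_radius_nm)) refine_radius_nm <- 2.5 * max(spot_sigma_nm)
  v <- stack$voxel_size_nm
  sig_vox <- spot_sigma_nm[c(3, 2, 1)] / v[c(3, 2, 1)]   # (z, y, x)
  arr <- stack$intensities
  dog <- gauss_blur3(arr, sig_vox) -
    gauss_blur3(arr, surround_factor * sig_vox)
  med <- stats::median(dog)
  sc <- stats::mad(dog)
  if (sc == 0) return(empty_spots())
  snr_img <- (dog - med) / sc
  cand <- which(snr_img >= min_snr)
  if (length(cand) == 0L) return(empty_spots())
  dims <- dim(arr)
  ai <- arrayInd(cand, dims)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    z <- ai[i, 1]; y <- ai[i, 2]; x <- ai[i, 3]
    zz <- max(1, z - 1):min(dims[1], z + 1)
    yy <- max(1, y - 1):min(dims[2], y + 1)
    xx <- max(1, x - 1):min(dims[3], x + 1)
    keep[i] <- dog[z, y, x] >= max(dog[zz, yy, xx])
  }
  ai <- ai[keep, , drop = FALSE]
  if (nrow(ai) == 0L) return(empty_spots())
  vals <- dog[ai]
  ord <- order(-vals, ai[, 1], ai[, 2], ai[, 3])
  ai <- ai[ord, , drop = FALSE]
  pos <- cbind((ai[, 3] - 0.5) * v[1], (ai[, 2] - 0.5) * v[2],
               (ai[, 1] - 0.5) * v[3])
  sel <- integer(0)
  for (i in seq_len(nrow(ai))) {
    if (length(sel) == 0L ||
        min(sqrt(rowSums((pos[sel, , drop = FALSE] -
                          matrix(pos[i, ], length(sel), 3, byrow = TRUE))^2))) >=
        min_separation_nm)
      sel <- c(sel, i)
  }
  ai <- ai[sel, , drop = FALSE]
  out <- lapply(seq_len(nrow(ai)), function(i) {
    ref <- tryCatch(refine_centroid(stack, ai[i, ], refine_radius_nm),
                    error = function(e) NULL)
    if (is.null(ref)) return(NULL)
    data.frame(x_nm = ref$centroid_nm[1], y_nm = ref$centroid_nm[2],
               z_nm = ref$centroid_nm[3], intensity = ref$intensity,
               snr = snr_img[ai[i, 1], ai[i, 2], ai[i, 3]])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_spots())
  if (min_rel_intensity > 0 && nrow(out) > 1L)
    out <- out[out$intensity >= min_rel_intensity * max(out$intensity), ,
               drop = FALSE]
  if (is.finite(max_spots) && nrow(out) > max_spots)
    out <- out[order(-out$intensity)[seq_len(max_spots)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_spots <- function() {
  data.frame(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
             intensity = numeric(0), snr = numeric(0))
}

#' Sub-voxel centroid refinement
#'
#' Background-subtracted intensity-weighted centroid over an ellipsoidal
#' neighbourhood of physical radius `radius_nm` around a seed voxel. The
#' background is the stack median (per-nucleus crops are dominated by
#' background voxels); weights are clamped at zero.
#'
#' @param stack An [image_stack()].
#' @param seed_voxel Integer voxel index `c(z, y, x)` (1-based).
#' @param radius_nm Neighbourhood radius in nm.
#' @return List with `centroid_nm` (`c(x, y, z)` in nm) and `intensity`
#'   (sum of background-subtracted weights). Errors if the neighbourhood is
#'   all zero after background subtraction (e.g. a uniform image).
#' @export
refine_centroid <- function(stack, seed_voxel, radius_nm) {
  stopifnot(inherits(stack, "image_stack"), length(seed_voxel) == 3L,
            radius_nm > 0)
  dims <- dim(stack$intensities)
  if (any(seed_voxel < 1L) || any(seed_voxel > dims))
    stop("seed voxel outside the stack")
  v <- stack$voxel_size_nm   # (x, y, z)
  nr <- ceiling(radius_nm / v[c(3, 2, 1)])   # (z, y, x)
  zz <- max(1, seed_voxel[1] - nr[1]):min(dims[1], seed_voxel[1] + nr[1])
  yy <- max(1, seed_voxel[2] - nr[2]):min(dims[2], seed_voxel[2] + nr[2])
  xx <- max(1, seed_voxel[3] - nr[3]):min(dims[3], seed_voxel[3] + nr[3])
  dz <- (zz - seed_voxel[1]) * v[3]
  dy <- (yy - seed_voxel[2]) * v[2]
  dx <- (xx - seed_voxel[3]) * v[1]
  mask <- (outer(outer(dz^2, dy^2, "+"), dx^2, "+")) <= radius_nm^2
  sub <- stack$intensities[zz, yy, xx, drop = FALSE]
  bg <- stats::median(stack$intensities)
  w <- pmax(sub - bg, 0) * mask
  s <- sum(w)
  if (s <= 0) stop("all-zero neighbourhood after background subtraction")
  cz <- sum(w * array(rep(zz, times = length(yy) * length(xx)), dim(w))) / s
  cy <- sum(w * array(rep(rep(yy, each = length(zz)), times = length(xx)),
                      dim(w))) / s
  cx <- sum(w * array(rep(xx, each = length(zz) * length(yy)), dim(w))) / s
  list(centroid_nm = c((cx - 0.5) * v[1], (cy - 0.5) * v[2], (cz - 0.5) * v[3]),
       intensity = s)
}

#' Euclidean inter-probe distance
#'
#' @param a,b Centroids `c(x, y, z)` in nm (anisotropy is already applied
#'   at voxel-to-nm conversion).
#' @return Distance in nm.
#' @export
pair_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite centroid coordinates")
  stopifnot(length(a) == 3L, length(b) == 3L)
  sqrt(sum((a - b)^2))
}

#' Pair two-colour spots into alleles
#'
#' Mutual-nearest-neighbour matching between channel-1 and channel-2 spots
#' under a distance gate: spots are paired iff each is the other's nearest
#' neighbour and their distance is at most `max_gate_nm`. Each spot appears
#' in at most one pair; unpaired spots are reported separately. The default
#' gate (2000 nm) sits far above reported inter-probe medians (~140-350 nm).
#'
#' @param spots_c1,spots_c2 Spot data frames from [detect_spots()] for the
#'   two channels of one nucleus.
#' @param max_gate_nm Pairing gate, nm.
#' @return List with `pairs` (data frame `idx1, idx2, d_nm` sorted by
#'   channel-1 index) and `unpaired_c1`, `unpaired_c2` (integer indices).
#' @export
pair_probes <- function(spots_c1, spots_c2, max_gate_nm = 2000) {
  n1 <- nrow(spots_c1); n2 <- nrow(spots_c2)
  empty <- data.frame(idx1 = integer(0), idx2 = integer(0), d_nm = numeric(0))
  if (n1 == 0L || n2 == 0L)
    return(list(pairs = empty, unpaired_c1 = seq_len(n1),
                unpaired_c2 = seq_len(n2)))
  p1 <- as.matrix(spots_c1[, c("x_nm", "y_nm", "z_nm")])
  p2 <- as.matrix(spots_c2[, c("x_nm", "y_nm", "z_nm")])
  dmat <- sqrt(outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2))
  dmat[dmat < 0 | is.nan(dmat)] <- 0
  nn1 <- apply(dmat, 1, which.min)   # ties -> smaller index
  nn2 <- apply(dmat, 2, which.min)
  idx1 <- which(nn2[nn1] == seq_len(n1) & dmat[cbind(seq_len(n1), nn1)] <= max_gate_nm)
  pairs <- data.frame(idx1 = idx1, idx2 = nn1[idx1],
                      d_nm = dmat[cbind(idx1, nn1[idx1])])
  pairs <- pairs[order(pairs$idx1), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_c1 = setdiff(seq_len(n1), pairs$idx1),
       unpaired_c2 = setdiff(seq_len(n2), pairs$idx2))
}

#' Quantify one nucleus: detect in both channels and pair
#'
#' @param stack_c1,stack_c2 The two channel stacks of one nucleus.
#' @param registration_offset_nm Optional rigid chromatic offset
#'   `c(x, y, z)` in nm added to channel-2 centroids before pairing.
#' @param ... Passed to [detect_spots()].
#' @inheritParams pair_probes
#' @return As [pair_probes()], plus elements `spots_c1`, `spots_c2`.
#' @export
quantify_nucleus <- function(stack_c1, stack_c2, max_gate_nm = 2000,
                             registration_offset_nm = c(0, 0, 0), ...) {
  s1 <- detect_spots(stack_c1, ...)
  s2 <- detect_spots(stack_c2, ...)
  if (nrow(s2) > 0)
    s2[, c("x_nm", "y_nm", "z_nm")] <-
      sweep(as.matrix(s2[, c("x_nm", "y_nm", "z_nm")]), 2,
            -as.numeric(registration_offset_nm))
  res <- pair_probes(s1, s2, max_gate_nm = max_gate_nm)
  res$spots_c1 <- s1
  res$spots_c2 <- s2
  res
}
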