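make_spot_stack <- function(centroids, params, noise = TRUE) {
  # render one or more spots at given nm centroids into a single stack
  arr <- array(params$background_level, dim = params$stack_dim[c(3, 2, 1)])
  for (i in seq_len(nrow(centroids)))
    arr <- arr + chromprox:::render_spot(centroids[i, ], params)
  if (noise) {
    arr <- array(rpois(length(arr), arr), dim = dim(arr))
    arr <- arr + array(rnorm(length(arr), 0, params$read_noise_sd), dim(arr))
  }
  image_stack(arr, params$voxel_size_nm)
}

test_that("a blank stack yields no spots", {
  p <- bright_params(1)
  set.seed(1)
  arr <- array(rpois(prod(p$stack_dim), p$background_level),
               dim = p$stack_dim[c(3, 2, 1)])
  st <- image_stack(arr, p$voxel_size_nm)
  sp <- detect_spots(st, min_snr = 6, spot_sigma_nm = p$psf_sigma_nm)
  expect_equal(nrow(sp), 0L)
})

test_that("single and double spots are detected at high SNR", {
  p <- bright_params(1, snr = 10)
  set.seed(4)
  cen <- matrix(c(1800, 1700, 1100), 1)
  st <- make_spot_stack(cen, p)
  sp <- detect_spots(st, min_snr = 6, spot_sigma_nm = p$psf_sigma_nm)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_nm - 1800), p$voxel_size_nm[1])
  expect_lt(abs(sp$y_nm - 1700), p$voxel_size_nm[2])
  expect_lt(abs(sp$z_nm - 1100), p$voxel_size_nm[3])
  # two spots separated by 5 lateral sigma resolve into two detections
  sep <- 5 * p$psf_sigma_nm[1]
  cen2 <- rbind(c(1500, 1600, 1000), c(1500 + sep, 1600, 1000))
  st2 <- make_spot_stack(cen2, p)
  sp2 <- detect_spots(st2, min_snr = 6, spot_sigma_nm = p$psf_sigma_nm,
                      min_separation_nm = 300)
  expect_equal(nrow(sp2), 2L)
})

test_that("centroid refinement is symmetric and sub-voxel accurate", {
  p <- bright_params(1)
  v <- p$voxel_size_nm
  # spot centred exactly on a voxel centre: centroid must be that centre
  cen <- c(17.5 * v[1], 16.5 * v[2], 8.5 * v[3])
  st <- make_spot_stack(matrix(cen, 1), p, noise = FALSE)
  seed <- c(9, 17, 18)   # (z, y, x) voxel containing the centre
  ref <- refine_centroid(st, seed, radius_nm = 400)
  expect_equal(ref$centroid_nm, cen, tolerance = 1e-6)
  # off-grid spot recovered within 0.05 voxel (noiseless)
  set.seed(9)
  for (rep in 1:5) {
    cen2 <- cen + runif(3, -0.5, 0.5) * v
    st2 <- make_spot_stack(matrix(cen2, 1), p, noise = FALSE)
    ref2 <- refine_centroid(st2, seed, radius_nm = 400)
    expect_true(all(abs(ref2$centroid_nm - cen2) / v < 0.05))
  }
})

test_that("refinement errors on uniform input and bad seeds", {
  st <- image_stack(array(5, dim = c(8, 10, 10)), c(100, 100, 120))
  expect_error(refine_centroid(st, c(4, 5, 5), 300), "all-zero")
  expect_error(refine_centroid(st, c(99, 5, 5), 300), "outside")
})

test_that("pair_distance is exact Euclidean geometry", {
  expect_equal(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # 3-4-5 triangle on the voxel grid (voxel 100 x 100 x 120 nm)
  a <- c(1 * 100, 2 * 100, 3 * 120)
  b <- c(4 * 100, 6 * 100, 3 * 120)
  expect_equal(pair_distance(a, b), 500)
  set.seed(10)
  for (i in 1:20) {
    u <- runif(3, 0, 3000); w <- runif(3, 0, 3000)
    expect_equal(pair_distance(u, w),
                 sqrt((u[1] - w[1])^2 + (u[2] - w[2])^2 + (u[3] - w[3])^2),
                 tolerance = 1e-9)
  }
  expect_error(pair_distance(c(1, NA, 3), c(0, 0, 0)), "non-finite")
  expect_error(pair_distance(c(1, Inf, 3), c(0, 0, 0)), "non-finite")
})

spots_df <- function(m) {
  data.frame(x_nm = m[, 1], y_nm = m[, 2], z_nm = m[, 3],
             intensity = 1, snr = 10)
}

test_that("mutual-nearest-neighbour pairing matches brute force", {
  # one spot per channel, 150 nm apart
  s1 <- spots_df(matrix(c(1000, 1000, 1000), 1))
  s2 <- spots_df(matrix(c(1150, 1000, 1000), 1))
  res <- pair_probes(s1, s2, max_gate_nm = 2000)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$d_nm, 150)
  # no partner within the gate
  res2 <- pair_probes(s1, spots_df(matrix(c(9000, 9000, 9000), 1)), 2000)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$unpaired_c1, 1L)
  expect_equal(res2$unpaired_c2, 1L)
  # two well-separated alleles: identical to minimum-total-distance assignment
  set.seed(21)
  for (rep in 1:10) {
    base <- matrix(runif(6, 500, 3000), 2, 3)
    base[2, ] <- base[1, ] + c(1800, 1200, 600)   # far apart
    off <- matrix(rnorm(6, 0, 80), 2, 3)
    p1 <- base; p2 <- base + off
    res3 <- pair_probes(spots_df(p1), spots_df(p2), 2000)
    oracle <- pairing_oracle(p1, p2, 2000)
    expect_equal(res3$pairs$idx1, oracle$idx1)
    expect_equal(res3$pairs$idx2, oracle$idx2)
    expect_equal(res3$pairs$d_nm, oracle$d_nm, tolerance = 1e-9)
  }
})

test_that("pairing is symmetric in channel order and list order", {
  set.seed(33)
  p1 <- matrix(runif(9, 200, 3000), 3, 3)
  p2 <- p1[c(2, 3, 1), ] + matrix(rnorm(9, 0, 60), 3, 3)
  a <- pair_probes(spots_df(p1), spots_df(p2), 2000)
  b <- pair_probes(spots_df(p2), spots_df(p1), 2000)
  ford <- a$pairs[order(a$pairs$d_nm), "d_nm"]
  bord <- b$pairs[order(b$pairs$d_nm), "d_nm"]
  expect_equal(ford, bord, tolerance = 1e-9)
  # permuting a spot list permutes indices but not the matched distances
  perm <- c(3, 1, 2)
  c2 <- pair_probes(spots_df(p1[perm, ]), spots_df(p2), 2000)
  expect_equal(sort(c2$pairs$d_nm), sort(a$pairs$d_nm), tolerance = 1e-9)
})

test_that("end-to-end recovery at SNR >= 10 finds nearly all alleles", {
  m <- distance_model_for_fraction(0.5)
  p <- bright_params(25, seed = 8, snr = 12)
  sim <- simulate_fish_stacks(p, m)
  ds <- quantify_simulation(sim, list(min_snr = 6))
  expect_gte(nrow(ds) / nrow(sim$truth), 0.95)
  err <- vapply(seq_len(nrow(ds)), function(i) {
    tr <- sim$truth[sim$truth$nucleus == ds$nucleus[i], ]
    min(abs(tr$d_nm - ds$d_nm[i]))
  }, numeric(1))
  expect_lt(median(err), p$voxel_size_nm[3])
})
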