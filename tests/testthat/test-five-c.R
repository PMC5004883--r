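toy_map <- function(n = 12, len = 1000, chrom = "chrT") {
  frags <- data.frame(chrom = chrom, start = (0:(n - 1)) * len,
                      end = (1:n) * len)
  frags$length <- len; frags$index <- seq_len(n)
  attr(frags, "region") <- c(0, n * len)
  assign_primers(frags)
}

test_that("digestion follows the A^AGCTT cut convention", {
  fr <- digest_sequence("AAAAGCTTAA")
  expect_equal(fr$start, c(0, 3))
  expect_equal(fr$end, c(3, 10))
  # no site: one fragment spanning everything
  fr2 <- digest_sequence("ACGTACGTACGT")
  expect_equal(nrow(fr2), 1L)
  expect_equal(fr2$length, 12L)
  expect_error(digest_sequence("ACGT", site = "AANGG"), "N")
  expect_error(digest_sequence("ACG", site = "AAGCTT"), "longer")
  expect_error(digest_sequence("ACGJ"), "A,C,G,T,N")
})

test_that("digestion cut set equals a naive substring scan", {
  set.seed(19)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  fr <- digest_sequence(seq)
  cuts <- fr$end[-nrow(fr)]
  expect_equal(cuts, digest_oracle(seq, "AAGCTT", 1))
  # fragments tile the sequence exactly
  expect_equal(fr$start[1], 0)
  expect_equal(fr$end[nrow(fr)], 10000)
  expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))
})

test_that("primer assignment filters by size and alternates orientations", {
  frags <- data.frame(chrom = "chrT",
                      start = cumsum(c(0, 50, 5000, 25000)),
                      end = cumsum(c(50, 5000, 25000, 3000)))
  frags$length <- frags$end - frags$start
  frags$index <- 1:4
  map <- assign_primers(frags)
  expect_equal(map$eligible, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(map$orientation[map$eligible], c("reverse", "forward"))
  expect_true(all(map$orientation[!map$eligible] == "none"))
  # a 365-primer design splits 183 reverse / 182 forward
  frags365 <- data.frame(chrom = "chrT", start = (0:364) * 1000,
                         end = (1:365) * 1000, length = 1000, index = 1:365)
  map365 <- assign_primers(frags365)
  expect_equal(sum(map365$orientation == "reverse"), 183L)
  expect_equal(sum(map365$orientation == "forward"), 182L)
  # nothing eligible -> an empty map is fine
  tiny <- data.frame(chrom = "chrT", start = c(0, 10), end = c(10, 20),
                     length = 10, index = 1:2)
  expect_equal(sum(assign_primers(tiny)$eligible), 0L)
})

test_that("forward/reverse parity holds for arbitrary fragment sets", {
  set.seed(23)
  for (rep in 1:50) {
    n <- sample(1:60, 1)
    lens <- sample(c(30, 500, 2000, 8000, 30000), n, replace = TRUE)
    frags <- data.frame(chrom = "chrT", start = cumsum(c(0, lens[-n])),
                        end = cumsum(lens), length = lens, index = seq_len(n))
    map <- assign_primers(frags)
    expect_lte(abs(sum(map$orientation == "forward") -
                   sum(map$orientation == "reverse")), 1L)
  }
})

test_that("normalisation is raw / total x 1000 and scale-exact", {
  map <- toy_map()
  raw <- matrix(0L, 6, 6); raw[1, 1] <- 5L
  cm <- normalize_counts(contact_matrix(map, raw, total_reads = 10000))
  expect_equal(cm$norm[1, 1], 0.5)
  expect_true(all(cm$norm[-1] == 0))
  # total = grand sum -> normalised entries sum to exactly 1000
  raw2 <- matrix(rpois(36, 4), 6, 6)
  cm2 <- normalize_counts(contact_matrix(map, raw2))
  expect_equal(sum(cm2$norm), 1000, tolerance = 1e-9)
  # multiplying raw and total by k leaves frequencies unchanged
  cm3 <- normalize_counts(contact_matrix(map, raw2 * 7L,
                                         total_reads = sum(raw2) * 7))
  expect_equal(cm3$norm, cm2$norm, tolerance = 1e-12)
  expect_error(normalize_counts(contact_matrix(map, raw, total_reads = 0)),
               "positive")
})

test_that("window binning averages normalised pair frequencies", {
  map <- toy_map(n = 4, len = 1000)   # R F R F over [0, 4000)
  raw <- matrix(0L, 2, 2)
  cm <- contact_matrix(map, raw, total_reads = 1000)
  cm$norm <- matrix(c(1, 0, 3, 0), 2, 2)   # two pairs in window pair (1,1)
  # fragments 1-4 mids 500,1500,2500,3500; window 2000 -> windows 1,1,2,2
  # norm rows = forward frags (2,4), cols = reverse frags (1,3)
  b <- bin_matrix(cm, window_bp = 2000)
  # pairs in (w1,w1): F2xR1 = 1; (w1,w2): F2xR3=3, F4xR1=0; (w2,w2): F4xR3=0
  expect_equal(b$values[1, 1], 1)
  expect_equal(b$values[1, 2], 1.5)
  expect_equal(b$values[2, 1], 1.5)
  expect_equal(b$values[2, 2], 0)
  # one fragment pair per window pair: binning is the identity
  map1 <- toy_map(n = 2, len = 1000)
  cm1 <- contact_matrix(map1, matrix(4L, 1, 1), total_reads = 8)
  cm1 <- normalize_counts(cm1)
  b1 <- bin_matrix(cm1, window_bp = 1000)
  expect_equal(b1$values[1, 2], cm1$norm[1, 1])
  expect_error(bin_matrix(cm1, window_bp = 0), "positive")
  expect_error(bin_matrix(contact_matrix(map1, matrix(1L, 1, 1)), 1000),
               "normalise")
})

test_that("binning equals the quadratic-time oracle on random matrices", {
  set.seed(31)
  n <- 50
  lens <- sample(500:4000, n, replace = TRUE)
  frags <- data.frame(chrom = "chrT", start = cumsum(c(0, lens[-n])),
                      end = cumsum(lens), length = lens, index = seq_len(n))
  attr(frags, "region") <- c(0, sum(lens))
  map <- assign_primers(frags)
  nf <- sum(map$orientation == "forward")
  nr <- sum(map$orientation == "reverse")
  cm <- normalize_counts(contact_matrix(map, matrix(rpois(nf * nr, 3), nf, nr)))
  for (w in c(7000, 28000)) {
    b <- bin_matrix(cm, window_bp = w)
    expect_equal(b$values, bin_oracle(cm, w), tolerance = 1e-12)
    # symmetry, and missing stays missing
    expect_identical(b$values, t(b$values))
  }
})

test_that("virtual 4C extracts the masked matrix row", {
  map <- toy_map(n = 12, len = 1000)
  nf <- sum(map$orientation == "forward")
  nr <- sum(map$orientation == "reverse")
  set.seed(41)
  cm <- normalize_counts(contact_matrix(map, matrix(rpois(nf * nr, 6), nf, nr)))
  b <- bin_matrix(cm, window_bp = 2000)
  # single-window viewpoint: the track is that row with the diagonal masked
  tr <- virtual_4c(b, c(2000, 4000))
  expect_equal(tr$value[-2], b$values[2, -2], tolerance = 1e-12)
  expect_true(is.na(tr$value[2]))
  # symmetric matrix: row and column viewpoints agree
  trc <- virtual_4c(b, c(2000, 4000))
  expect_equal(tr$value, trc$value, tolerance = 1e-12)
  expect_error(virtual_4c(b, c(5e6, 6e6)), "outside")
})

test_that("an enriched pair dominates its viewpoint track", {
  map <- simulate_fragment_map(region = c(0, 5e5), chrom = "chrT", seed = 3)
  model <- contact_model(region = c(0, 5e5), domain_boundaries = numeric(0),
                         peak_pairs = list(list(a = c(10000, 20000),
                                                b = c(400000, 410000),
                                                fold = 12)),
                         total_reads = 2e5, seed = 4)
  cm <- normalize_counts(simulate_contact_counts(map, model))
  b <- bin_matrix(cm, window_bp = 10000)
  tr <- virtual_4c(b, c(10000, 20000))
  far <- which(b$windows$start >= 3e5)   # outside the decay neighbourhood
  expect_equal(far[which.max(tr$value[far])],
               which(b$windows$start == 400000))
})

test_that("insulation boundaries: none on uniform, two on three domains", {
  # uniform matrix -> no boundaries
  map <- toy_map(n = 40, len = 1000)
  W <- 20
  bu <- structure(list(values = matrix(1, W, W),
                       windows = data.frame(start = (0:(W - 1)) * 2000,
                                            end = (1:W) * 2000),
                       window_bp = 2000, chrom = "chrT"),
                  class = "binned_matrix")
  expect_equal(nrow(insulation_boundaries(bu)), 0L)
  expect_error(insulation_score(bu, flank_windows = 12), "few")
  # three-domain simulated matrix: both boundaries within one window
  map2 <- simulate_fragment_map(region = c(0, 1.4e6), chrom = "chrT", seed = 6)
  model <- contact_model(region = c(0, 1.4e6),
                         domain_boundaries = c(450000, 950000),
                         inter_domain_factor = 0.2, peak_pairs = list(),
                         total_reads = 2e5, seed = 8)
  cm <- normalize_counts(simulate_contact_counts(map2, model))
  b <- bin_matrix(cm, window_bp = 28000)
  bd <- insulation_boundaries(b)
  expect_equal(nrow(bd), 2L)
  true_w <- floor(c(450000, 950000) / 28000) + 1
  expect_true(all(abs(bd$window - true_w) <= 1))
  # decay-only matrix: no boundaries
  model0 <- contact_model(region = c(0, 1.4e6), domain_boundaries = numeric(0),
                          peak_pairs = list(), total_reads = 2e5, seed = 9)
  cm0 <- normalize_counts(simulate_contact_counts(map2, model0))
  expect_equal(nrow(insulation_boundaries(bin_matrix(cm0, 28000))), 0L)
})
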