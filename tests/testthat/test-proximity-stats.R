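test_that("distance classes partition at the 200/400 nm thresholds", {
  expect_equal(as.character(classify_distance(c(0, 250, 450))),
               c("colocalised", "adjacent", "separate"))
  # boundaries are half-open: exactly 200 is adjacent, exactly 400 separate
  expect_equal(as.character(classify_distance(c(199.999, 200, 399.999, 400))),
               c("colocalised", "adjacent", "adjacent", "separate"))
  expect_error(classify_distance(-1), "non-negative")
  # every distance maps to exactly one category
  set.seed(1)
  d <- runif(1000, 0, 1500)
  expect_false(any(is.na(classify_distance(d))))
})

test_that("binned proportions match direct counting", {
  ds <- distance_dataset(c(100, 100, 300, 500))
  b <- bin_distances(ds)
  expect_equal(b$proportion, c(0.5, 0.25, 0.25))
  expect_equal(sum(b$proportion), 1, tolerance = 1e-9)
  # all mass in one bin
  b2 <- bin_distances(distance_dataset(rep(150, 7)))
  expect_equal(b2$proportion, 1)
  # random data against the brute-force histogram oracle
  set.seed(14)
  d <- rgamma(500, 2, 1 / 200)
  b3 <- bin_distances(distance_dataset(d))
  expect_equal(b3$proportion, hist_oracle(d, 200, nrow(b3)), tolerance = 1e-12)
  expect_equal(sum(b3$proportion), 1, tolerance = 1e-9)
  # first two bins equal colocalised + adjacent fractions
  cls <- classify_distance(d)
  expect_equal(b3$proportion[1] + b3$proportion[2],
               mean(cls != "separate"), tolerance = 1e-12)
  expect_error(bin_distances(distance_dataset(numeric(0))), "empty")
})

test_that("s.e.m. is computed across sections, not alleles", {
  # one section: sem undefined
  one <- distance_dataset(c(100, 300), section = 1)
  cf <- coloc_frequency(one)
  expect_equal(cf$proportion, 0.5)
  expect_true(is.na(cf$sem))
  # two equal-n sections with per-section proportions 0.4 / 0.6
  d <- c(rep(100, 4), rep(300, 6), rep(100, 6), rep(300, 4))
  two <- distance_dataset(d, section = rep(c(1, 2), each = 10))
  cf2 <- coloc_frequency(two)
  expect_equal(cf2$proportion, 0.5)
  expect_equal(cf2$sem, sd(c(0.4, 0.6)) / sqrt(2))
  # binned sem agrees for the first bin
  b <- bin_distances(two)
  expect_equal(b$sem[1], cf2$sem)
  # pooled estimate invariant to section relabelling
  relab <- two
  relab$section <- rep(c("b", "a"), each = 10)
  expect_equal(coloc_frequency(relab)$proportion, cf2$proportion)
  expect_equal(coloc_frequency(relab)$sem, cf2$sem)
})

test_that("coloc_frequency recovers a known simulated fraction", {
  m <- distance_model_for_fraction(0.35)
  set.seed(77)
  d <- sample_pair_distance(m, 120)
  ds <- distance_dataset(d, section = rep(1:2, each = 60))
  cf <- coloc_frequency(ds)
  expect_lt(abs(cf$proportion - 0.35), 3 * sqrt(0.35 * 0.65 / 120))
})

test_that("per-cell allele categories count both/one/none", {
  d <- c(100, 150, 100, 500, 500, 600)
  ds <- distance_dataset(d, nucleus = rep(1:3, each = 2),
                         allele = rep(1:2, 3))
  ac <- allele_categories(ds)
  expect_equal(unname(ac$fractions), c(1, 1, 1) / 3)
  expect_equal(sum(ac$fractions), 1)
  expect_equal(ac$n_excluded, 0L)
  # nuclei without exactly two measured alleles are excluded but counted
  ds2 <- distance_dataset(c(d, 100), nucleus = c(rep(1:3, each = 2), 4))
  ac2 <- allele_categories(ds2)
  expect_equal(ac2$n_nuclei, 3L)
  expect_equal(ac2$n_excluded, 1L)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  t2 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact(t2), fisher_oracle(t2), tolerance = 1e-12)
  t3 <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact(t3), fisher_oracle(t3), tolerance = 1e-12)
  # zero-margin tables are defined as p = 1
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2)), 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Mann-Whitney matches rank enumeration", {
  # identical samples (with ties): U = n^2/2 and p ~ 1
  x <- c(1, 2, 3, 4)
  mw <- mann_whitney(x, x)
  expect_equal(mw$U, length(x)^2 / 2)
  expect_gt(mw$p, 0.95)
  # complete separation of 3 vs 3: U = 0, exact p = 0.1
  mw2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw2$U, 0)
  expect_equal(mw2$p, 0.1, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # random small samples against full enumeration
  set.seed(5)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1000, n1 + n2)   # distinct -> no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    mw3 <- mann_whitney(x, y)
    or <- mw_oracle(x, y)
    expect_equal(mw3$U, or$U)
    expect_equal(mw3$p, or$p, tolerance = 1e-12)
  }
})

test_that("boxplot summaries follow the 95%-range convention", {
  s <- summarize_box(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  s2 <- summarize_box(rep(7, 10))
  expect_equal(s2$q1, 7); expect_equal(s2$whisker_high, 7)
  set.seed(6)
  d <- rlnorm(200, 5, 0.4)
  s3 <- summarize_box(d)
  q <- quantile(d, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  expect_equal(c(s3$whisker_low, s3$q1, s3$median, s3$q3, s3$whisker_high),
               q, tolerance = 1e-12)
  expect_true(s3$whisker_low <= s3$q1 && s3$q1 <= s3$median &&
              s3$median <= s3$q3 && s3$q3 <= s3$whisker_high)
  expect_error(summarize_box(numeric(0)), "empty")
})

test_that("group comparison table carries both tests for each pair", {
  set.seed(8)
  ds <- list(a = distance_dataset(sample_pair_distance(distance_model_for_fraction(0.7), 80)),
             b = distance_dataset(sample_pair_distance(distance_model_for_fraction(0.2), 80)))
  cmp <- compare_groups(ds)
  expect_equal(nrow(cmp), 2L)
  expect_setequal(cmp$test, c("fisher_exact", "mann_whitney"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_lt(cmp$p[cmp$test == "fisher_exact"], 0.001)
})
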