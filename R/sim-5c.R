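#' Generative model for 5C contact counts
#'
#' Expected contacts between two fragments follow a power-law decay in
#' genomic separation, attenuated by a multiplicative factor for every
#' interaction-domain boundary the pair straddles, and amplified over
#' declared peak pairs (e.g. an enriched gene-enhancer contact). Observed
#' counts are a single multinomial draw of `total_reads` over all
#' forward x reverse fragment pairs. Defaults sketch the ~1.7 Mb regulatory
#' landscape the package targets: a three-domain structure whose middle
#' domain contains both a gene and its distal limb enhancer, with an
#' enriched contact between them.
#'
#' @param region Genomic interval `c(start, end)`, 0-based half-open.
#' @param domain_boundaries Strictly increasing positions inside `region`
#'   partitioning it into domains (two boundaries give three domains).
#' @param decay_exponent Power-law exponent for within-domain decay (> 0).
#' @param inter_domain_factor Multiplier in (0, 1] applied once per
#'   boundary a fragment pair straddles.
#' @param peak_pairs List of `list(a = c(start, end), b = c(start, end),
#'   fold = f)` with `fold >= 1`.
#' @param total_reads Total read count of the simulated run.
#' @param seed Optional integer seed used by [simulate_contact_counts()].
#' @return Object of class `contact_model`.
#' @export
contact_model <- function(region = c(28317086, 30005000),
                          domain_boundaries = c(28650000, 29900000),
                          decay_exponent = 1.0,
                          inter_domain_factor = 0.3,
                          peak_pairs = list(list(a = c(28779000, 28790000),
                                                 b = c(29760000, 29771000),
                                                 fold = 3)),
                          total_reads = 1e6,
                          seed = NULL) {
  stopifnot(length(region) == 2L, region[1] < region[2])
  if (length(domain_boundaries) > 1 && any(diff(domain_boundaries) <= 0))
    stop("'domain_boundaries' must be strictly increasing")
  if (length(domain_boundaries) > 0 &&
      (any(domain_boundaries <= region[1]) ||
       any(domain_boundaries >= region[2])))
    stop("'domain_boundaries' must lie strictly inside the region")
  if (decay_exponent <= 0) stop("'decay_exponent' must be positive")
  if (inter_domain_factor <= 0 || inter_domain_factor > 1)
    stop("'inter_domain_factor' must lie in (0, 1]")
  for (p in peak_pairs)
    if (p$fold < 1) stop("peak enrichment folds must be >= 1")
  if (total_reads <= 0) stop("'total_reads' must be positive")
  structure(list(region = as.numeric(region),
                 domain_boundaries = as.numeric(domain_boundaries),
                 decay_exponent = decay_exponent,
                 inter_domain_factor = inter_domain_factor,
                 peak_pairs = peak_pairs,
                 total_reads = total_reads,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("contact_model: region %d-%d, %d domain(s), decay %.2f, inter-domain factor %.2f\n",
              x$region[1], x$region[2], length(x$domain_boundaries) + 1L,
              x$decay_exponent, x$inter_domain_factor))
  cat(sprintf("  %d peak pair(s); %s total reads\n", length(x$peak_pairs),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Expected (unnormalised) contact intensities
#'
#' The deterministic expectation surface of [contact_model()] over the
#' forward x reverse fragment pairs of a map, before multinomial sampling.
#' Depends only on the unordered fragment pair.
#'
#' @param map A [assign_primers()] fragment map.
#' @param model A [contact_model()].
#' @return Matrix `n_forward x n_reverse` of relative intensities.
#' @export
expected_contacts <- function(map, model) {
  stopifnot(inherits(map, "fragment_map"), inherits(model, "contact_model"))
  fwd <- which(map$orientation == "forward")
  rev <- which(map$orientation == "reverse")
  if (length(fwd) == 0L || length(rev) == 0L) stop("empty fragment map")
  mid <- (map$start + map$end) / 2
  mf <- mid[fwd]; mr <- mid[rev]
  dist <- abs(outer(mf, mr, "-"))
  dist[dist < 1] <- 1
  lam <- dist^(-model$decay_exponent)
  if (length(model$domain_boundaries) > 0) {
    domf <- findInterval(mf, model$domain_boundaries)
    domr <- findInterval(mr, model$domain_boundaries)
    ncross <- abs(outer(domf, domr, "-"))
    lam <- lam * model$inter_domain_factor^ncross
  }
  for (p in model$peak_pairs) {
    inA_f <- mf >= p$a[1] & mf < p$a[2]; inB_f <- mf >= p$b[1] & mf < p$b[2]
    inA_r <- mr >= p$a[1] & mr < p$a[2]; inB_r <- mr >= p$b[1] & mr < p$b[2]
    hit <- outer(inA_f, inB_r, "&") | outer(inB_f, inA_r, "&")
    lam[hit] <- lam[hit] * p$fold
  }
  lam
}

#' Simulate 5C contact counts with known structure
#'
#' Draws raw counts as a multinomial over all forward x reverse fragment
#' pairs with probabilities proportional to [expected_contacts()] and total
#' equal to `model$total_reads` (counts always sum to the total exactly).
#' Seeds R's RNG with `model$seed` when set, so a fixed seed reproduces the
#' count matrix bit-identically.
#'
#' @param map A [assign_primers()] fragment map.
#' @param model A [contact_model()].
#' @return A raw [contact_matrix()] with `total_reads = model$total_reads`.
#' @export
simulate_contact_counts <- function(map, model) {
  lam <- expected_contacts(map, model)
  if (!is.null(model$seed)) set.seed(model$seed)
  counts <- stats::rmultinom(1, size = model$total_reads,
                             prob = as.vector(lam / sum(lam)))
  contact_matrix(map, matrix(counts, nrow(lam), ncol(lam)),
                 total_reads = model$total_reads)
}

#' Simulate a restriction fragment map for a region
#'
#' Draws a uniform random DNA sequence of the region's width, digests it
#' with the restriction site (HindIII by default, giving ~4 kb mean
#' fragments), and assigns alternating primers. A convenient scaffold for
#' simulated 5C experiments when no reference sequence is at hand.
#'
#' @param region Genomic interval `c(start, end)`, 0-based half-open.
#' @param chrom Chromosome label.
#' @param site Restriction site, default `"AAGCTT"`.
#' @param seed Optional integer seed.
#' @param ... Passed to [assign_primers()].
#' @return A `fragment_map` whose coordinates start at `region[1]`.
#' @export
simulate_fragment_map <- function(region = c(28317086, 30005000),
                                  chrom = "chr5", site = "AAGCTT",
                                  seed = NULL, ...) {
  stopifnot(region[1] < region[2])
  if (!is.null(seed)) set.seed(seed)
  n <- region[2] - region[1]
  seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
  frags <- digest_sequence(seq, site = site, chrom = chrom,
                           offset = region[1])
  assign_primers(frags, ...)
}
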