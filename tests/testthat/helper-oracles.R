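# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

# two-sided Fisher p by full hypergeometric enumeration with the
# minimum-likelihood rule (1 + 1e-7 relative tolerance on the observed
# table's probability)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# exact Mann-Whitney two-sided p by enumerating every assignment of the
# pooled ranks to sample x (no ties); doubling rule as in common practice
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  p <- if (u_obs > n1 * n2 / 2) mean(us >= u_obs) else mean(us <= u_obs)
  list(U = u_obs, p = min(2 * p, 1))
}

# histogram proportions by direct counting
hist_oracle <- function(d, width, nbins) {
  counts <- vapply(seq_len(nbins), function(k)
    sum(d >= (k - 1) * width & d < k * width), numeric(1))
  counts / length(d)
}

# minimum-total-distance pairing by enumerating all injective assignments
pairing_oracle <- function(p1, p2, gate) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  k <- min(n1, n2)
  best <- NULL; best_cost <- Inf
  sub1 <- utils::combn(n1, k, simplify = FALSE)
  for (s1 in sub1) {
    perms2 <- all_perms(n2, k)
    for (s2 in perms2) {
      d <- sqrt(rowSums((p1[s1, , drop = FALSE] - p2[s2, , drop = FALSE])^2))
      if (any(d > gate)) next
      if (sum(d) < best_cost) {
        best_cost <- sum(d)
        best <- data.frame(idx1 = s1, idx2 = s2, d_nm = d)
      }
    }
  }
  best
}

all_perms <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (s in utils::combn(n, k, simplify = FALSE)) {
    perm_rec <- function(v) {
      if (length(v) == 1) return(list(v))
      res <- list()
      for (i in seq_along(v))
        for (p in perm_rec(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
      res
    }
    out <- c(out, perm_rec(s))
  }
  out
}

# restriction-cut positions by naive substring scan
digest_oracle <- function(seq, site, cut_offset) {
  n <- nchar(seq); m <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(n - m + 1))
    if (substr(seq, i, i + m - 1) == site) cuts <- c(cuts, i - 1 + cut_offset)
  sort(unique(cuts[cuts > 0 & cuts < n]))
}

# window-pair means by a quadratic double loop over fragment pairs
bin_oracle <- function(m, window_bp) {
  region <- attr(m$map, "region")
  nW <- length(seq(region[1], region[2] - 1, by = window_bp))
  w_of <- function(pos) min(floor((pos - region[1]) / window_bp) + 1, nW)
  mid <- (m$map$start + m$map$end) / 2
  vals <- matrix(NA_real_, nW, nW)
  for (u in 1:nW) for (v in u:nW) {
    acc <- c()
    for (i in seq_along(m$fwd)) for (j in seq_along(m$rev)) {
      wi <- w_of(mid[m$fwd[i]]); wj <- w_of(mid[m$rev[j]])
      if ((wi == u && wj == v) || (wi == v && wj == u))
        acc <- c(acc, m$norm[i, j])
    }
    if (length(acc)) vals[u, v] <- vals[v, u] <- mean(acc)
  }
  vals
}

# convenience: a bright, low-noise simulation whose spots are easy to find
bright_params <- function(n_nuclei, modality = "conventional", seed = NULL,
                          snr = 15) {
  p <- nucleus_sim_params(n_nuclei = n_nuclei, modality = modality,
                          background_sd_frac = 0, seed = seed)
  p$photons_per_spot <- photons_for_snr(snr, p)
  p
}
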