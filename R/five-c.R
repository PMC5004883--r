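#' Digest a DNA sequence into restriction fragments
#'
#' Finds every occurrence of the recognition site (HindIII, `AAGCTT`, by
#' default) and cuts at `site start + cut_offset` (HindIII cuts A^AGCTT, so
#' the offset is 1). Fragments tile the sequence exactly. Coordinates are
#' 0-based half-open; an optional genomic `offset` shifts them onto a
#' chromosome.
#'
#' @param seq DNA as a character string or `Biostrings::DNAString`
#'   (alphabet ACGTN; `N` never matches the site).
#' @param site Recognition sequence, default `"AAGCTT"`.
#' @param cut_offset Cut position within the site, default 1.
#' @param chrom Chromosome label for the fragments.
#' @param offset Genomic start (0-based) of the sequence.
#' @return `data.frame`: `chrom, start, end, length, index`, with attribute
#'   `region = c(start, end)` of the digested span.
#' @examples
#' digest_sequence("AAAAGCTTAA")   # fragments [0,3) and [3,10)
#' @export
digest_sequence <- function(seq, site = "AAGCTT", cut_offset = 1L,
                            chrom = "chrS", offset = 0L) {
  if (!nzchar(site)) stop("'site' must be non-empty")
  if (grepl("N", site, fixed = TRUE)) stop("'site' must not contain N")
  s <- if (inherits(seq, "DNAString")) seq else {
    if (!grepl("^[ACGTNacgtn]*$", as.character(seq)))
      stop("sequence must be over {A,C,G,T,N}")
    Biostrings::DNAString(toupper(as.character(seq)))
  }
  if (nchar(site) > length(s)) stop("'site' longer than the sequence")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("'cut_offset' must lie within the site")
  m <- Biostrings::matchPattern(Biostrings::DNAString(site), s)
  cuts <- Biostrings::start(m) - 1L + as.integer(cut_offset)  # 0-based cuts
  cuts <- sort(unique(cuts[cuts > 0L & cuts < length(s)]))
  bounds <- c(0L, cuts, length(s))
  out <- data.frame(chrom = chrom,
                    start = bounds[-length(bounds)] + offset,
                    end = bounds[-1] + offset)
  out$length <- out$end - out$start
  out$index <- seq_len(nrow(out))
  attr(out, "region") <- c(offset, offset + length(s))
  out
}

#' Assign alternating forward/reverse primers to eligible fragments
#'
#' Fragments are eligible for a primer when their length lies in
#' `[min_len, max_len]` (very small and very large restriction fragments
#' carry no primer) and they are not masked by `exclude` (a repeat /
#' low-complexity mask supplied by the caller, not recomputed here).
#' Eligible fragments receive alternating orientations in genomic order,
#' starting with reverse, so forward and reverse counts differ by at most
#' one (e.g. a 365-primer design splits 182 forward / 183 reverse).
#'
#' @param fragments Ordered fragment table from [digest_sequence()].
#' @param min_len,max_len Eligibility bounds in bp (defaults 100 and 20000).
#' @param exclude Optional logical mask, `TRUE` = never eligible.
#' @return `data.frame` of class `fragment_map`: fragments plus `eligible`
#'   and `orientation` (`"forward"`, `"reverse"` or `"none"`).
#' @export
assign_primers <- function(fragments, min_len = 100, max_len = 20000,
                           exclude = NULL) {
  stopifnot(is.data.frame(fragments), all(diff(fragments$start) > 0))
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(fragments))
  stopifnot(length(exclude) == nrow(fragments))
  map <- fragments
  map$eligible <- map$length >= min_len & map$length <= max_len & !exclude
  map$orientation <- "none"
  ei <- which(map$eligible)
  if (length(ei) > 0)
    map$orientation[ei] <-
      rep(c("reverse", "forward"), length.out = length(ei))
  attr(map, "region") <- attr(fragments, "region")
  class(map) <- c("fragment_map", "data.frame")
  map
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments (%d eligible: %d forward, %d reverse) on %s\n",
              nrow(x), sum(x$eligible), sum(x$orientation == "forward"),
              sum(x$orientation == "reverse"), x$chrom[1]))
  reg <- attr(x, "region")
  if (!is.null(reg)) cat(sprintf("  region %s:%d-%d (0-based half-open)\n",
                                 x$chrom[1], reg[1], reg[2]))
  invisible(x)
}

#' A 5C contact matrix over forward x reverse fragment pairs
#'
#' Only forward x reverse primer pairs can be amplified by the alternating
#' 5C design, so counts live on an `n_forward x n_reverse` grid; forward x
#' forward and reverse x reverse pairs are structurally absent.
#'
#' @param map A [assign_primers()] fragment map.
#' @param raw Integer matrix of raw counts, `n_forward x n_reverse` (rows
#'   follow forward fragments in genomic order, columns reverse fragments).
#' @param total_reads Total read count of the run used for normalisation;
#'   defaults to the grand sum of `raw`.
#' @return Object of class `contact_matrix` with elements `map`, `fwd`,
#'   `rev` (fragment row indices), `raw`, `norm` (`NULL` until
#'   [normalize_counts()]), `total_reads`.
#' @export
contact_matrix <- function(map, raw, total_reads = sum(raw)) {
  stopifnot(inherits(map, "fragment_map"))
  fwd <- which(map$orientation == "forward")
  rev <- which(map$orientation == "reverse")
  if (length(fwd) == 0L || length(rev) == 0L)
    stop("map has no forward x reverse pairs")
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == length(fwd), ncol(raw) == length(rev),
            all(raw >= 0))
  structure(list(map = map, fwd = fwd, rev = rev, raw = raw, norm = NULL,
                 total_reads = total_reads),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d forward x %d reverse fragments, %s reads (%s)\n",
              length(x$fwd), length(x$rev), format(x$total_reads),
              if (is.null(x$norm)) "raw" else "normalised"))
  invisible(x)
}

#' Normalise 5C counts by total reads
#'
#' Each contact's normalised frequency is its raw count divided by the
#' total number of reads of the run, scaled by 10^3. Raw counts are
#' retained. When `total_reads` equals the grand sum of the raw counts the
#' normalised entries sum to exactly 1000.
#'
#' @param m A [contact_matrix()].
#' @return The matrix with `norm` filled in.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$total_reads <= 0) stop("'total_reads' must be positive")
  m$norm <- m$raw / m$total_reads * 1e3
  m
}

window_table <- function(region, window_bp) {
  starts <- seq(region[1], region[2] - 1L, by = window_bp)
  data.frame(start = starts, end = pmin(starts + window_bp, region[2]))
}

#' Bin a normalised contact matrix over fixed genomic windows
#'
#' Non-overlapping windows tile the region from its start (default 28 kb;
#' the terminal window may be partial). Each forward x reverse fragment
#' pair is assigned to the window pair containing the two fragment
#' midpoints; the window value is the arithmetic mean of the normalised
#' frequencies of its contributing pairs. Window pairs with no contributing
#' pair are `NA` (missing, never zero). The result is symmetric in the
#' unordered window pair.
#'
#' @param m A normalised [contact_matrix()].
#' @param window_bp Window size in bp, default 28000.
#' @return Object of class `binned_matrix`: `values` (symmetric matrix with
#'   `NA` for empty window pairs), `windows` (coordinates), `window_bp`,
#'   `chrom`.
#' @export
bin_matrix <- function(m, window_bp = 28000) {
  stopifnot(inherits(m, "contact_matrix"))
  if (window_bp <= 0) stop("'window_bp' must be positive")
  if (is.null(m$norm)) stop("normalise the matrix first (normalize_counts)")
  region <- attr(m$map, "region")
  if (is.null(region)) region <- c(min(m$map$start), max(m$map$end))
  win <- window_table(region, window_bp)
  w_of <- function(pos) pmin(floor((pos - region[1]) / window_bp) + 1L,
                             nrow(win))
  mid <- (m$map$start + m$map$end) / 2
  wf <- w_of(mid[m$fwd])
  wr <- w_of(mid[m$rev])
  wi <- rep(wf, times = length(wr))
  wj <- rep(wr, each = length(wf))
  lo <- pmin(wi, wj); hi <- pmax(wi, wj)
  key <- (lo - 1L) * nrow(win) + hi
  v <- as.vector(m$norm)
  sums <- rowsum(v, key)
  cnts <- rowsum(rep(1, length(v)), key)
  W <- nrow(win)
  vals <- matrix(NA_real_, W, W)
  k <- as.integer(rownames(sums))
  li <- (k - 1L) %/% W + 1L
  hj <- (k - 1L) %% W + 1L
  mv <- sums[, 1] / cnts[, 1]
  vals[cbind(li, hj)] <- mv
  vals[cbind(hj, li)] <- mv
  structure(list(values = vals, windows = win, window_bp = window_bp,
                 chrom = m$map$chrom[1]),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d windows of %d bp on %s (%d window pairs populated)\n",
              nrow(x$windows), x$window_bp, x$chrom,
              sum(!is.na(x$values[upper.tri(x$values, diag = TRUE)]))))
  invisible(x)
}

#' Virtual 4C: extract a one-viewpoint interaction profile
#'
#' Fixes a viewpoint interval and reads the binned interaction values
#' between the viewpoint's window(s) and every other window (mean when the
#' viewpoint spans several windows). The viewpoint's own window(s) are
#' masked (`NA`).
#'
#' @param b A [bin_matrix()] result.
#' @param viewpoint Genomic interval `c(start, end)` (0-based half-open)
#'   that must overlap at least one window.
#' @return `data.frame` of class `viewpoint_track`: `chrom, start, end,
#'   value`, one row per window.
#' @export
virtual_4c <- function(b, viewpoint) {
  stopifnot(inherits(b, "binned_matrix"), length(viewpoint) == 2L,
            viewpoint[1] < viewpoint[2])
  vw <- which(b$windows$start < viewpoint[2] & b$windows$end > viewpoint[1])
  if (length(vw) == 0L) stop("viewpoint outside the binned region")
  rows <- b$values[vw, , drop = FALSE]
  value <- colMeans(rows, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  value[vw] <- NA_real_
  out <- data.frame(chrom = b$chrom, start = b$windows$start,
                    end = b$windows$end, value = value)
  attr(out, "viewpoint") <- viewpoint
  class(out) <- c("viewpoint_track", "data.frame")
  out
}

#' Insulation score per window
#'
#' Mean binned interaction value in the square of window pairs crossing
#' each window: rows `w - flank_windows .. w - 1` against columns
#' `w + 1 .. w + flank_windows`. Low scores mark positions that few
#' contacts cross, i.e. candidate domain boundaries. Scores are defined for
#' windows with a full flank on both sides; `NA` elsewhere.
#'
#' @param b A [bin_matrix()] result.
#' @param flank_windows Flank half-width in windows, default 3.
#' @return Numeric vector of length `nrow(b$windows)`.
#' @export
insulation_score <- function(b, flank_windows = 3L) {
  stopifnot(inherits(b, "binned_matrix"), flank_windows >= 1L)
  W <- nrow(b$windows)
  if (W < 2L * flank_windows + 1L)
    stop("too few windows for this flank")
  s <- rep(NA_real_, W)
  for (w in (flank_windows + 1L):(W - flank_windows)) {
    sq <- b$values[(w - flank_windows):(w - 1L),
                   (w + 1L):(w + flank_windows), drop = FALSE]
    if (all(is.na(sq))) next
    s[w] <- mean(sq, na.rm = TRUE)
  }
  s
}

#' Detect interaction-domain boundaries from insulation minima
#'
#' A window is called a boundary when its insulation score is a strict
#' local minimum, falls below `mean - n_sd * sd` of all defined scores, and
#' is deep in absolute terms (below `max_ratio` times the median score —
#' this depth requirement keeps shallow noise minima of a homogeneous,
#' single-domain map from being called). Thresholds are heuristic and
#' configurable.
#'
#' @param b A [bin_matrix()] result.
#' @param flank_windows Insulation flank half-width, default 3.
#' @param n_sd Threshold below the score mean, in sd units (default 1).
#' @param max_ratio Maximum boundary score as a fraction of the median
#'   score (default 0.7).
#' @return `data.frame`: `window`, `start`, `end`, `score`; zero rows when
#'   no boundary is found.
#' @export
insulation_boundaries <- function(b, flank_windows = 3L, n_sd = 1,
                                  max_ratio = 0.7) {
  s <- insulation_score(b, flank_windows)
  ok <- which(!is.na(s))
  if (length(ok) < 3L)
    return(data.frame(window = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  thr <- mean(s[ok]) - n_sd * stats::sd(s[ok])
  depth <- max_ratio * stats::median(s[ok])
  hits <- integer(0)
  for (w in ok) {
    if (w - 1L < 1L || w + 1L > length(s)) next
    if (is.na(s[w - 1L]) || is.na(s[w + 1L])) next
    if (s[w] < s[w - 1L] && s[w] < s[w + 1L] && s[w] < thr && s[w] < depth)
      hits <- c(hits, w)
  }
  data.frame(window = hits, start = b$windows$start[hits],
             end = b$windows$end[hits], score = s[hits])
}
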