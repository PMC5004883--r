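# Writers emit plain tab-separated text; numeric columns are serialised with
# "%.17g" so that read_* reproduces doubles bit-exactly.

write_tsv_exact <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write per-allele distance tables
#'
#' Tab-separated with columns `tissue, stage, modality, section, nucleus,
#' allele, d_nm`; the interchange format between image quantification and
#' the distance statistics.
#'
#' @param data A [distance_dataset()].
#' @param file Path.
#' @return `write_pairs_tsv` returns the path; `read_pairs_tsv` a
#'   [distance_dataset()].
#' @export
write_pairs_tsv <- function(data, file) {
  write_tsv_exact(as.data.frame(data), file)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(file) {
  as_distance_dataset(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' Write and read an image stack as multi-page TIFF
#'
#' One page per z-slice, 32-bit float samples. TIFF stores values in
#' `[0, 1]`, so intensities are divided by `scale` on write and multiplied
#' back on read; pick `scale` at least the maximum intensity (default).
#'
#' @param stack An [image_stack()].
#' @param file Path.
#' @param scale Intensity divisor stored nowhere in the file; keep it in a
#'   sample sheet (see [write_fish_stacks()]).
#' @param voxel_size_nm,channel,nucleus Calibration/labels to attach on read.
#' @return `write_stack_tiff` returns `scale` invisibly; `read_stack_tiff`
#'   an [image_stack()].
#' @export
write_stack_tiff <- function(stack, file, scale = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  arr <- pmax(stack$intensities, 0)
  if (is.null(scale)) scale <- max(arr, 1)
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / scale)
  tiff::writeTIFF(pages, file, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(file, voxel_size_nm, scale = 1,
                            channel = 1L, nucleus = NA) {
  pages <- tiff::readTIFF(file, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * scale
  image_stack(arr, voxel_size_nm, channel = channel, nucleus = nucleus)
}

#' Export a simulated FISH experiment to disk
#'
#' Writes one TIFF per nucleus per channel, the ground-truth table as TSV,
#' a sample sheet TSV (file, nucleus, channel, intensity scale plus group
#' labels) and the simulation parameters echoed to YAML.
#'
#' @param sim Result of [simulate_fish_stacks()].
#' @param dir Output directory (created if needed).
#' @param tissue,stage,section Labels written into the sample sheet.
#' @return The sample sheet as a data frame, invisibly.
#' @export
write_fish_stacks <- function(sim, dir, tissue = "tissue", stage = "stage",
                              section = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim$stacks, function(st) {
    fn <- sprintf("nucleus%03d_ch%d.tif", st$nucleus, st$channel)
    sc <- write_stack_tiff(st, file.path(dir, fn))
    data.frame(file = fn, nucleus = st$nucleus, channel = st$channel,
               scale = sc, tissue = tissue, stage = stage,
               modality = sim$params$modality, section = section)
  })
  sheet <- do.call(rbind, rows)
  write_tsv_exact(sheet, file.path(dir, "samples.tsv"))
  write_tsv_exact(as.data.frame(sim$truth), file.path(dir, "truth.tsv"))
  pl <- sim$params
  class(pl) <- NULL
  yaml::write_yaml(pl, file.path(dir, "params.yaml"))
  invisible(sheet)
}

#' Write and read a fragment map as BED
#'
#' BED6 with the fragment index as name, eligibility as score (0/1) and
#' primer orientation as strand (`+` forward, `-` reverse, `.` none).
#' Coordinates are 0-based half-open, as BED requires. Round-trips
#' bit-exactly.
#'
#' @param map A `fragment_map`.
#' @param file Path.
#' @return `write_fragment_bed` the path; `read_fragment_bed` a
#'   `fragment_map`.
#' @export
write_fragment_bed <- function(map, file) {
  stopifnot(inherits(map, "fragment_map"))
  strand <- c(forward = "+", reverse = "-", none = ".")[map$orientation]
  bed <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                    name = map$index, score = as.integer(map$eligible),
                    strand = strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_fragment_bed
#' @export
read_fragment_bed <- function(file) {
  bed <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  map <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    length = bed$end - bed$start, index = bed$name,
                    eligible = bed$score == 1L,
                    orientation = c("+" = "forward", "-" = "reverse",
                                    "." = "none")[bed$strand])
  rownames(map) <- NULL
  attr(map, "region") <- c(min(map$start), max(map$end))
  class(map) <- c("fragment_map", "data.frame")
  map
}

#' Write and read 5C contacts as BEDPE-like pairs
#'
#' One line per forward x reverse fragment pair with a positive raw count:
#' `chrom1 start1 end1 chrom2 start2 end2 raw_count [norm_freq]`.
#' `read_contacts_bedpe` rebuilds the full (dense) count matrix against a
#' fragment map, restoring zeros for absent pairs; round-trips bit-exactly.
#'
#' @param m A [contact_matrix()].
#' @param file Path.
#' @param map The `fragment_map` to reconstruct against.
#' @param total_reads Total reads of the run the file came from.
#' @return `write_contacts_bedpe` the path; `read_contacts_bedpe` a
#'   [contact_matrix()].
#' @export
write_contacts_bedpe <- function(m, file) {
  stopifnot(inherits(m, "contact_matrix"))
  idx <- which(m$raw > 0, arr.ind = TRUE)
  fi <- m$fwd[idx[, 1]]; ri <- m$rev[idx[, 2]]
  df <- data.frame(chrom1 = m$map$chrom[fi], start1 = m$map$start[fi],
                   end1 = m$map$end[fi], chrom2 = m$map$chrom[ri],
                   start2 = m$map$start[ri], end2 = m$map$end[ri],
                   raw_count = m$raw[idx])
  if (!is.null(m$norm)) df$norm_freq <- m$norm[idx]
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  write_tsv_exact(df, file)
}

#' @rdname write_contacts_bedpe
#' @export
read_contacts_bedpe <- function(file, map, total_reads = NULL) {
  stopifnot(inherits(map, "fragment_map"))
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  fwd <- which(map$orientation == "forward")
  rev <- which(map$orientation == "reverse")
  raw <- matrix(0L, length(fwd), length(rev))
  i <- match(df$start1, map$start[fwd])
  j <- match(df$start2, map$start[rev])
  if (any(is.na(i)) || any(is.na(j)))
    stop("contact coordinates do not match the fragment map")
  raw[cbind(i, j)] <- df$raw_count
  if (is.null(total_reads)) total_reads <- sum(raw)
  contact_matrix(map, raw, total_reads = total_reads)
}

#' Write and read a dense matrix as TSV
#'
#' Used for dense contact matrices (fragment by fragment) and binned
#' matrices (window by window). Missing values are written as `NA` and
#' restored as `NA` — missing window pairs never silently become zeros.
#'
#' @param values Numeric matrix.
#' @param file Path.
#' @param row_labels,col_labels Labels written as first column / header.
#' @return `write_dense_tsv` the path; `read_dense_tsv` a list
#'   `values, row_labels, col_labels`.
#' @export
write_dense_tsv <- function(values, file, row_labels = rownames(values),
                            col_labels = colnames(values)) {
  if (is.null(row_labels)) row_labels <- seq_len(nrow(values))
  if (is.null(col_labels)) col_labels <- seq_len(ncol(values))
  df <- data.frame(label = row_labels)
  for (j in seq_len(ncol(values))) df[[paste0("c", j)]] <- values[, j]
  names(df) <- c("label", col_labels)
  write_tsv_exact(df, file)
}

#' @rdname write_dense_tsv
#' @export
read_dense_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  list(values = vals, row_labels = df[[1]], col_labels = names(df)[-1])
}

#' Write a binned matrix with window coordinates
#'
#' @param b A [bin_matrix()] result.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_binned_tsv <- function(b, file) {
  stopifnot(inherits(b, "binned_matrix"))
  lab <- sprintf("%s:%d-%d", b$chrom, b$windows$start, b$windows$end)
  write_dense_tsv(b$values, file, row_labels = lab, col_labels = lab)
}

#' Write and read a viewpoint track as bedGraph
#'
#' Masked/missing windows (NA) are omitted from the file, as bedGraph has
#' no missing-value representation; `read_bedgraph` returns only the
#' windows present.
#'
#' @param track A [virtual_4c()] result.
#' @param file Path.
#' @return `write_bedgraph` the path; `read_bedgraph` a data frame
#'   `chrom, start, end, value`.
#' @export
write_bedgraph <- function(track, file) {
  keep <- !is.na(track$value)
  df <- data.frame(chrom = track$chrom[keep], start = track$start[keep],
                   end = track$end[keep],
                   value = sprintf("%.17g", track$value[keep]))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file) {
  utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "value"))
}
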