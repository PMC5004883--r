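#' Default end-to-end run configuration
#'
#' One serialisable list drives both pipelines. FISH groups are defined by
#' a target true colocalised fraction (see
#' [distance_model_for_fraction()]), a nucleus count and a number of
#' tissue sections; imaging and detection settings are shared. The 5C block
#' defines the simulated region, domain structure, viewpoints and window
#' size. Everything here is plain data: a run's config echo suffices to
#' reproduce it.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return Nested list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    fish = list(
      groups = list(
        zpa             = list(coloc_fraction = 0.79, n_nuclei = 30L, n_sections = 2L),
        distal_anterior = list(coloc_fraction = 0.25, n_nuclei = 30L, n_sections = 2L)),
      stage = "E11.5",
      modality = "conventional",
      photons_per_spot = 500, background_level = 20, read_noise_sd = 2,
      detection = list(min_snr = 6, min_separation_nm = 400,
                       max_gate_nm = 2000),
      write_images = FALSE),
    five_c = list(
      region = c(28317086, 30005000), chrom = "chr5",
      domain_boundaries = c(28650000, 29900000),
      decay_exponent = 1.0, inter_domain_factor = 0.3,
      peak_pairs = list(list(a = c(28779000, 28790000),
                             b = c(29760000, 29771000), fold = 3)),
      total_reads = 1e6,
      window_bp = 28000, flank_windows = 3L,
      viewpoints = list(gene = c(28779000, 28790000),
                        enhancer = c(29760000, 29771000)))),
    class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' @param config A `run_config` list.
#' @param file Path to a YAML file.
#' @return `write_run_config` the path; `read_run_config` a `run_config`.
#' @export
write_run_config <- function(config, file) {
  cl <- unclass(config)
  yaml::write_yaml(cl, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  structure(yaml::read_yaml(file), class = "run_config")
}

config_checksum <- function(config) {
  raw <- charToRaw(yaml::as.yaml(unclass(config)))
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% .Machine$integer.max)
}

validate_fish_config <- function(config) {
  errs <- character(0)
  f <- config$fish
  if (is.null(f)) errs <- c(errs, "fish: block missing")
  else {
    if (is.null(f$groups) || length(f$groups) == 0L ||
        is.null(names(f$groups)) || any(names(f$groups) == ""))
      errs <- c(errs, "fish.groups: must be a non-empty named list")
    else for (g in names(f$groups)) {
      gr <- f$groups[[g]]
      if (is.null(gr$coloc_fraction) || gr$coloc_fraction < 0 ||
          gr$coloc_fraction > 1)
        errs <- c(errs, sprintf("fish.groups.%s.coloc_fraction: must lie in [0,1]", g))
      if (is.null(gr$n_nuclei) || gr$n_nuclei < 1)
        errs <- c(errs, sprintf("fish.groups.%s.n_nuclei: must be >= 1", g))
    }
    if (!is.null(f$modality) && !f$modality %in% c("conventional", "sim"))
      errs <- c(errs, "fish.modality: must be 'conventional' or 'sim'")
  }
  if (is.null(config$seed)) errs <- c(errs, "seed: missing")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Run the FISH simulation-and-quantification pipeline
#'
#' Simulate -> detect -> pair -> classify -> test, for every configured
#' group: ground-truthed image stacks are simulated, spots detected and
#' paired, per-allele distances assembled into a [distance_dataset()]
#' (nuclei dealt round-robin onto tissue sections), and the group readouts
#' computed: 200-nm binned distributions with across-section s.e.m.,
#' colocalisation frequencies, boxplot summaries, per-cell allele
#' categories and pairwise Fisher / Mann-Whitney comparisons. All tables
#' are written as TSV under `out_dir`; runs with the same config are
#' byte-identical.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory.
#' @return Report bundle: list with `datasets`, `distributions`,
#'   `frequencies`, `boxplots`, `categories`, `comparisons`, `truth`.
#' @export
run_fish_pipeline <- function(config, out_dir = tempfile("fishrun")) {
  validate_fish_config(config)
  message(sprintf("[chromprox] fish pipeline: seed %d, config %s",
                  config$seed, config_checksum(config)))
  f <- config$fish
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- list(); truths <- list()
  for (gi in seq_along(f$groups)) {
    gname <- names(f$groups)[gi]
    gr <- f$groups[[gi]]
    model <- distance_model_for_fraction(gr$coloc_fraction)
    params <- nucleus_sim_params(
      n_nuclei = gr$n_nuclei, modality = f$modality,
      photons_per_spot = f$photons_per_spot,
      background_level = f$background_level,
      read_noise_sd = f$read_noise_sd,
      seed = config$seed + 1000L * gi)
    sim <- simulate_fish_stacks(params, model)
    if (isTRUE(f$write_images))
      write_fish_stacks(sim, file.path(out_dir, paste0("images_", gname)),
                        tissue = gname, stage = f$stage)
    ds <- quantify_simulation(sim, f$detection)
    n_sections <- max(1L, as.integer(gr$n_sections %||% 2L))
    ds$section <- ((ds$nucleus - 1L) %% n_sections) + 1L
    ds$tissue <- gname; ds$stage <- f$stage; ds$modality <- f$modality
    datasets[[gname]] <- as_distance_dataset(ds)
    truths[[gname]] <- sim$truth
  }
  all_pairs <- do.call(rbind, lapply(names(datasets), function(g)
    as.data.frame(datasets[[g]])))
  write_pairs_tsv(as_distance_dataset(all_pairs),
                  file.path(out_dir, "pairs.tsv"))
  dist_tab <- do.call(rbind, lapply(names(datasets), function(g) {
    b <- bin_distances(datasets[[g]])
    data.frame(group = g, as.data.frame(b))
  }))
  write_tsv_exact(dist_tab, file.path(out_dir, "distributions.tsv"))
  freq <- do.call(rbind, lapply(names(datasets), function(g) {
    cf <- coloc_frequency(datasets[[g]])
    data.frame(group = g, proportion = cf$proportion, sem = cf$sem,
               n_alleles = cf$n, n_sections = cf$n_sections)
  }))
  write_tsv_exact(freq, file.path(out_dir, "frequencies.tsv"))
  box <- do.call(rbind, lapply(names(datasets), function(g) {
    s <- summarize_box(datasets[[g]])
    data.frame(group = g, median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n = s$n)
  }))
  write_tsv_exact(box, file.path(out_dir, "boxplots.tsv"))
  cats <- do.call(rbind, lapply(names(datasets), function(g) {
    ac <- allele_categories(datasets[[g]])
    data.frame(group = g, both = ac$fractions["both"],
               one = ac$fractions["one"], none = ac$fractions["none"],
               n_nuclei = ac$n_nuclei, n_excluded = ac$n_excluded,
               row.names = NULL)
  }))
  write_tsv_exact(cats, file.path(out_dir, "allele_categories.tsv"))
  comparisons <- if (length(datasets) >= 2L) compare_groups(datasets) else NULL
  if (!is.null(comparisons))
    write_tsv_exact(comparisons, file.path(out_dir, "comparisons.tsv"))
  invisible(list(datasets = datasets, distributions = dist_tab,
                 frequencies = freq, boxplots = box, categories = cats,
                 comparisons = comparisons, truth = truths,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify a simulated FISH experiment
#'
#' Runs detection and mutual-nearest-neighbour pairing on every nucleus of
#' a [simulate_fish_stacks()] result, using the PSF of the simulation as
#' the expected spot scale.
#'
#' @param sim A [simulate_fish_stacks()] result.
#' @param detection List with `min_snr`, `min_separation_nm`,
#'   `max_gate_nm` (missing entries take the defaults).
#' @return `data.frame` with columns `nucleus, allele, d_nm` (one row per
#'   measured pair; `allele` numbers pairs within a nucleus).
#' @export
quantify_simulation <- function(sim, detection = list()) {
  det <- utils::modifyList(list(min_snr = 6, min_separation_nm = 400,
                                max_gate_nm = 2000), detection)
  sigma <- sim$params$psf_sigma_nm
  rows <- list()
  nucs <- unique(vapply(sim$stacks, function(s) s$nucleus, numeric(1)))
  for (nuc in nucs) {
    st <- sim$stacks[vapply(sim$stacks, function(s) s$nucleus == nuc,
                            logical(1))]
    ch <- vapply(st, function(s) s$channel, numeric(1))
    res <- quantify_nucleus(st[[which(ch == 1)]], st[[which(ch == 2)]],
                            max_gate_nm = det$max_gate_nm,
                            min_snr = det$min_snr,
                            min_separation_nm = det$min_separation_nm,
                            spot_sigma_nm = sigma,
                            max_spots = sim$params$alleles_per_nucleus)
    if (nrow(res$pairs) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        nucleus = nuc, allele = seq_len(nrow(res$pairs)),
        d_nm = res$pairs$d_nm)
  }
  if (length(rows) == 0L)
    return(data.frame(nucleus = integer(0), allele = integer(0),
                      d_nm = numeric(0)))
  do.call(rbind, rows)
}

validate_5c_config <- function(config) {
  errs <- character(0)
  c5 <- config$five_c
  if (is.null(c5)) errs <- c(errs, "five_c: block missing")
  else {
    if (is.null(c5$region) || length(c5$region) != 2L ||
        c5$region[1] >= c5$region[2])
      errs <- c(errs, "five_c.region: must be c(start, end) with start < end")
    if (!is.null(c5$window_bp) && c5$window_bp <= 0)
      errs <- c(errs, "five_c.window_bp: must be positive")
    if (!is.null(c5$total_reads) && c5$total_reads <= 0)
      errs <- c(errs, "five_c.total_reads: must be positive")
    if (!is.null(c5$viewpoints) && length(c5$viewpoints) > 0 &&
        (is.null(names(c5$viewpoints)) || any(names(c5$viewpoints) == "")))
      errs <- c(errs, "five_c.viewpoints: must be a named list of intervals")
  }
  if (is.null(config$seed)) errs <- c(errs, "seed: missing")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Run the 5C processing pipeline
#'
#' Fragment map -> contact counts -> total-read normalisation -> 28-kb
#' window binning -> virtual 4C at named viewpoints -> insulation
#' boundaries. Counts are simulated from the configured [contact_model()]
#' unless `config$five_c$counts_file` (BEDPE) and `fragments_file` (BED)
#' point at an experiment to load. Writes the fragment BED, raw contacts
#' BEDPE, normalised dense TSV, binned matrix TSV, one bedGraph per
#' viewpoint and a boundary table under `out_dir`.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory.
#' @return Report bundle: list with `map`, `contacts`, `binned`, `tracks`,
#'   `boundaries`.
#' @export
run_5c_pipeline <- function(config, out_dir = tempfile("c5run")) {
  validate_5c_config(config)
  message(sprintf("[chromprox] 5C pipeline: seed %d, config %s",
                  config$seed, config_checksum(config)))
  c5 <- config$five_c
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(c5$counts_file)) {
    if (is.null(c5$fragments_file))
      stop("five_c.fragments_file required when loading counts")
    map <- read_fragment_bed(c5$fragments_file)
    cm <- read_contacts_bedpe(c5$counts_file, map,
                              total_reads = c5$total_reads)
  } else {
    map <- simulate_fragment_map(region = c5$region, chrom = c5$chrom,
                                 seed = config$seed + 77L)
    model <- contact_model(region = c5$region,
                           domain_boundaries = c5$domain_boundaries,
                           decay_exponent = c5$decay_exponent,
                           inter_domain_factor = c5$inter_domain_factor,
                           peak_pairs = c5$peak_pairs,
                           total_reads = c5$total_reads,
                           seed = config$seed + 78L)
    cm <- simulate_contact_counts(map, model)
  }
  cm <- normalize_counts(cm)
  binned <- bin_matrix(cm, window_bp = c5$window_bp %||% 28000)
  tracks <- list()
  for (vp in names(c5$viewpoints)) {
    iv <- as.numeric(c5$viewpoints[[vp]])
    if (iv[1] >= binned$windows$end[nrow(binned$windows)] ||
        iv[2] <= binned$windows$start[1])
      stop(sprintf("viewpoint '%s' outside the 5C region", vp))
    tracks[[vp]] <- virtual_4c(binned, iv)
    write_bedgraph(tracks[[vp]],
                   file.path(out_dir, sprintf("virtual4c_%s.bedGraph", vp)))
  }
  boundaries <- insulation_boundaries(binned,
                                      flank_windows = c5$flank_windows %||% 3L)
  write_fragment_bed(map, file.path(out_dir, "fragments.bed"))
  write_contacts_bedpe(cm, file.path(out_dir, "contacts.bedpe"))
  write_binned_tsv(binned, file.path(out_dir, "binned_matrix.tsv"))
  write_tsv_exact(boundaries, file.path(out_dir, "boundaries.tsv"))
  invisible(list(map = map, contacts = cm, binned = binned, tracks = tracks,
                 boundaries = boundaries, out_dir = out_dir))
}
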