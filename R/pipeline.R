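#' Load and validate a pipeline configuration
#'
#' Configuration is a flat YAML mapping. Every parameter has to pass eager
#' validation; unknown keys are rejected by name, and an explicit `seed` is
#' mandatory — stochastic stages never fall back to a hidden default.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `PipelineConfig` list (defaults filled in).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = NULL,
    genome_length = 5e5,
    gatc_rate = 0.004,
    gtac_rate = 0.004,
    primary_site = "GATC",
    secondary_site = "GTAC",
    window_size = 30L,
    window_step = 1L,
    exclusion_radius = 2L,
    z_threshold = 2,
    q_threshold = 0.05,
    normalization_span_bp = 15e6,
    proximity_windows = c(10000, 20000),
    permutations = 5000L,
    profile_half_width = 2000L,
    profile_bin_width = 10L,
    replicates = 2L,
    decay_alpha = 1,
    decay_amplitude = 1,
    noise_fraction = 0.1,
    n_per_class = 100L,
    enhancer_effect_down = 4)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) {
    stop("config must set an explicit 'seed'", call. = FALSE)
  }
  pos <- c("genome_length", "window_size", "window_step", "z_threshold",
           "q_threshold", "normalization_span_bp", "permutations",
           "profile_half_width", "profile_bin_width", "replicates",
           "decay_alpha", "decay_amplitude")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || any(cfg[[k]] <= 0)) {
      stop("config key '", k, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$exclusion_radius < 0) {
    stop("config key 'exclusion_radius' must be >= 0", call. = FALSE)
  }
  if (cfg$replicates < 2) {
    stop("the consensus rule needs >= 2 replicates", call. = FALSE)
  }
  cutter_scheme(cfg$primary_site, cfg$secondary_site)  # validates motifs
  structure(cfg, class = "PipelineConfig")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes, in dependency order: genome simulation and virtual digestion;
#' 4C read simulation (with one planted enriched region) for each replicate;
#' capture calling and windowing; decay fitting and consensus contact
#' calling; the gene-fixture proximity arm (nearest distances, window
#' frequencies, permutation null, rank test) and the TSS meta-profile. All
#' stage outputs are written as plain-text tables under `out_dir`, together
#' with a manifest recording parameters, per-stage record counts, output
#' checksums and the package version. Identical config implies
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or list/path accepted by it).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results (`map`,
#'   `profiles`, `fits`, `contacts`, `proximity`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "PipelineConfig")) config else
    pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c()
  note <- function(...) log <<- c(log, sprintf(...))

  # stage: genome + digestion
  scheme <- cutter_scheme(cfg$primary_site, cfg$secondary_site)
  genome <- make_genome(cfg$seed, cfg$genome_length, cfg$gatc_rate,
                        cfg$gtac_rate, scheme = scheme)
  map <- fragment_map(genome, scheme)
  write_fragment_bed(map, file.path(out_dir, "fragments.bed"))
  nfrag <- nrow(map$fragments[[1]])
  note("digest: %d fragments", nfrag)

  # stage: simulate 4C (one planted 10-fold enriched region)
  ch <- names(map$fragments)[1]
  vp_frag <- map$fragments[[ch]][nfrag %/% 2, ]
  vp <- viewpoint_spec("vp", ch, floor((vp_frag$start + vp_frag$end) / 2),
                       map, exclusion_radius = cfg$exclusion_radius)
  enr_first <- vp_frag$index + nfrag %/% 8
  enriched <- data.frame(frag_first = enr_first,
                         frag_last = enr_first + cfg$window_size - 1L,
                         fold = 10)
  reads <- simulate_4c(map, vp, seed = cfg$seed, alpha = cfg$decay_alpha,
                       amplitude = cfg$decay_amplitude,
                       replicates = cfg$replicates, enriched = enriched,
                       noise_fraction = cfg$noise_fraction)
  profiles <- list()
  for (r in names(reads)) {
    write_sam(reads[[r]], map$seqlengths,
              file.path(out_dir, paste0("reads_", r, ".sam")))
    profiles[[r]] <- capture_profile(reads[[r]], map, vp,
                                     window_size = cfg$window_size,
                                     step = cfg$window_step, replicate = r)
    write_capture_profile(profiles[[r]],
                          file.path(out_dir, paste0("windows_", r, ".tsv")),
                          file.path(out_dir,
                                    paste0("windows_", r, ".bedGraph")))
    note("capture %s: %d reads, %d windows", r, nrow(reads[[r]]),
         nrow(profiles[[r]]$windows))
  }

  # stage: decay fit + consensus contacts
  fits <- lapply(profiles, fit_decay)
  contacts <- score_contacts(fits, z_threshold = cfg$z_threshold,
                             q_threshold = cfg$q_threshold)
  write.table(contacts, file.path(out_dir, "contacts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_contacts_bed(contacts, file.path(out_dir, "contacts.bed"))
  note("contacts: %d consensus-significant of %d windows",
       sum(contacts$consensus_significant), nrow(contacts))

  # stage: proximity arm on a planted gene fixture
  fx <- make_gene_fixture(cfg$seed, n_per_class = cfg$n_per_class,
                          enhancer_effect =
                            c(down = cfg$enhancer_effect_down))
  write_gene_fixture(fx, file.path(out_dir, "fixture"))
  nd <- nearest_distance(fx$genes, fx$enhancers)
  write.table(nd, file.path(out_dir, "gene_distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wf <- window_frequency(fx$genes, fx$ctcf_peaks,
                         windows = cfg$proximity_windows)
  down <- nd[nd$class == "down", ]
  unch <- nd[nd$class == "unchanged_expressed", ]
  expressed <- nd[nd$class != "not_expressed", ]
  mw <- mann_whitney(down$distance, unch$distance)
  pn <- permutation_null(function(g) mean(g$distance), down, expressed,
                         n_draws = cfg$permutations, seed = cfg$seed)
  summary_df <- wf
  summary_df$mw_p_down_vs_unchanged <- mw$p
  summary_df$perm_p_down_mean_distance <- pn$p_lower
  write.table(summary_df, file.path(out_dir, "proximity_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("proximity: %d genes, MW p = %.3g, perm p = %.3g", nrow(nd), mw$p,
       pn$p_lower)

  mp <- meta_profile(fx$genes, fx$track,
                     half_width = cfg$profile_half_width,
                     bin_width = cfg$profile_bin_width)
  write.table(mp$profiles, file.path(out_dir, "meta_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("profile: %d classes x %d bins", length(unique(mp$profiles$class)),
       length(mp$position))

  # manifest: parameters, stage log, output checksums
  outs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                       "manifest.txt"))
  sums <- tools::md5sum(file.path(out_dir, outs))
  manifest <- c(
    sprintf("package_version=%s",
            as.character(utils::packageVersion("contactscape"))),
    vapply(names(cfg), function(k) {
      sprintf("param_%s=%s", k, paste(cfg[[k]], collapse = ","))
    }, character(1)),
    paste0("stage_", log),
    sprintf("md5_%s=%s", outs, unname(sums)))
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(list(map = map, viewpoint = vp, profiles = profiles,
                 fits = fits, contacts = contacts,
                 proximity = list(distances = nd, window_freq = wf,
                                  mann_whitney = mw, permutation = pn,
                                  meta_profile = mp),
                 manifest_path = manifest_path))
}
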