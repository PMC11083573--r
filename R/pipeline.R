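# Orchestration: run every analysis stage over one trajectory from a
# single configuration, write the report bundle, and summarize it.

#' Default analysis configuration
#'
#' The parameter set of the pH-2 beta-lactoglobulin peptide study:
#' 4 Angstrom all-atom contact cutoff, 10-frame (1 ns at 100 ps spacing)
#' running-average window, hydrogen-bond criteria 1.2 / 3.0 Angstrom and
#' 150 degrees, Shrake-Rupley SASA with a 1.4 Angstrom probe and 960
#' points on Bondi radii, pH 2 protonation, and a 12 x 12
#' order-vs-H-bond histogram.
#'
#' @param ... Overrides for individual fields.
#' @return A named list of class `aggtraj_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    cutoff = 4.0, window = 10L,
    dh_cutoff = 1.2, da_cutoff = 3.0, angle_min = 150,
    probe = 1.4, n_points = 960L,
    pH = 2, top_k = 40L,
    hist_x_bins = 12L, hist_y_bins = 12L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "aggtraj_config")
}

#' Run the full aggregation-analysis pipeline over one trajectory
#'
#' Stages, in order: per-frame contact clustering, largest /
#' second-largest cluster series (raw and running-averaged), cluster-size
#' distribution, transition network (pruned to the top k edges),
#' secondary-structure assignment with largest-cluster content,
#' beta-peptide fraction and per-residue beta propensity, hydrogen-bond
#' series and intermolecular contact map, SASA decomposition series, and
#' largest-cluster order records with the order-vs-H-bond histogram.
#' Identical config + input produce identical output.
#'
#' @param traj An [aggtraj_trajectory].
#' @param config An `aggtraj_config` (see [default_config]).
#' @param out_dir Optional directory: when given, every table is written
#'   there as TSV/JSON together with the serialized config.
#' @return A named list (report bundle) with elements `config`,
#'   `cluster_series`, `size_distribution`, `network`, `ss_content`,
#'   `beta_fraction`, `propensity`, `hbond_series`, `contact_map`,
#'   `sasa_series`, `order_records`, `histogram`.
#' @export
run_pipeline <- function(traj, config = default_config(), out_dir = NULL) {
  stage <- "clustering"
  bundle <- tryCatch({
    assignments <- cluster_frames(traj, config$cutoff)
    largest <- cluster_timeseries(assignments, rank = 1L)
    second <- cluster_timeseries(assignments, rank = 2L)
    cluster_series <- data.frame(
      frame = seq_along(assignments),
      time = vapply(traj$frames, function(f) f$time, numeric(1)),
      largest = largest, second = second,
      largest_ravg = running_average(largest, config$window),
      second_ravg = running_average(second, config$window)
    )
    dist_tab <- size_distribution(assignments)
    network <- if (length(assignments) >= 2L) {
      top_k_edges(track_transitions(assignments), config$top_k)
    } else NULL

    stage <- "secondary structure"
    ssm <- assign_ss_trajectory(traj)
    ss_content <- ss_content_of_largest_cluster(assignments, ssm)
    beta_frac <- beta_peptide_fraction(assignments, ssm)
    propensity <- residue_beta_propensity(ssm)

    stage <- "hydrogen bonds"
    hb <- hbond_timeseries(traj, da_cutoff = config$da_cutoff,
                           angle_min = config$angle_min,
                           dh_cutoff = config$dh_cutoff)
    cmap <- hbond_contact_map(traj, "intermolecular",
                              bonds = attr(hb, "bonds"))

    stage <- "surface area"
    sasa <- sasa_timeseries(traj, config$cutoff, assignments,
                            probe = config$probe,
                            n_points = config$n_points)

    stage <- "order parameters"
    records <- order_records(traj, config$cutoff, assignments,
                             hbonds = attr(hb, "bonds"))
    histogram <- order_hbond_histogram(records, config$hist_x_bins,
                                       config$hist_y_bins)

    list(config = config, cluster_series = cluster_series,
         size_distribution = dist_tab, network = network,
         ss_content = ss_content, beta_fraction = beta_frac,
         propensity = propensity, hbond_series = hb,
         contact_map = cmap, sasa_series = sasa,
         order_records = records, histogram = histogram)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(bundle$config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_results(bundle$cluster_series,
                  file.path(out_dir, "cluster_series.tsv"))
    write_results(bundle$size_distribution,
                  file.path(out_dir, "size_distribution.tsv"))
    if (!is.null(bundle$network)) {
      write_results(bundle$network, file.path(out_dir, "network.json"))
    }
    write_results(bundle$ss_content, file.path(out_dir, "ss_content.tsv"))
    write_results(bundle$beta_fraction,
                  file.path(out_dir, "beta_fraction.tsv"))
    write_results(bundle$propensity, file.path(out_dir, "propensity.tsv"))
    write_results(as.data.frame(bundle$hbond_series),
                  file.path(out_dir, "hbond_series.tsv"))
    utils::write.table(bundle$contact_map,
                       file.path(out_dir, "hbond_contact_map.tsv"),
                       sep = "\t", quote = FALSE)
    write_results(bundle$sasa_series, file.path(out_dir, "sasa_series.tsv"))
    write_results(as.data.frame(bundle$order_records),
                  file.path(out_dir, "order_records.tsv"))
    write_results(bundle$histogram,
                  file.path(out_dir, "order_hbond_histogram.tsv"))
  }
  bundle
}

#' Snapshot and pooled-time accounting for production runs
#'
#' Bookkeeping for trajectory-derived statistics: how many snapshots a run
#' of given duration yields at a given saving interval, the per-residue
#' propensity normalizer (snapshots x chains), and the pooled analyzed
#' time over several runs. A 900 ns run saved every 100 ps yields 9000
#' frames; with 20 chains the propensity normalizer is 9000 x 20, and
#' three such runs pool to 2.7 microseconds.
#'
#' @param duration_ns Production run length in ns.
#' @param interval_ps Snapshot saving interval in ps (default 100).
#' @param n_chains Chains per system (default 20).
#' @param n_runs Independent runs pooled (default 1).
#' @return List: `frames_per_run`, `total_frames`,
#'   `propensity_normalizer` (frames_per_run x n_chains),
#'   `total_time_us` (pooled, microseconds).
#' @export
snapshot_accounting <- function(duration_ns, interval_ps = 100,
                                n_chains = 20L, n_runs = 1L) {
  if (duration_ns <= 0 || interval_ps <= 0) {
    stop("duration and interval must be positive")
  }
  frames <- duration_ns * 1000 / interval_ps
  list(frames_per_run = frames,
       total_frames = frames * n_runs,
       propensity_normalizer = frames * n_chains,
       total_time_us = duration_ns * n_runs / 1000)
}

#' Human-readable summary of a pipeline report bundle
#'
#' Digests the bundle into the headline quantities of an aggregation
#' analysis: final largest/second-largest cluster sizes, final
#' secondary-structure percentages, final hydrogen-bond counts, and the
#' observed nematic-order range.
#'
#' @param bundle The result of [run_pipeline].
#' @return Character vector of summary lines (also printed invisibly
#'   usable via `cat`).
#' @export
summarize_pipeline <- function(bundle) {
  cs <- bundle$cluster_series
  if (is.null(cs) || nrow(cs) == 0L) return("no frames analyzed")
  last <- nrow(cs)
  ss <- bundle$ss_content[nrow(bundle$ss_content), ]
  hb <- bundle$hbond_series[nrow(bundle$hbond_series), ]
  p2 <- bundle$order_records$P2
  p2 <- p2[!is.na(p2)]
  lines <- c(
    sprintf("frames analyzed: %d (%g-%g ps)", last, cs$time[1],
            cs$time[last]),
    sprintf("final largest cluster: %d chains; second largest: %d",
            cs$largest[last], cs$second[last]),
    sprintf("final secondary structure of largest cluster: %.1f%% helix, %.1f%% strand, %.1f%% coil",
            ss$helix, ss$strand, ss$coil),
    sprintf("final hydrogen bonds: %d total (%d inter, %d intra)",
            hb$total, hb$inter, hb$intra),
    if (length(p2) > 0) {
      sprintf("nematic order parameter range: %.3f-%.3f", min(p2), max(p2))
    } else "nematic order parameter: undefined (no multi-chain cluster)"
  )
  lines
}
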