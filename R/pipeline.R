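#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the standard defaults:
#' hydrogen bonds at 3.5 Angstrom / 120 degrees, salt bridges below 4
#' Angstrom, hydrophobic contacts within 4 Angstrom, occupancy filter at 50
#' percent, region thresholds 0.5 and 1.0 Angstrom, converged window the
#' last 75 percent of each run. Every default can be overridden by name.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class \code{run_config}.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    hb_distance_cutoff = 3.5, hb_angle_cutoff = 120,
    sb_cutoff = 4.0, contact_cutoff = 4.0,
    occupancy_filter = 50,
    comparability_tol = 10, maintained_floor = 80,
    region_thresholds = c(0.5, 1.0), region_min_length = 3,
    region_max_gap = 1, region_exclude_termini = 5,
    window = c(0.25, 1),
    catalytic_set = default_catalytic_set(),
    sasa_probe_radius = 1.4, sasa_n_points = 960, sasa_stride = 1L,
    sasa_bin_width = 2,
    monitor_pairs = list(),   # each: list(res_a, atom_a, res_b, atom_b)
    monitor_threshold = 3.5,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the single-condition analysis pipeline
#'
#' Computes, for one trajectory: the RMSD and radius-of-gyration series with
#' converged-window summaries, the SASA series, breakdown and distribution,
#' deduplicated and classified hydrogen-bond records with category mean
#' counts and lifetime histograms (intra-protein and protein-water), unique
#' salt-bridge records, hydrophobic-contact records, any monitored atom-pair
#' distances, and the per-residue RMSF profile. The fully resolved
#' configuration is embedded in the result so every parameter actually used
#' is visible.
#'
#' @param traj a \code{trajectory}.
#' @param config a \code{run_config}.
#' @return list of class \code{condition_report}.
#' @export
run_analysis <- function(traj, config = analysis_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(config, "run_config"))
  topo <- traj$topology
  rmsd <- rmsd_series(traj, window = config$window)
  rg <- radius_of_gyration(traj, window = config$window)
  sasa <- sasa_series(traj, probe_radius = config$sasa_probe_radius,
                      n_points = config$sasa_n_points,
                      catalytic_set = config$catalytic_set,
                      window = config$window, stride = config$sasa_stride)
  sasa_dist <- sasa_distribution(sasa$series$sasa_total,
                                 bin_width = config$sasa_bin_width)
  hb <- detect_hbonds(traj, distance_cutoff = config$hb_distance_cutoff,
                      angle_cutoff = config$hb_angle_cutoff)
  hb <- classify_hbonds(dedupe_hbonds(hb))
  hb_counts <- mean_hbond_counts(hb)
  hb_records <- hb$pairs[hb$pairs$occupancy > 0, , drop = FALSE]
  hb_records <- hb_records[order(-hb_records$occupancy, hb_records$donor,
                                 hb_records$acceptor), , drop = FALSE]
  rownames(hb_records) <- NULL
  hb_prot <- hb_records[hb_records$partner_kind == "protein", , drop = FALSE]
  hb_lifetimes <- lifetime_histogram(hb_prot$occupancy)
  sb <- detect_salt_bridges(traj, cutoff = config$sb_cutoff)
  sb_records <- unique_salt_bridges(sb)
  sb_lifetimes <- lifetime_histogram(
    sb_records$occupancy[sb_records$occupancy > 0])
  ct <- detect_hydrophobic_contacts(traj, cutoff = config$contact_cutoff)
  ct_records <- contact_records(ct)
  ct_lifetimes <- lifetime_histogram(ct_records$occupancy)
  monitors <- lapply(config$monitor_pairs, function(mp) {
    monitor_distance(traj, mp$res_a, mp$atom_a, mp$res_b, mp$atom_b,
                     threshold = config$monitor_threshold)
  })
  rmsf <- rmsf_profile(traj)
  structure(list(
    condition = traj$condition,
    n_frames = n_frames(traj),
    rmsd = rmsd, rg = rg,
    sasa = sasa, sasa_distribution = sasa_dist,
    hbonds = hb, hb_records = hb_records, hb_counts = hb_counts,
    hb_lifetimes = hb_lifetimes,
    sb_records = sb_records, sb_lifetimes = sb_lifetimes,
    contact_records = ct_records, contact_lifetimes = ct_lifetimes,
    monitors = monitors,
    rmsf = rmsf,
    config = unclass(config)
  ), class = "condition_report")
}

#' Cross-condition comparison
#'
#' Given per-condition reports (first = reference), classifies salt bridges
#' and filtered hydrogen bonds differentially across the condition order,
#' calls thermal-sensitive regions from each condition's RMSF profile minus
#' the reference profile, and runs the one-way ANOVA on the per-frame RMSD,
#' Rg and total-SASA series of every condition pair against the reference.
#'
#' @param reports named list of \code{condition_report}s in comparison order.
#' @param config a \code{run_config} (defaults taken from the first report).
#' @return list of class \code{comparison_report}: \code{sb_calls},
#'   \code{hb_calls}, \code{regions} (per non-reference condition),
#'   \code{anova} (data.frame).
#' @export
compare_runs <- function(reports, config = NULL) {
  stopifnot(is.list(reports), length(reports) >= 2)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    stop("reports must be a named list of conditions")
  }
  if (is.null(config)) {
    config <- do.call(analysis_config, reports[[1]]$config[
      intersect(names(reports[[1]]$config), names(analysis_config()))])
  }
  sb_tables <- lapply(reports, function(r) {
    data.frame(id = paste(r$sb_records$pair, r$sb_records$acidic_atom,
                          r$sb_records$basic_atom),
               occupancy = r$sb_records$occupancy)
  })
  sb_calls <- differential_classify(
    sb_tables, occupancy_filter = config$occupancy_filter,
    comparability_tol = config$comparability_tol,
    maintained_floor = config$maintained_floor)
  hb_tables <- lapply(reports, function(r) {
    rec <- r$hb_records[r$hb_records$partner_kind == "protein", , drop = FALSE]
    data.frame(id = paste0(rec$donor_res, ":", rec$donor_atom, "->",
                           rec$acceptor_res, ":", rec$acceptor_atom),
               occupancy = rec$occupancy)
  })
  hb_calls <- differential_classify(
    hb_tables, occupancy_filter = config$occupancy_filter,
    comparability_tol = config$comparability_tol,
    maintained_floor = config$maintained_floor)
  ref <- reports[[1]]
  regions <- list()
  anova_rows <- list()
  for (nm in names(reports)[-1]) {
    rep_k <- reports[[nm]]
    delta <- delta_rmsf(rep_k$rmsf, ref$rmsf)
    regions[[nm]] <- call_regions(
      delta, thresholds = config$region_thresholds,
      min_length = config$region_min_length,
      max_gap = config$region_max_gap,
      exclude_termini = config$region_exclude_termini)
    for (metric in c("rmsd", "rg", "sasa_total")) {
      x <- if (metric == "sasa_total") ref$sasa$series$sasa_total
           else ref[[metric]]$series$value
      y <- if (metric == "sasa_total") rep_k$sasa$series$sasa_total
           else rep_k[[metric]]$series$value
      an <- one_way_anova(list(x, y))
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        comparison = paste(nm, "vs", names(reports)[1]), metric = metric,
        F = an$F, df1 = an$df_between, df2 = an$df_within,
        p = an$p_value, significant = an$significant)
    }
  }
  structure(list(
    sb_calls = sb_calls, hb_calls = hb_calls, regions = regions,
    anova = do.call(rbind, anova_rows), reference = names(reports)[1],
    config = unclass(config)
  ), class = "comparison_report")
}

#' Write a condition report as CSV tables plus a JSON config echo
#'
#' Emits a deterministic file bundle: time series (rmsd.csv, rg.csv,
#' sasa.csv), sasa_distribution.csv, hb_records.csv, hb_counts_protein.csv,
#' hb_counts_water.csv, hb_lifetimes.csv, sb_records.csv, contacts.csv,
#' contact_lifetimes.csv, rmsf.csv, monitor_<k>.csv and config.json. Row
#' orders are fixed (time order, descending occupancy, residue order), so
#' rerunning an identical analysis reproduces the bundle byte for byte.
#'
#' @param report a \code{condition_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "condition_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    write_records(df, path, "csv")
    files <<- c(files, path)
  }
  ser <- function(ms) data.frame(frame = ms$series$frame,
                                 time_ns = ms$series$time_ns,
                                 value = ms$series$value)
  put(ser(report$rmsd), "rmsd.csv")
  put(ser(report$rg), "rg.csv")
  put(report$sasa$series, "sasa.csv")
  put(report$sasa_distribution$histogram, "sasa_distribution.csv")
  hbcols <- c("donor_res", "donor_resname", "donor_atom", "h_atom",
              "acceptor_res", "acceptor_resname", "acceptor_atom",
              "occupancy", "backbone_class", "chem_class", "partner_kind")
  put(report$hb_records[, hbcols], "hb_records.csv")
  put(report$hb_counts$protein, "hb_counts_protein.csv")
  put(report$hb_counts$water, "hb_counts_water.csv")
  put(cbind(kind = "hbond", report$hb_lifetimes$fine), "hb_lifetimes.csv")
  put(report$sb_records, "sb_records.csv")
  put(cbind(kind = "saltbridge", report$sb_lifetimes$fine), "sb_lifetimes.csv")
  put(report$contact_records, "contacts.csv")
  put(cbind(kind = "contact", report$contact_lifetimes$fine),
      "contact_lifetimes.csv")
  put(report$rmsf, "rmsf.csv")
  for (k in seq_along(report$monitors)) {
    put(report$monitors[[k]]$series, sprintf("monitor_%d.csv", k))
  }
  summ <- data.frame(
    metric = c("rmsd", "rg", "sasa_total", "sasa_pho", "sasa_phil",
               "sasa_catalytic"),
    window_mean = c(report$rmsd$window_mean, report$rg$window_mean,
                    report$sasa$window_mean),
    window_sd = c(report$rmsd$window_sd, report$rg$window_sd,
                  report$sasa$window_sd)
  )
  put(summ, "summary.csv")
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(report$config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cfg_path)
  invisible(files)
}

#' Write a comparison report
#'
#' @param comparison a \code{comparison_report}.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    write_records(as.data.frame(df), path, "csv")
    files <<- c(files, path)
  }
  put(comparison$sb_calls, "sb_differential.csv")
  put(comparison$hb_calls, "hb_differential.csv")
  put(comparison$anova, "anova.csv")
  for (nm in names(comparison$regions)) {
    put(comparison$regions[[nm]], sprintf("regions_%s.csv", nm))
  }
  invisible(files)
}
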