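#' Scenario configuration for a single experimental condition
#'
#' A \code{scenario_config} bundles every mechanistic and penetrance
#' parameter needed to simulate one experimental condition: the nuclear
#' export program of the labeled transcript, how often cells exhibit the
#' hallmark phenotype, transcription and export kinetics, microtubule
#' transport parameters, MS2 coat-protein pool bookkeeping, and reporter
#' (Rev, Gag, VLP) kinetics.
#'
#' @param name identifier for the condition.
#' @param export_mode one of \code{"none"} (transcripts are retained in the
#'   nucleus), \code{"gradual"} (Rev-dependent export without bursts),
#'   \code{"burst"} (Rev/CRM1 program: gradual in most exporting cells,
#'   threshold-triggered en-masse evacuation in a subset) or
#'   \code{"cte_mtoc"} (NXF1/NXT1 program with microtubule-directed
#'   clustering at the MTOC).
#' @param penetrance probability in \[0,1\] that a cell exhibits the mode's
#'   hallmark phenotype (cytoplasmic-dominant redistribution for the Rev
#'   program; MTOC targeting for the CTE program).
#' @param burst_penetrance probability that a cell undergoes en-masse burst
#'   export; burst cells are treated as a subset of the penetrant
#'   (cytoplasmic-dominant) cells, so \code{burst_penetrance <= penetrance}.
#' @param k_tx transcription rate, labeled transcripts per hour.
#' @param k_exp_max baseline nuclear export rate (1/h) for transcripts not
#'   governed by a scheduled transition window.
#' @param burst_threshold nuclear transcript count that arms the burst.
#' @param ms2_saturation number of transcripts that fully sequester the
#'   nuclear MS2-YFP pool. Defaults to 30 for the Rev program (cooperative
#'   sequestration: the pool is carried by few, fully loaded transcripts,
#'   saturating well before the burst trigger) and 150 for the CTE program
#'   (distributive loading across many transcripts).
#' @param burst_duration hours over which a burst empties the nucleus.
#' @param transition_duration_mean,transition_duration_sd hours; per-cell
#'   gradual min-to-max C:N transition durations are drawn from this normal
#'   truncated at zero.
#' @param cn_plateau_mean,cn_plateau_sd per-cell final C:N signal ratio for
#'   gradual cells (truncated below at 2 so exporting cells end
#'   cytoplasmic-dominant).
#' @param mt_speed microtubule motor speed, um/s.
#' @param mt_run_length mean run length between direction reversals, um.
#' @param mt_attach_prob probability per internal step that a cytoplasmic
#'   particle engages a microtubule (fast mode).
#' @param mtoc_capture_radius um; a motile particle reaching this distance of
#'   the centrosome is captured into the MTOC compartment.
#' @param mtoc_dwell_mean mean MTOC dwell time, seconds (fast mode).
#' @param mtoc_occupancy long-run fraction of exported, phenotype-positive
#'   particles residing in the MTOC compartment (long mode steady state).
#' @param nocodazole logical; disables microtubule transport and arrests
#'   exported transcripts in a band at the nuclear envelope.
#' @param D_nuc,D_cyt diffusion coefficients, um^2/s.
#' @param ms2_pool total nuclear MS2-YFP pool, arbitrary fluorescence units.
#' @param loops_per_transcript MS2 binding loops per transcript (24).
#' @param coats_per_transcript maximum MS2 coat proteins bound per transcript
#'   (dimeric coat binding, at most 48).
#' @param rev_onset_mean,rev_onset_sd hours post-transfection at which
#'   Rev-mCherry becomes detectable; \code{NA} when Rev is absent.
#' @param k_translate Gag units synthesized per cytoplasmic transcript per
#'   hour.
#' @param vlp_onset_mean,vlp_onset_sd,vlp_onset_min hours; per-cell
#'   virus-like-particle onset. The (mean, sd) are quoted in measured space:
#'   they are the moments of the observable onset distribution truncated at
#'   \code{vlp_onset_min}. \code{NA} mean disables VLP formation.
#' @param punctae_enrichment target fold-enrichment of a single nuclear
#'   punctum over the surrounding nucleoplasm, defined in measured space
#'   (spot-disk MFI over nucleoplasm MFI after PSF and noise).
#' @param tx_onset hours post-transfection at which transcription of the
#'   transfected reporter begins.
#' @param n_cells default cohort size.
#' @param seed default RNG seed.
#' @return object of class \code{scenario_config} (a validated list).
#' @seealso [scenario_registry()] for the named presets.
#' @export
scenario_config <- function(name,
                            export_mode = c("none", "gradual", "burst", "cte_mtoc"),
                            penetrance = 0,
                            burst_penetrance = 0,
                            k_tx = 8,
                            k_exp_max = 2,
                            burst_threshold = 100,
                            ms2_saturation = NULL,
                            burst_duration = 0.25,
                            transition_duration_mean = 9.0,
                            transition_duration_sd = 3.4,
                            cn_plateau_mean = 3.2,
                            cn_plateau_sd = 0.5,
                            mt_speed = 0.6,
                            mt_run_length = 3,
                            mt_attach_prob = 0.1,
                            mtoc_capture_radius = 1.0,
                            mtoc_dwell_mean = 240,
                            mtoc_occupancy = 0.75,
                            nocodazole = FALSE,
                            D_nuc = 0.05,
                            D_cyt = 0.5,
                            ms2_pool = 2.4e6,
                            loops_per_transcript = 24L,
                            coats_per_transcript = 48L,
                            rev_onset_mean = 8,
                            rev_onset_sd = 2,
                            k_translate = 2,
                            vlp_onset_mean = NA_real_,
                            vlp_onset_sd = NA_real_,
                            vlp_onset_min = 5,
                            punctae_enrichment = 2.8,
                            tx_onset = 4,
                            n_cells = 30L,
                            seed = 1L) {
  export_mode <- match.arg(export_mode)
  ms2_saturation <- ms2_saturation %||%
    (if (export_mode == "cte_mtoc") 150L else 30L)
  cfg <- list(
    name = name, export_mode = export_mode,
    penetrance = penetrance, burst_penetrance = burst_penetrance,
    k_tx = k_tx, k_exp_max = k_exp_max,
    burst_threshold = as.integer(burst_threshold),
    ms2_saturation = as.integer(ms2_saturation),
    burst_duration = burst_duration,
    transition_duration_mean = transition_duration_mean,
    transition_duration_sd = transition_duration_sd,
    cn_plateau_mean = cn_plateau_mean, cn_plateau_sd = cn_plateau_sd,
    mt_speed = mt_speed, mt_run_length = mt_run_length,
    mt_attach_prob = mt_attach_prob,
    mtoc_capture_radius = mtoc_capture_radius,
    mtoc_dwell_mean = mtoc_dwell_mean, mtoc_occupancy = mtoc_occupancy,
    nocodazole = isTRUE(nocodazole),
    D_nuc = D_nuc, D_cyt = D_cyt,
    ms2_pool = ms2_pool,
    loops_per_transcript = as.integer(loops_per_transcript),
    coats_per_transcript = as.integer(coats_per_transcript),
    rev_onset_mean = rev_onset_mean, rev_onset_sd = rev_onset_sd,
    k_translate = k_translate,
    vlp_onset_mean = vlp_onset_mean, vlp_onset_sd = vlp_onset_sd,
    vlp_onset_min = vlp_onset_min,
    punctae_enrichment = punctae_enrichment,
    tx_onset = tx_onset,
    n_cells = as.integer(n_cells), seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks every invariant of the configuration and stops with a
#' configuration error naming the offending field.
#'
#' @param config a \code{scenario_config}.
#' @return the config, invisibly, if valid.
#' @export
validate_scenario_config <- function(config) {
  fail <- function(field, why) {
    stop(sprintf("configuration error in field '%s': %s", field, why),
         call. = FALSE)
  }
  rates <- c("k_tx", "k_exp_max", "burst_duration", "mt_speed",
             "mt_run_length", "mtoc_capture_radius", "mtoc_dwell_mean",
             "D_nuc", "D_cyt", "ms2_pool", "k_translate",
             "transition_duration_mean", "transition_duration_sd")
  for (f in rates) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      fail(f, "must be a non-negative number")
  }
  for (f in c("penetrance", "burst_penetrance", "mt_attach_prob",
              "mtoc_occupancy")) {
    v <- config[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      fail(f, "must be a probability in [0, 1]")
  }
  if (config$burst_penetrance > config$penetrance + 1e-12 &&
      config$export_mode %in% c("burst", "gradual"))
    fail("burst_penetrance", "burst cells are a subset of penetrant cells")
  if (config$burst_threshold < 1)
    fail("burst_threshold", "must be a positive integer")
  if (is.null(config$ms2_saturation) || config$ms2_saturation < 1)
    fail("ms2_saturation", "must be a positive integer")
  if (config$loops_per_transcript != 24L)
    fail("loops_per_transcript", "MS2 cassette carries 24 binding loops")
  if (config$coats_per_transcript > 48L || config$coats_per_transcript < 1L)
    fail("coats_per_transcript", "at most 48 coat proteins bind per transcript")
  if (!is.na(config$vlp_onset_mean)) {
    if (is.na(config$vlp_onset_sd) || config$vlp_onset_sd < 0)
      fail("vlp_onset_sd", "must be non-negative when VLP onset is enabled")
    if (config$vlp_onset_min > config$vlp_onset_mean)
      fail("vlp_onset_min", "must not exceed vlp_onset_mean")
  }
  if (!is.na(config$rev_onset_mean) && config$rev_onset_mean < 0)
    fail("rev_onset_mean", "must be non-negative")
  if (config$punctae_enrichment < 1)
    fail("punctae_enrichment", "fold-enrichment must be >= 1")
  if (config$n_cells < 1) fail("n_cells", "need at least one cell")
  invisible(config)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s\n", x$name))
  cat(sprintf("  export mode: %s%s\n", x$export_mode,
              if (x$nocodazole) " (nocodazole)" else ""))
  cat(sprintf("  penetrance: %.3f (burst %.3f)\n",
              x$penetrance, x$burst_penetrance))
  cat(sprintf("  k_tx: %g/h  pool: %g  threshold: %d transcripts\n",
              x$k_tx, x$ms2_pool, x$burst_threshold))
  invisible(x)
}

#' Registry of named experimental scenario presets
#'
#' Returns the catalog of preconfigured experimental conditions. Penetrance
#' fractions, transition and burst durations, VLP onset distributions,
#' microtubule speed, MS2 stoichiometry and the punctae enrichment are the
#' published values for each condition; diffusion coefficients, the
#' transcription rate and the burst threshold are free defaults chosen for a
#' realistic HeLa-like cell.
#'
#' Presets (transcript / trans-acting factors):
#' \describe{
#'   \item{dEE}{transcript without an export element: nucleus-retained.}
#'   \item{RRE_noRev}{RRE transcript, no Rev: nucleus-retained punctae; the
#'     reference condition for the 2.8-fold punctae enrichment.}
#'   \item{RRE_Rev}{RRE + Rev-mCherry: 74.3\% of cells become
#'     cytoplasmic-dominant, 30\% show burst export; gradual transitions run
#'     9.0 +/- 3.4 h; VLP onset 20.3 +/- 8.07 h (never before 5 h).}
#'   \item{RRE_RevM10}{RRE + RevM10 (CRM1-binding dead): no export.}
#'   \item{1xCTE}{single CTE: weak NXF1-dependent export, rare MTOC capture.}
#'   \item{4xCTE}{four CTE copies: NXF1/NXT1 export with MTOC clustering;
#'     VLP onset 16.7 +/- 8.06 h.}
#'   \item{4xCTE_nocodazole}{as 4xCTE with microtubules depolymerized:
#'     transcripts arrest at the nuclear envelope, MTOC clustering abolished.}
#'   \item{MS2Rev_dEEgRNA}{Rev tethered via MS2 to an export-element-free
#'     gRNA: burst export in 8.9\% of cells.}
#'   \item{MS2NXF1}{NXF1 tethered via MS2: MTOC targeting in >20\% of cells.}
#'   \item{RevNXF1}{Rev-NXF1 fusion on the RRE: burst in 11.5\% of cells.}
#'   \item{RevNXF1_NXT1}{Rev-NXF1 + NXT1: bursts abolished, MTOC targeting in
#'     6.8\% of cells.}
#'   \item{RevM10NXF1_NXT1}{RevM10-NXF1 + NXT1: MTOC targeting in 17.7\%.}
#'   \item{HIV_fulllength}{full-length HIV-1 reporter genome: burst program.}
#'   \item{MPMV}{full-length M-PMV reporter genome: MTOC targeting in >10\%.}
#' }
#'
#' @return named list of \code{scenario_config} objects; every entry passes
#'   [validate_scenario_config()].
#' @export
scenario_registry <- function() {
  presets <- list(
    dEE = scenario_config("dEE", "none", rev_onset_mean = NA_real_),
    RRE_noRev = scenario_config("RRE_noRev", "none",
                                rev_onset_mean = NA_real_),
    RRE_Rev = scenario_config("RRE_Rev", "burst",
                              penetrance = 0.743, burst_penetrance = 0.30,
                              vlp_onset_mean = 20.3, vlp_onset_sd = 8.07),
    RRE_RevM10 = scenario_config("RRE_RevM10", "none"),
    `1xCTE` = scenario_config("1xCTE", "cte_mtoc",
                              penetrance = 0.05, rev_onset_mean = NA_real_,
                              k_exp_max = 0.1),
    `4xCTE` = scenario_config("4xCTE", "cte_mtoc",
                              penetrance = 0.50, rev_onset_mean = NA_real_,
                              vlp_onset_mean = 16.7, vlp_onset_sd = 8.06),
    `4xCTE_nocodazole` = scenario_config("4xCTE_nocodazole", "cte_mtoc",
                                         penetrance = 0.50,
                                         rev_onset_mean = NA_real_,
                                         nocodazole = TRUE,
                                         vlp_onset_mean = 16.7,
                                         vlp_onset_sd = 8.06),
    MS2Rev_dEEgRNA = scenario_config("MS2Rev_dEEgRNA", "burst",
                                     penetrance = 0.089,
                                     burst_penetrance = 0.089),
    MS2NXF1 = scenario_config("MS2NXF1", "cte_mtoc", penetrance = 0.20,
                              rev_onset_mean = NA_real_),
    RevNXF1 = scenario_config("RevNXF1", "burst",
                              penetrance = 0.115, burst_penetrance = 0.115),
    RevNXF1_NXT1 = scenario_config("RevNXF1_NXT1", "cte_mtoc",
                                   penetrance = 0.068),
    RevM10NXF1_NXT1 = scenario_config("RevM10NXF1_NXT1", "cte_mtoc",
                                      penetrance = 0.177),
    HIV_fulllength = scenario_config("HIV_fulllength", "burst",
                                     penetrance = 0.743,
                                     burst_penetrance = 0.30,
                                     vlp_onset_mean = 20.3,
                                     vlp_onset_sd = 8.07),
    MPMV = scenario_config("MPMV", "cte_mtoc", penetrance = 0.10,
                           rev_onset_mean = NA_real_)
  )
  for (p in presets) validate_scenario_config(p)
  presets
}
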