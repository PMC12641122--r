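#' Pipeline run configuration
#'
#' Bundles every analysis constant with its standard default: the 16-band
#' spectral grid; 5-s fE/I windows with 80% overlap; DFA fit range 0.4-30 s
#' and gate 0.6; 2-min minimum quiet-wake duration; PAC grids with a 10-min
#' monthly target; NEO event-detection constants; the vigilance state used
#' by each analysis (quiet wake for fE/I, active wake for PAC, all states
#' for event detection); and the significance conventions (alpha = 0.01
#' primary, 0.01-0.05 marginal, no formal correction across bands).
#' Overrides are recorded in the returned object.
#'
#' Beyond the scientific constants, `fei_channels` / `pac_channels`
#' (restrict an analysis to a channel subset) and `pac_grids_override` (a
#' fixed [pac_grids()] list for all channels) trade coverage for speed in
#' simulation studies.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    grid = band_grid(),
    fei_window_s = 5, fei_overlap = 0.8,
    dfa_fit_range_s = c(0.4, 30), beta_threshold = 0.6,
    min_quiet_s = 120, min_windows = 40,
    pac_target_minutes = 10, pac_phase_step = 1, pac_amp_step = NULL,
    pac_grids_override = NULL, fei_channels = NULL,
    pac_channels = NULL,
    k_thresh = 8,
    fei_state = "quiet_wake", pac_state = "active_wake",
    alpha = 0.01, alpha_marginal = 0.05, fdr_q = 0.05,
    seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("run_config: unknown option(s) ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg$overrides <- names(ov)
  class(cfg) <- "run_config"
  cfg
}

# Analysis region label: HC channels are kept separate per CA1 layer; PTC
# and PFC are their own regions. Regions are never pooled.
region_label <- function(channels) {
  ifelse(channels$region == "HC", paste0("HC_", channels$hc_layer),
         channels$region)
}

#' Band-resolved weekly fE/I for a whole cohort
#'
#' Runs [fei_spectrum()] for every recording and channel. Recordings with
#' insufficient quiet wake are excluded (logged with reason); per-band
#' missingness is typed in the output.
#'
#' @param cohort an `lfp_cohort` (see [gen_cohort()]).
#' @param config a [run_config()].
#' @return list with `table` (tidy rows: subject, genotype, ages, channel,
#'   region, band, fei, r, dfa_beta, n_windows, missing_reason) and
#'   `exclusions` (rec_id + reason).
#' @export
run_fei <- function(cohort, config = run_config()) {
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(cohort$manifest))) {
    m <- cohort$manifest[i, ]
    rec <- cohort$recordings[[m$rec_id]]
    track <- cohort$tracks[[m$rec_id]]
    reg <- region_label(rec$channels)
    use <- seq_len(nrow(rec$channels))
    if (!is.null(config$fei_channels)) {
      use <- use[rec$channels$name %in% config$fei_channels]
    }
    for (ci in use) {
      ch <- rec$channels$name[ci]
      sp <- fei_spectrum(rec, ch, config$grid, track,
                         state = config$fei_state,
                         min_total_s = config$min_quiet_s,
                         beta_threshold = config$beta_threshold,
                         min_windows = config$min_windows)
      if (!nrow(sp)) {
        excl[[length(excl) + 1L]] <- data.frame(
          rec_id = m$rec_id, channel = ch,
          reason = attr(sp, "excluded_reason"))
        next
      }
      sp$subject_id <- m$subject_id; sp$genotype <- m$genotype
      sp$age_week <- m$age_week; sp$age_month <- m$age_month
      sp$channel <- ch; sp$region <- reg[ci]
      rows[[length(rows) + 1L]] <- sp
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Monthly theta-gamma PAC for a whole cohort
#'
#' For every subject-month and every PTC/HC channel, concatenates the
#' month's weekly active-wake data (up to the 10-min target), computes the
#' comodulogram on the region-appropriate grid and the band-averaged
#' summaries.
#'
#' @inheritParams run_fei
#' @return tidy data.frame: subject, genotype, age_month, channel, region,
#'   theta_low_gamma, theta_high_gamma, theta_total_gamma (HC only),
#'   minutes_used, shortfall.
#' @export
run_pac <- function(cohort, config = run_config()) {
  mf <- cohort$manifest
  rows <- list()
  reg <- region_label(cohort$channels)
  for (sid in unique(mf$subject_id)) {
    for (mo in unique(mf$age_month[mf$subject_id == sid])) {
      ids <- mf$rec_id[mf$subject_id == sid & mf$age_month == mo]
      ids <- ids[order(mf$age_week[match(ids, mf$rec_id)])]
      recs <- cohort$recordings[ids]
      trks <- cohort$tracks[ids]
      fs <- recs[[1]]$fs
      use <- which(cohort$channels$region %in% c("PTC", "HC"))
      if (!is.null(config$pac_channels)) {
        use <- use[cohort$channels$name[use] %in% config$pac_channels]
      }
      for (ci in use) {
        ch <- cohort$channels$name[ci]
        is_hc <- cohort$channels$region[ci] == "HC"
        grids <- if (!is.null(config$pac_grids_override)) {
          config$pac_grids_override
        } else {
          pac_grids(if (is_hc) "hippocampal" else "cortical", fs,
                    phase_step = config$pac_phase_step,
                    amp_step = config$pac_amp_step)
        }
        mp <- monthly_pac(recs, trks, ch, grids,
                          target_minutes = config$pac_target_minutes,
                          state = config$pac_state)
        if (is.null(mp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid,
          genotype = mf$genotype[mf$subject_id == sid][1],
          age_month = mo, channel = ch, region = reg[ci],
          theta_low_gamma = mp$summary$theta_low_gamma,
          theta_high_gamma = mp$summary$theta_high_gamma,
          theta_total_gamma = if (is_hc) mp$summary$theta_total_gamma else NA_real_,
          minutes_used = mp$minutes_used, shortfall = mp$shortfall)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Epileptiform event catalogs and rates for a whole cohort
#'
#' Vigilance-agnostic detection on every recording; weekly rates per event
#' type.
#'
#' @inheritParams run_fei
#' @return list with `catalogs` (named by rec_id) and `rates` (tidy rows:
#'   subject, genotype, age_week, age_month, type, rate).
#' @export
run_events <- function(cohort, config = run_config()) {
  catalogs <- list(); rows <- list()
  for (i in seq_len(nrow(cohort$manifest))) {
    m <- cohort$manifest[i, ]
    cat <- detect_events(cohort$recordings[[m$rec_id]],
                         k_thresh = config$k_thresh)
    catalogs[[m$rec_id]] <- cat
    for (type in c("isolated_hc", "isolated_ctx", "giant", "swd")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = m$subject_id, genotype = m$genotype,
        age_week = m$age_week, age_month = m$age_month, type = type,
        rate = event_rate(cat, type))
    }
  }
  list(catalogs = catalogs, rates = do.call(rbind, rows))
}

#' Repeated-measures correlation sweeps linking fE/I, PAC and spiking
#'
#' Three analyses, each conducted separately per brain region (the three
#' hippocampal CA1 layers and PTC are never pooled): (1) monthly
#' channel-level fE/I vs theta-low-gamma PAC across every fE/I band;
#' (2) weekly mouse-level fE/I vs spike rate across every band, zero-rate
#' weeks excluded; (3) monthly PAC vs monthly mean spike rate, zero-rate
#' months excluded. Every analysis is computed separately per genotype.
#' Significance: alpha = 0.01 primary, 0.01-0.05 marginal.
#'
#' @param fei_table output table of [run_fei()].
#' @param pac_table output of [run_pac()].
#' @param rates rates table of [run_events()].
#' @param config a [run_config()].
#' @param spike_type event type for the spiking analyses
#'   (default `"isolated_hc"`).
#' @return list of data.frames `fei_pac`, `fei_spikes`, `pac_spikes`, each
#'   with one row per (region, band) or region: `r_rm`, `p`, `ci_lo`,
#'   `ci_hi`, `n_pairs`, `n_subjects`, `significance`.
#' @export
run_correlations <- function(fei_table, pac_table, rates,
                             config = run_config(),
                             spike_type = "isolated_hc") {
  sig_label <- function(p) {
    ifelse(p < config$alpha, "significant",
           ifelse(p < config$alpha_marginal, "marginal", "ns"))
  }
  rm_row <- function(pairs) {
    r <- tryCatch(rmcorr(pairs), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(r_rm = r$r_rm, p = r$p, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               n_pairs = r$n_pairs, n_subjects = r$n_subjects,
               significance = sig_label(r$p))
  }
  fei_table$metric <- "fei"; fei_table$value <- fei_table$fei
  regions <- intersect(unique(fei_table$region),
                       unique(pac_table$region))
  genotypes <- unique(fei_table$genotype)
  fp <- list(); fsp <- list(); psp <- list()
  for (gt in genotypes) {
    for (reg in regions) {
      ft <- fei_table[fei_table$region == reg & fei_table$genotype == gt, ]
      pt <- pac_table[pac_table$region == reg & pac_table$genotype == gt, ]
      if (!nrow(ft) || !nrow(pt)) next
      pt$value <- pt$theta_low_gamma
      for (b in unique(ft$band_label)) {
        fb <- ft[ft$band_label == b, ]
        agg <- weekly_to_monthly(fb)
        pairs <- tryCatch(match_fei_pac(agg$electrode_month, pt),
                          error = function(e) NULL)
        if (!is.null(pairs)) {
          row <- rm_row(pairs)
          if (!is.null(row)) {
            row$genotype <- gt; row$region <- reg; row$band_label <- b
            fp[[length(fp) + 1L]] <- row
          }
        }
      }
      rw <- rates[rates$type == spike_type & rates$genotype == gt, ]
      for (b in unique(ft$band_label)) {
        fb <- ft[ft$band_label == b, ]
        pairs <- tryCatch(match_fei_spikes(fb, rw), error = function(e) NULL)
        if (!is.null(pairs)) {
          row <- rm_row(pairs)
          if (!is.null(row)) {
            row$genotype <- gt; row$region <- reg; row$band_label <- b
            fsp[[length(fsp) + 1L]] <- row
          }
        }
      }
      pairs <- tryCatch(match_pac_spikes(pt, rw), error = function(e) NULL)
      if (!is.null(pairs)) {
        row <- rm_row(pairs)
        if (!is.null(row)) {
          row$genotype <- gt; row$region <- reg
          psp[[length(psp) + 1L]] <- row
        }
      }
    }
  }
  list(fei_pac = if (length(fp)) do.call(rbind, fp) else NULL,
       fei_spikes = if (length(fsp)) do.call(rbind, fsp) else NULL,
       pac_spikes = if (length(psp)) do.call(rbind, psp) else NULL)
}

#' End-to-end cohort analysis
#'
#' fE/I spectra, monthly PAC, event catalogs and rates, weekly-to-monthly
#' aggregation, monthly genotype contrasts on the low-gamma band and on
#' theta-low-gamma PAC, and the three correlation sweeps. Deterministic for
#' a fixed cohort and config.
#'
#' @inheritParams run_fei
#' @param fei_band band label for the genotype contrast
#'   (default `"35-45 Hz"`).
#' @return list with `fei`, `pac`, `events`, `aggregated`,
#'   `contrast_fei`, `contrast_pac`, `correlations`.
#' @export
run_all <- function(cohort, config = run_config(), fei_band = "35-45 Hz") {
  fei <- run_fei(cohort, config)
  pac <- run_pac(cohort, config)
  ev <- run_events(cohort, config)

  control <- unique(cohort$effects$genotype)[1]   # first genotype = control
  fei_tab <- fei$table
  fei_tab$metric <- "fei"; fei_tab$value <- fei_tab$fei
  agg <- weekly_to_monthly(fei_tab[fei_tab$band_label == fei_band, ])
  contrast_fei <- genotype_compare(agg$mouse_month, q = config$fdr_q,
                                   control = control)

  pac_mm <- stats::aggregate(theta_low_gamma ~ subject_id + genotype + age_month,
                             data = pac, FUN = mean, na.rm = TRUE)
  names(pac_mm)[names(pac_mm) == "theta_low_gamma"] <- "value"
  contrast_pac <- genotype_compare(pac_mm, q = config$fdr_q,
                                   control = control)

  corr <- run_correlations(fei$table, pac, ev$rates, config)
  list(fei = fei, pac = pac, events = ev, aggregated = agg,
       contrast_fei = contrast_fei, contrast_pac = contrast_pac,
       correlations = corr)
}
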