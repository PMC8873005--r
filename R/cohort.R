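#' Default acquisition protocols
#'
#' Current-clamp steps of -10 to +60 pA in 5 pA increments (400 ms step,
#' 10 kHz); voltage-clamp steps of -90 to +40 mV in 10 mV increments from
#' a -70 mV holding potential (400 ms, 10 kHz); gap-free synaptic
#' recording (default 120 s at 5 kHz). These are package defaults chosen
#' to cover the dynamic range of the model cells; every field is
#' overridable.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Gap-free recording length, s (gap-free only).
#' @name default_protocols
NULL

#' @rdname default_protocols
#' @export
cc_protocol <- function(fs = 10000) {
  protocol_spec("current_clamp_steps", holding = 0,
                steps = seq(-10, 60, by = 5),
                t_on = 0.05, t_off = 0.45, duration = 0.5, fs = fs)
}

#' @rdname default_protocols
#' @export
vc_protocol <- function(fs = 10000) {
  protocol_spec("voltage_clamp_steps", holding = -70,
                steps = seq(-90, 40, by = 10),
                t_on = 0.05, t_off = 0.45, duration = 0.5, fs = fs)
}

#' @rdname default_protocols
#' @export
gapfree_protocol <- function(duration_s = 120, fs = 5000) {
  protocol_spec("gap_free", duration = duration_s, fs = fs)
}

# Per-condition generative means. Conductances in nS, capacitance pF,
# synaptic rates Hz. The ordering across conditions encodes the
# developmental phenotype the generator emulates: the mutant starts with
# larger Na/K conductances (hyperexcitable, deep fast AHP, narrow spike)
# and crosses below control by week 11, where its synaptic traffic also
# collapses (lower event and burst rates, much longer interburst
# spacing).
condition_presets <- function() {
  tibble::tribble(
    ~genotype, ~week, ~c_m, ~g_na, ~g_kd, ~g_a, ~g_m, ~g_l,
    ~syn_rate, ~syn_amp, ~burst_rate, ~burst_event_rate, ~burst_duration,
    "control", 5, 25, 40, 14, 1.5, 4.0, 1.0, 0.20, 20, 0.000, 0, 0.3,
    "mutant", 5, 25, 120, 30, 8.0, 4.0, 1.0, 0.20, 28, 0.000, 0, 0.3,
    "control", 7, 28, 80, 14, 2.0, 4.0, 1.0, 0.50, 20, 0.000, 0, 0.3,
    "mutant", 7, 29, 130, 45, 12.0, 4.0, 1.0, 0.50, 22, 0.000, 0, 0.3,
    "control", 11, 52, 220, 38, 6.0, 4.0, 1.2, 0.30, 25, 0.120, 25, 0.4,
    "mutant", 11, 51, 130, 28, 6.0, 4.0, 1.2, 0.10, 25, 0.015, 25, 0.3
  )
}

#' Specify a simulated control/mutant cohort
#'
#' Describes the per-condition parameter distributions (means from the
#' developmental preset, log-normal spread for conductances, normal for
#' capacitance), the synaptic-input statistics, the number of cells per
#' condition and the master seed. The default preset encodes the
#' developmental contrast the generator emulates: mutant weeks 5 and 7
#' have larger `g_na`, `g_kd` and `g_a` than control; mutant week 11 has
#' smaller `g_na` and `g_kd`, about 0.14x the control synaptic event
#' rate, 0.125x the burst-epoch rate and 8x the interburst spacing.
#'
#' @param n_per_condition Cells per genotype-week condition (>= 1).
#' @param weeks Weeks in culture to include.
#' @param seed Master seed; per-cell child seeds are derived by a fixed
#'   counter scheme.
#' @param conductance_cv Coefficient of variation of conductances.
#' @param c_m_cv Coefficient of variation of capacitance.
#' @param noise_sd Current-noise SD passed to the simulators, pA.
#' @param presets Per-condition mean table; defaults to the built-in
#'   developmental preset (see Details in [condition_presets()] source).
#'
#' @return An object of class `ck_cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition = 20, weeks = c(5, 7, 11), seed = 1,
                        conductance_cv = 0.2, c_m_cv = 0.1, noise_sd = 2,
                        presets = condition_presets()) {
  if (n_per_condition < 1) stop("n_per_condition must be >= 1", call. = FALSE)
  if (conductance_cv < 0 || c_m_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (!all(weeks %in% presets$week)) {
    stop("unknown condition week(s): ",
         paste(setdiff(weeks, presets$week), collapse = ", "), call. = FALSE)
  }
  structure(list(n_per_condition = n_per_condition, weeks = weeks,
                 seed = seed, conductance_cv = conductance_cv,
                 c_m_cv = c_m_cv, noise_sd = noise_sd,
                 presets = presets[presets$week %in% weeks, ]),
            class = "ck_cohort_spec")
}

#' @export
print.ck_cohort_spec <- function(x, ...) {
  cat(sprintf("<ck_cohort_spec> %d conditions x %d cells, master seed %s\n",
              nrow(x$presets), x$n_per_condition, format(x$seed)))
  invisible(x)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean <= 0 || cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Draw the ground-truth parameter table of a cohort
#'
#' Samples per-cell biophysical and synaptic parameters from the cohort
#' spec. Fully determined by the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per cell: identifiers, condition,
#'   every [neuron_params()] conductance field, synaptic-rate fields
#'   (including the composite `total_syn_rate_hz`), and the derived
#'   per-protocol child seeds.
#' @export
draw_cohort <- function(spec) {
  stopifnot(inherits(spec, "ck_cohort_spec"))
  n <- spec$n_per_condition
  gt <- with_seed(spec$seed, purrr::map_dfr(seq_len(nrow(spec$presets)), function(i) {
    pr <- spec$presets[i, ]
    tibble::tibble(
      genotype = pr$genotype, week = pr$week, cell = seq_len(n),
      c_m = pmax(5, stats::rnorm(n, pr$c_m, spec$c_m_cv * pr$c_m)),
      g_na = rlnorm_mean_cv(n, pr$g_na, spec$conductance_cv),
      g_kd = rlnorm_mean_cv(n, pr$g_kd, spec$conductance_cv),
      g_a = rlnorm_mean_cv(n, pr$g_a, spec$conductance_cv),
      g_m = rlnorm_mean_cv(n, pr$g_m, spec$conductance_cv),
      g_l = rlnorm_mean_cv(n, pr$g_l, spec$conductance_cv),
      syn_rate_hz = pr$syn_rate, syn_amp_pA = pr$syn_amp,
      burst_rate_hz = pr$burst_rate,
      burst_event_rate_hz = pr$burst_event_rate,
      burst_duration_s = pr$burst_duration
    )
  }))
  gt$total_syn_rate_hz <- gt$syn_rate_hz +
    gt$burst_rate_hz * gt$burst_event_rate_hz * gt$burst_duration_s
  gt$cell_id <- sprintf("%s_w%02d_c%03d", gt$genotype, gt$week, gt$cell)
  gt$cell_index <- seq_len(nrow(gt))
  gt$seed_cc <- derive_seed(spec$seed, gt$cell_index, 1)
  gt$seed_vc <- derive_seed(spec$seed, gt$cell_index, 2)
  gt$seed_syn <- derive_seed(spec$seed, gt$cell_index, 3)
  gt
}

cell_neuron_params <- function(row, noise_sd) {
  neuron_params(c_m = row$c_m, g_na = row$g_na, g_kd = row$g_kd,
                g_a = row$g_a, g_m = row$g_m, g_l = row$g_l,
                noise_sd = noise_sd)
}

cell_synaptic_stats <- function(row) {
  synaptic_stats(rate_hz = row$syn_rate_hz, amp_mean_pA = row$syn_amp_pA,
                 burst_rate_hz = row$burst_rate_hz,
                 burst_event_rate_hz = row$burst_event_rate_hz,
                 burst_duration_s = row$burst_duration_s)
}

simulate_cell <- function(row, noise_sd,
                          protocols = c("current_clamp", "voltage_clamp", "gap_free"),
                          cc_proto = cc_protocol(), vc_proto = vc_protocol(),
                          gap_proto = gapfree_protocol()) {
  p <- cell_neuron_params(row, noise_sd)
  out <- list()
  if ("current_clamp" %in% protocols) {
    out$cc <- simulate_current_clamp(p, cc_proto, seed = row$seed_cc,
                                     cell_id = row$cell_id,
                                     genotype = row$genotype, week = row$week)
  }
  if ("voltage_clamp" %in% protocols) {
    out$vc <- simulate_voltage_clamp(p, vc_proto, seed = row$seed_vc,
                                     cell_id = row$cell_id,
                                     genotype = row$genotype, week = row$week)
  }
  if ("gap_free" %in% protocols) {
    out$syn <- simulate_synaptic_recording(cell_synaptic_stats(row),
                                           duration_s = gap_proto$duration,
                                           fs = gap_proto$fs,
                                           noise_sd = noise_sd,
                                           seed = row$seed_syn)
  }
  out
}

#' Generate a labelled control/mutant cohort of recordings
#'
#' Draws `n` cells per condition from the cohort spec and simulates, for
#' each cell, the requested recordings: a current-clamp step family, a
#' voltage-clamp step family, and a gap-free synaptic recording. The
#' master seed fully determines the output.
#'
#' @param spec A [cohort_spec()].
#' @param protocols Which recordings to simulate per cell.
#' @param cc_proto,vc_proto,gap_proto Protocol overrides.
#'
#' @return A list of class `ck_cohort`: `ground_truth` (tibble from
#'   [draw_cohort()]) and `cells` (named list; per cell a list with
#'   elements `cc`, `vc` ([sweep_set()]s) and `syn`
#'   (`ck_synth_recording`) as requested).
#' @export
generate_cohort <- function(spec,
                            protocols = c("current_clamp", "voltage_clamp", "gap_free"),
                            cc_proto = cc_protocol(), vc_proto = vc_protocol(),
                            gap_proto = gapfree_protocol()) {
  stopifnot(inherits(spec, "ck_cohort_spec"))
  gt <- draw_cohort(spec)
  cells <- lapply(seq_len(nrow(gt)), function(i) {
    simulate_cell(gt[i, ], spec$noise_sd, protocols,
                  cc_proto, vc_proto, gap_proto)
  })
  names(cells) <- gt$cell_id
  structure(list(ground_truth = gt, cells = cells), class = "ck_cohort")
}

#' @export
print.ck_cohort <- function(x, ...) {
  cat(sprintf("<ck_cohort> %d cells, %d conditions\n", nrow(x$ground_truth),
              nrow(unique(x$ground_truth[, c("genotype", "week")]))))
  invisible(x)
}

#' Extract the full feature record of one cell
#'
#' Combines the excitability summary and rheobase-spike shape (current
#' clamp), capacitance and I-V peaks (voltage clamp), and detected EPSC
#' and burst statistics (gap-free) into a single feature row. Missing
#' recordings leave their features `NA`; QC flags record why.
#'
#' @param cc Current-clamp [sweep_set()] or `NULL`.
#' @param vc Voltage-clamp [sweep_set()] or `NULL`.
#' @param syn Gap-free current [trace()], `ck_synth_recording`, or `NULL`.
#' @param cell_id,genotype,week Labels (taken from `cc`/`vc` when absent).
#' @param ... Passed to the feature extractors.
#'
#' @return A one-row tibble (one cell per row): identifiers, excitability,
#'   spike shape, capacitance, peak currents, synaptic and burst
#'   statistics, and a `qc` list column of flag strings.
#' @export
extract_cell_features <- function(cc = NULL, vc = NULL, syn = NULL,
                                  cell_id = NULL, genotype = NULL,
                                  week = NULL, ...) {
  src <- cc %||% vc
  cell_id <- cell_id %||% src$cell_id %||% "cell"
  genotype <- genotype %||% src$genotype %||% NA_character_
  week <- week %||% src$week %||% NA_real_
  qc <- character(0)

  exc <- tibble::tibble(total_evoked = NA_real_, max_per_step = NA_real_,
                        rheobase_pA = NA_real_)
  shape <- tibble::tibble(threshold_mV = NA_real_, amplitude_mV = NA_real_,
                          fwhm_ms = NA_real_, fahp_mV = NA_real_)
  if (!is.null(cc)) {
    es <- excitability_summary(cc, ...)
    exc <- es[, c("total_evoked", "max_per_step", "rheobase_pA")]
    fs <- first_spike_features(cc, ...)
    shape <- fs[, c("threshold_mV", "amplitude_mV", "fwhm_ms", "fahp_mV")]
    if (es$total_evoked == 0) qc <- c(qc, "no_spikes")
  }

  vcf <- tibble::tibble(capacitance_pF = NA_real_, na_peak_pA = NA_real_,
                        kfast_peak_pA = NA_real_, kslow_peak_pA = NA_real_)
  if (!is.null(vc)) {
    vf <- vclamp_features(vc)
    if (is.na(vf$capacitance_pF)) qc <- c(qc, "no_transient")
    vcf <- tibble::tibble(capacitance_pF = vf$capacitance_pF,
                          na_peak_pA = min(vf$iv$na_peak_pA),
                          kfast_peak_pA = max(vf$iv$kfast_peak_pA),
                          kslow_peak_pA = max(vf$iv$kslow_pA))
  }

  syn_row <- tibble::tibble(epsc_rate_hz = NA_real_,
                            epsc_amp_mean_pA = NA_real_,
                            epsc_amplitudes = list(numeric(0)),
                            n_bursts = NA_real_, burst_rate_hz = NA_real_,
                            burst_duration_s = NA_real_,
                            interburst_s = NA_real_)
  if (!is.null(syn)) {
    syn_tr <- if (inherits(syn, "ck_synth_recording")) syn$trace else syn
    if (trace_duration(syn_tr) < 10) qc <- c(qc, "short_recording")
    ev <- detect_events(syn_tr)
    st <- event_statistics(ev, trace_duration(syn_tr))
    bu <- detect_bursts(ev$time_s, trace_duration(syn_tr))
    syn_row <- tibble::tibble(epsc_rate_hz = st$rate_hz,
                              epsc_amp_mean_pA = st$mean_amplitude_pA,
                              epsc_amplitudes = list(ev$amplitude_pA),
                              n_bursts = bu$n_bursts,
                              burst_rate_hz = bu$burst_rate_hz,
                              burst_duration_s = bu$mean_duration_s,
                              interburst_s = bu$mean_interburst_s)
  }

  dplyr::bind_cols(
    tibble::tibble(cell_id = cell_id, genotype = genotype, week = week),
    exc, shape, vcf, syn_row, tibble::tibble(qc = list(qc))
  )
}

#' Simulate a cohort and extract its feature table in one pass
#'
#' Streams cell by cell (simulate, extract, discard the raw traces), so
#' arbitrarily large cohorts fit in memory. Equivalent to
#' [generate_cohort()] followed by [extract_cell_features()] on every
#' cell.
#'
#' @inheritParams generate_cohort
#' @param ... Passed to the feature extractors.
#' @return A list: `features` (tibble, one row per cell), `ground_truth`
#'   (tibble from [draw_cohort()]).
#' @export
cohort_features <- function(spec,
                            protocols = c("current_clamp", "voltage_clamp", "gap_free"),
                            cc_proto = cc_protocol(), vc_proto = vc_protocol(),
                            gap_proto = gapfree_protocol(), ...) {
  stopifnot(inherits(spec, "ck_cohort_spec"))
  gt <- draw_cohort(spec)
  feats <- purrr::map_dfr(seq_len(nrow(gt)), function(i) {
    rec <- simulate_cell(gt[i, ], spec$noise_sd, protocols,
                         cc_proto, vc_proto, gap_proto)
    extract_cell_features(cc = rec$cc, vc = rec$vc, syn = rec$syn,
                          cell_id = gt$cell_id[i], genotype = gt$genotype[i],
                          week = gt$week[i], ...)
  })
  list(features = feats, ground_truth = gt)
}
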