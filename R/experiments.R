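# Experiment harness: the one-at-a-time acquisition parameter sweep and
# the three-protocol comparison, with deterministic per-scan seeding.

#' Acquisition parameter sweep conditions
#'
#' The baseline protocol (3000 radial views, 5 bins, 3 mm slices, axial)
#' plus the tested one-at-a-time modifications: 1500/2000 views, 4/7/10
#' bins, 1.5/2 mm slices, coronal orientation.  Exactly one field differs
#' from baseline in every non-baseline row.
#'
#' @return Data frame with `condition`, `n_spokes`, `n_bins`,
#'   `slice_thickness_mm`, `orientation`.
#' @export
sweep_conditions <- function() {
  base <- data.frame(condition = "baseline", n_spokes = 3000L, n_bins = 5L,
                     slice_thickness_mm = 3, orientation = "axial")
  vary <- rbind(
    data.frame(condition = c("views_1500", "views_2000"),
               n_spokes = c(1500L, 2000L), n_bins = 5L,
               slice_thickness_mm = 3, orientation = "axial"),
    data.frame(condition = c("bins_4", "bins_7", "bins_10"),
               n_spokes = 3000L, n_bins = c(4L, 7L, 10L),
               slice_thickness_mm = 3, orientation = "axial"),
    data.frame(condition = c("thickness_1.5", "thickness_2"),
               n_spokes = 3000L, n_bins = 5L,
               slice_thickness_mm = c(1.5, 2), orientation = "axial"),
    data.frame(condition = "coronal", n_spokes = 3000L, n_bins = 5L,
               slice_thickness_mm = 3, orientation = "coronal"))
  rbind(base, vary)
}

# deterministic per-scan seed from the master seed and the scan's place in
# the design; stays below 2^31
scan_seed <- function(master, condition_index, waveform_index, replicate) {
  (((master %% 1048576) * 1009 + condition_index * 10007 +
      waveform_index * 257 + replicate * 13) %% 2147483629) + 1
}

# rotate a trace's time origin: scans start at an arbitrary point of the
# breathing cycle, which is the physical source of replicate-to-replicate
# variability for a deterministic waveform
rotate_trace <- function(trace, offset_s) {
  a <- trace_position(trace, trace$t + offset_s)
  respiratory_trace(trace$t, a, label = trace$label,
                    category = trace$category)
}

#' Run the one-at-a-time acquisition parameter sweep
#'
#' Simulates every condition for every waveform with `replicates` repeated
#' scans, measures the extreme-bin FWHM displacement of each, and returns
#' one row per scan.  Each scan gets a deterministic seed derived from
#' `master_seed` and its position in the design, and starts at a seeded
#' random point of the breathing cycle (the replicate-to-replicate
#' variability of a repeated acquisition).  Stage errors are recorded
#' per-row and the run continues.
#'
#' @param waveforms Named list of [respiratory_trace()]s.
#' @param conditions Data frame like [sweep_conditions()].
#' @param replicates Repeated scans per condition and waveform.
#' @param master_seed Master seed for the scan seed derivation.
#' @param spec A [phantom_spec()].
#' @param acq_base Baseline [acquisition_params()] supplying the fields
#'   the sweep does not vary (matrix, FOV, slab, TR, noise).
#' @param summary Edge combination rule, see [measure_displacement()].
#' @param half_length_mm Profile half-extent, see [extract_profile()].
#' @param verbose Log one line per scan.
#' @return Data frame: `scan_id`, `condition`, acquisition fields,
#'   `waveform_id`, `waveform_category`, `ground_truth_pp` (mean
#'   per-cycle excursion), `replicate`, `displacement`, `sup_shift`,
#'   `inf_shift`, `background_sd`, `seed`, `error`.
#' @export
run_sweep <- function(waveforms, conditions = sweep_conditions(),
                      replicates = 4, master_seed = 1,
                      spec = phantom_spec(),
                      acq_base = acquisition_params(), summary = "mean",
                      half_length_mm = 36, verbose = FALSE) {
  stopifnot(replicates >= 1, is.list(waveforms), length(waveforms) >= 1)
  if (is.null(names(waveforms)) || any(!nzchar(names(waveforms)))) {
    names(waveforms) <- sprintf("waveform_%02d", seq_along(waveforms))
  }
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (wi in seq_along(waveforms)) {
      wf <- waveforms[[wi]]
      gt <- tryCatch(mean_max_amplitude(wf), error = function(e) NA_real_)
      for (ri in seq_len(replicates)) {
        seed <- scan_seed(master_seed, ci, wi, ri)
        scan_id <- sprintf("%s_%s_r%d", cond$condition,
                           names(waveforms)[wi], ri)
        res <- tryCatch({
          tr <- with_seed(seed, {
            rotate_trace(wf, stats::runif(1, 0, trace_duration(wf)))
          })
          acq <- acquisition_params(
            n_spokes = cond$n_spokes, n_bins = cond$n_bins,
            slice_thickness_mm = cond$slice_thickness_mm,
            orientation = cond$orientation, matrix = acq_base$matrix,
            fov_mm = acq_base$fov_mm, slab_mm = acq_base$slab_mm,
            tr_ms = acq_base$tr_ms, noise_sigma = acq_base$noise_sigma,
            seed = seed)
          set <- simulate_mr(tr, acq, spec)
          m <- measure_set_displacement(set, summary = summary,
                                        half_length_mm = half_length_mm)
          list(disp = m$displacement, sup = m$sup_shift,
               inf = m$inf_shift, bsd = background_sd(set), err = NA_character_)
        }, error = function(e) {
          list(disp = NA_real_, sup = NA_real_, inf = NA_real_,
               bsd = NA_real_, err = conditionMessage(e))
        })
        if (verbose) {
          message(sprintf("[sweep] %s displacement=%.3f seed=%d",
                          scan_id, res$disp, seed))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = scan_id, condition = cond$condition,
          n_spokes = cond$n_spokes, n_bins = cond$n_bins,
          slice_thickness_mm = cond$slice_thickness_mm,
          orientation = cond$orientation,
          waveform_id = names(waveforms)[wi],
          waveform_category = wf$category, ground_truth_pp = gt,
          replicate = ri, displacement = res$disp, sup_shift = res$sup,
          inf_shift = res$inf, background_sd = res$bsd, seed = seed,
          error = res$err)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare the three clinical protocols
#'
#' Runs the axial 5-bin MR protocol, the modified coronal 10-bin MR
#' protocol and the 10-phase CT protocol on every waveform with
#' `replicates` repeated scans each, and fits the linear mixed-effects
#' comparison against the coronal MR reference.
#'
#' @inheritParams run_sweep
#' @param replicates Repeated scans per protocol and waveform (default 5).
#' @param ct_slice_thickness_mm CT slice thickness, mm.
#' @param reference Reference protocol for [lmm_compare()].
#' @return List with `table` (one row per scan, protocol in
#'   `{MR_axial_5bin, MR_coronal_10bin, CT}`) and `lmm` (an `lmm_result`,
#'   or `NULL` if the fit failed).
#' @export
run_protocol_comparison <- function(waveforms, replicates = 5,
                                    master_seed = 1, spec = phantom_spec(),
                                    acq_base = acquisition_params(),
                                    ct_slice_thickness_mm = 2.5,
                                    summary = "mean",
                                    reference = "MR_coronal_10bin",
                                    half_length_mm = 36, verbose = FALSE) {
  stopifnot(is.list(waveforms), length(waveforms) >= 1)
  if (is.null(names(waveforms)) || any(!nzchar(names(waveforms)))) {
    names(waveforms) <- sprintf("waveform_%02d", seq_along(waveforms))
  }
  protocols <- data.frame(
    protocol = c("MR_axial_5bin", "MR_coronal_10bin", "CT"),
    orientation = c("axial", "coronal", NA), n_bins = c(5L, 10L, 10L))
  rows <- list()
  for (pi in seq_len(nrow(protocols))) {
    prot <- protocols[pi, ]
    for (wi in seq_along(waveforms)) {
      wf <- waveforms[[wi]]
      gt <- tryCatch(mean_max_amplitude(wf), error = function(e) NA_real_)
      for (ri in seq_len(replicates)) {
        seed <- scan_seed(master_seed, pi + 100L, wi, ri)
        scan_id <- sprintf("%s_%s_r%d", prot$protocol,
                           names(waveforms)[wi], ri)
        res <- tryCatch({
          tr <- with_seed(seed, {
            rotate_trace(wf, stats::runif(1, 0, trace_duration(wf)))
          })
          set <- if (prot$protocol == "CT") {
            simulate_ct(tr, spec, n_phases = prot$n_bins,
                        slice_thickness_mm = ct_slice_thickness_mm,
                        seed = seed)
          } else {
            simulate_mr(tr, acquisition_params(
              n_spokes = acq_base$n_spokes, n_bins = prot$n_bins,
              slice_thickness_mm = acq_base$slice_thickness_mm,
              orientation = prot$orientation, matrix = acq_base$matrix,
              fov_mm = acq_base$fov_mm, slab_mm = acq_base$slab_mm,
              tr_ms = acq_base$tr_ms, noise_sigma = acq_base$noise_sigma,
              seed = seed), spec)
          }
          m <- measure_set_displacement(set, summary = summary,
                                        half_length_mm = half_length_mm)
          list(disp = m$displacement, err = NA_character_)
        }, error = function(e) {
          list(disp = NA_real_, err = conditionMessage(e))
        })
        if (verbose) {
          message(sprintf("[compare] %s displacement=%.3f seed=%d",
                          scan_id, res$disp, seed))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scan_id = scan_id, protocol = prot$protocol,
          waveform_id = names(waveforms)[wi],
          waveform_category = wf$category, ground_truth_pp = gt,
          replicate = ri, displacement = res$disp, seed = seed,
          error = res$err)
      }
    }
  }
  table <- do.call(rbind, rows)
  lmm <- tryCatch(
    suppressWarnings(lmm_compare(table, reference = reference)),
    error = function(e) NULL)
  list(table = table, lmm = lmm)
}

#' Read an experiment configuration from YAML
#'
#' Light-weight configuration support for scripted runs.  Recognised
#' blocks: `waveform` (`kind`, `pp_mm`, `period_s`, `category`, `seed`,
#' `duration_s`), `acquisition` (any [acquisition_params()] argument),
#' `ct` (`n_phases`, `slice_thickness_mm`, `sorting_artifacts`),
#' `replicates`, `master_seed`.
#'
#' @param path YAML file path.
#' @return Named list of configuration blocks.
#' @export
read_experiment_config <- function(path) {
  yaml::read_yaml(path)
}

#' Build a waveform from a configuration block
#'
#' @param cfg List with `kind` (`"sinusoid"` or `"patient"`) and the
#'   matching generator arguments.
#' @return A [respiratory_trace()].
#' @export
config_waveform <- function(cfg) {
  kind <- cfg$kind %||% "sinusoid"
  if (kind == "sinusoid") {
    generate_sinusoid(cfg$pp_mm %||% 10, cfg$period_s %||% 4,
                      cfg$duration_s %||% 60)
  } else {
    generate_patient_trace(cfg$category %||% "regular",
                           duration_s = cfg$duration_s %||% 120,
                           mean_pp_mm = cfg$pp_mm %||% 10,
                           period_s = cfg$period_s %||% 4,
                           seed = cfg$seed %||% 1L)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
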