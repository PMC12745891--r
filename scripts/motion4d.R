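#!/usr/bin/env Rscript
# Thin command-line wrapper over the motion4d package:
#
#   Rscript scripts/motion4d.R simulate     --config cfg.yaml --out dir
#   Rscript scripts/motion4d.R measure      --in dir --out measurements.csv
#   Rscript scripts/motion4d.R sweep        --config cfg.yaml --out sweep.csv
#   Rscript scripts/motion4d.R compare      --config cfg.yaml --out dir
#   Rscript scripts/motion4d.R stats        --in table.csv --group-by col --out dir
#   Rscript scripts/motion4d.R organ-tables --out dir
#
# Common flags: --seed <int>.  Config blocks are described in
# ?read_experiment_config.

suppressPackageStartupMessages(library(motion4d))

`%||%` <- function(a, b) if (is.null(a)) b else a

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: motion4d.R <subcommand> [--flags]")
cmd <- argv[1L]
flags <- list()
i <- 2L
while (i <= length(argv)) {
  key <- sub("^--", "", argv[i])
  flags[[key]] <- argv[i + 1L]
  i <- i + 2L
}
seed <- as.integer(flags$seed %||% 1L)
cfg <- if (!is.null(flags$config)) read_experiment_config(flags$config)
       else list()

cfg_acq <- function(cfg, seed) {
  a <- cfg$acquisition %||% list()
  acquisition_params(
    n_spokes = a$n_spokes %||% 3000, n_bins = a$n_bins %||% 5,
    slice_thickness_mm = a$slice_thickness_mm %||% 3,
    orientation = a$orientation %||% "axial",
    matrix = a$matrix %||% 128, fov_mm = a$fov_mm %||% 300,
    slab_mm = a$slab_mm %||% 90, tr_ms = a$tr_ms %||% 4.03,
    noise_sigma = a$noise_sigma %||% 0.006, seed = seed)
}

if (cmd == "simulate") {
  tr <- config_waveform(cfg$waveform %||% list())
  modality <- (cfg$modality %||% "MR")
  set <- if (toupper(modality) == "CT") {
    ct <- cfg$ct %||% list()
    simulate_ct(tr, n_phases = ct$n_phases %||% 10,
                slice_thickness_mm = ct$slice_thickness_mm %||% 2.5,
                sorting_artifacts = isTRUE(ct$sorting_artifacts),
                seed = seed)
  } else {
    simulate_mr(tr, cfg_acq(cfg, seed))
  }
  write_nifti_set(set, flags$out %||% "simulated_bins")
  message(sprintf("[simulate] wrote %d %s bins to %s", set$n_bins,
                  set$modality, flags$out %||% "simulated_bins"))
} else if (cmd == "measure") {
  set <- read_nifti_set(flags[["in"]])
  m <- measure_set_displacement(set)
  df <- data.frame(
    scan_id = basename(flags[["in"]]), modality = set$modality,
    n_bins = set$n_bins, orientation = set$grid$orientation,
    sup_shift_mm = m$sup_shift, inf_shift_mm = m$inf_shift,
    displacement_mm = m$displacement)
  write.csv(df, flags$out %||% stdout(), row.names = FALSE)
} else if (cmd == "sweep") {
  wf <- config_waveform(cfg$waveform %||% list())
  tab <- run_sweep(stats::setNames(list(wf), wf$label),
                   replicates = cfg$replicates %||% 4,
                   master_seed = cfg$master_seed %||% seed,
                   acq_base = cfg_acq(cfg, seed), verbose = TRUE)
  write.csv(tab, flags$out %||% "sweep.csv", row.names = FALSE)
} else if (cmd == "compare") {
  wcfgs <- cfg$waveforms %||% list(list(kind = "sinusoid", pp_mm = 10))
  wfs <- lapply(wcfgs, config_waveform)
  names(wfs) <- vapply(seq_along(wfs), function(k) {
    wcfgs[[k]]$name %||% sprintf("waveform_%02d", k)
  }, character(1))
  res <- run_protocol_comparison(wfs, replicates = cfg$replicates %||% 5,
                                 master_seed = cfg$master_seed %||% seed,
                                 acq_base = cfg_acq(cfg, seed),
                                 verbose = TRUE)
  out <- flags$out %||% "comparison"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$table, file.path(out, "measurements.csv"),
            row.names = FALSE)
  if (!is.null(res$lmm)) {
    write.csv(res$lmm$effects, file.path(out, "lmm_effects.csv"),
              row.names = FALSE)
    print(res$lmm)
  }
} else if (cmd == "stats") {
  tab <- read.csv(flags[["in"]])
  group <- flags[["group-by"]] %||% "condition"
  out <- flags$out %||% "stats"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  w <- welch_anova(tab, group)
  print(w)
  gh <- games_howell(tab, group)
  write.csv(gh, file.path(out, "games_howell.csv"), row.names = FALSE)
  if (!is.null(flags$reference)) {
    fit <- lmm_compare(tab, flags$reference)
    write.csv(fit$effects, file.path(out, "lmm_effects.csv"),
              row.names = FALSE)
    print(fit)
  }
} else if (cmd == "organ-tables") {
  ot <- organ_tables()
  out <- flags$out %||% "organ_tables"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(ot$per_patient, file.path(out, "per_patient.csv"),
            row.names = FALSE)
  write.csv(ot$means, file.path(out, "means.csv"), row.names = FALSE)
  write.csv(ot$differences, file.path(out, "differences.csv"),
            row.names = FALSE)
  write.csv(ot$flags, file.path(out, "flags.csv"), row.names = FALSE)
  message(sprintf("[organ-tables] wrote tables (%d flagged cells) to %s",
                  nrow(ot$flags), out))
} else {
  stop("unknown subcommand: ", cmd)
}
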