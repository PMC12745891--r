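# In-vivo organ displacement arithmetic: per-direction box-ROI
# translations, Euclidean norms, per-direction means, and CT-minus-MR
# modality difference tables.

#' Exact decimal half-up rounding
#'
#' Rounds half away from zero in decimal arithmetic (4.85 -> 4.9,
#' 4.05 -> 4.1), compensating binary floating-point representation so the
#' result matches hand-rounded table values; base R's banker's rounding
#' would give 4.8 / 4.0.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Euclidean displacement from per-direction translations
#'
#' Three-dimensional displacement magnitude
#' `sqrt(dx^2 + dy^2 + dz^2)`, reported like the clinical tables: decimal
#' half-up at one decimal place.
#'
#' @param dx,dy,dz Translations in mm (left-right, anterior-posterior,
#'   superior-inferior); vectorised.
#' @return Euclidean displacement in mm, one decimal.
#' @export
euclidean_displacement <- function(dx, dy, dz) {
  round_half_up(sqrt(dx^2 + dy^2 + dz^2), 1)
}

#' Mean of per-patient displacement values
#'
#' Arithmetic mean of the printed per-patient values, decimal half-up to
#' one decimal, as used for the per-direction table means.
#'
#' @param values Numeric vector of per-patient displacements in mm.
#' @return Mean in mm, one decimal.
#' @export
direction_means <- function(values) {
  if (!length(values) || !all(is.finite(values))) {
    stop("`values` must be a non-empty finite vector", call. = FALSE)
  }
  round_half_up(mean(values), 1)
}

#' Load the packaged per-patient organ displacement fixture
#'
#' Per-patient box-ROI translations (mm) of the liver and the
#' left/right-averaged kidneys for three compression-belt patients, as
#' printed in the clinical comparison tables, for CT, axial 5-bin MR and
#' coronal 10-bin MR 4D scans.  `euclid_mm` is the printed per-patient
#' Euclidean displacement (for kidneys this is the average of the left and
#' right kidney Euclidean displacements, which differs from the Euclidean
#' norm of the averaged components).
#'
#' @return Data frame with columns `patient_id`, `organ`, `modality`,
#'   `dx_mm`, `dy_mm`, `dz_mm`, `euclid_mm`.
#' @export
load_organ_displacements <- function() {
  utils::read.csv(system.file("extdata", "organ_displacements.csv",
                              package = "motion4d", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Load the packaged printed table means
#'
#' Printed per-direction, per-modality mean displacements for the same
#' tables.  Some printed means are not reproducible from the printed
#' per-patient values (the source tables were evidently computed from
#' unrounded data); they are kept verbatim here and flagged by
#' [organ_tables()].
#'
#' @return Data frame with columns `organ`, `modality`, `direction`
#'   (`dX`, `dY`, `dZ`, `euclidean`), `mean_mm`.
#' @export
load_organ_means <- function() {
  utils::read.csv(system.file("extdata", "organ_means.csv",
                              package = "motion4d", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Modality difference table (CT minus MR)
#'
#' Differences of the per-direction means: rows `CT-AX_MR` and
#' `CT-COR_MR` per organ, each entry at one decimal, computed from the
#' one-decimal (printed) means.  A positive value means the CT displacement
#' measurement was larger.
#'
#' @param means Data frame as returned by [load_organ_means()] (columns
#'   `organ`, `modality`, `direction`, `mean_mm`) containing `CT`,
#'   `AX_MR` and `COR_MR` for every organ/direction.
#' @return Data frame with columns `organ`, `comparison`, `direction`,
#'   `difference_mm`.
#' @export
modality_difference_table <- function(means) {
  need <- c("CT", "AX_MR", "COR_MR")
  out <- list()
  for (org in unique(means$organ)) {
    sub <- means[means$organ == org, ]
    for (dir in unique(sub$direction)) {
      row <- sub[sub$direction == dir, ]
      val <- function(mod) {
        v <- row$mean_mm[row$modality == mod]
        if (length(v) != 1L) {
          stop(sprintf("missing modality %s for %s/%s", mod, org, dir),
               call. = FALSE)
        }
        v
      }
      vals <- vapply(need, val, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        organ = org,
        comparison = c("CT-AX_MR", "CT-COR_MR"),
        direction = dir,
        difference_mm = round_half_up(
          c(vals["CT"] - vals["AX_MR"], vals["CT"] - vals["COR_MR"]), 1))
    }
  }
  do.call(rbind, out)
}

#' Rebuild the organ displacement tables and flag inconsistencies
#'
#' From the per-patient fixture, recomputes (a) each patient's Euclidean
#' displacement from its printed components, (b) the per-direction and
#' Euclidean means, and (c) the CT-minus-MR difference table from the
#' printed means.  Cells whose recomputed value disagrees with the printed
#' one are reported in `flags` rather than silently matched -- several
#' printed kidney means (and one liver Euclidean) are inconsistent with
#' the printed per-patient inputs, implying unrounded sources.
#'
#' @param per_patient Data frame like [load_organ_displacements()].
#' @param printed_means Data frame like [load_organ_means()], or `NULL` to
#'   use the recomputed means everywhere.
#' @return List with `per_patient` (plus recomputed `euclid_computed`),
#'   `means` (computed and, when supplied, printed), `differences` (from
#'   the printed means when available) and `flags` (data frame of
#'   mismatching cells).
#' @export
organ_tables <- function(per_patient = load_organ_displacements(),
                         printed_means = load_organ_means()) {
  pp <- per_patient
  pp$euclid_computed <- euclidean_displacement(pp$dx_mm, pp$dy_mm, pp$dz_mm)
  flags <- list()
  bad <- which(abs(pp$euclid_computed - pp$euclid_mm) > 1e-9)
  for (i in bad) {
    flags[[length(flags) + 1L]] <- data.frame(
      table = "per_patient_euclidean",
      cell = sprintf("%s/%s/patient %s", pp$organ[i], pp$modality[i],
                     pp$patient_id[i]),
      printed = pp$euclid_mm[i], computed = pp$euclid_computed[i])
  }
  dirs <- c(dX = "dx_mm", dY = "dy_mm", dZ = "dz_mm",
            euclidean = "euclid_mm")
  means <- do.call(rbind, lapply(unique(pp$organ), function(org) {
    do.call(rbind, lapply(unique(pp$modality), function(mod) {
      sub <- pp[pp$organ == org & pp$modality == mod, ]
      data.frame(organ = org, modality = mod, direction = names(dirs),
                 mean_computed = vapply(dirs, function(cl) {
                   direction_means(sub[[cl]])
                 }, numeric(1)), row.names = NULL)
    }))
  }))
  if (!is.null(printed_means)) {
    means <- merge(means, printed_means, sort = FALSE)
    names(means)[names(means) == "mean_mm"] <- "mean_printed"
    bad <- which(abs(means$mean_computed - means$mean_printed) > 1e-9)
    for (i in bad) {
      flags[[length(flags) + 1L]] <- data.frame(
        table = "direction_mean",
        cell = sprintf("%s/%s/%s", means$organ[i], means$modality[i],
                       means$direction[i]),
        printed = means$mean_printed[i], computed = means$mean_computed[i])
    }
    diff_in <- data.frame(organ = means$organ, modality = means$modality,
                          direction = means$direction,
                          mean_mm = means$mean_printed)
  } else {
    diff_in <- data.frame(organ = means$organ, modality = means$modality,
                          direction = means$direction,
                          mean_mm = means$mean_computed)
  }
  list(per_patient = pp, means = means,
       differences = modality_difference_table(diff_in),
       flags = if (length(flags)) do.call(rbind, flags) else
         data.frame(table = character(0), cell = character(0),
                    printed = numeric(0), computed = numeric(0)))
}

#' Rigid box-ROI translation between two volumes
#'
#' Estimates the translation of the inhale volume relative to the exhale
#' volume by maximising the normalised cross-correlation of a box region
#' of interest over integer voxel shifts, refined to sub-voxel precision
#' by quadratic interpolation of the correlation peak along each axis.
#'
#' @param inhale,exhale 3D arrays on the same grid.
#' @param box_roi List with integer voxel index vectors `lo` and `hi`
#'   (inclusive corners of the box in the exhale volume).
#' @param voxel_mm Voxel size triplet in mm.
#' @param search Maximum shift searched per axis, voxels.
#' @return Numeric `c(dx, dy, dz)` translation in mm (inhale position
#'   minus exhale position).
#' @export
roi_translation <- function(inhale, exhale, box_roi,
                            voxel_mm = c(1, 1, 1), search = 8L) {
  stopifnot(identical(dim(inhale), dim(exhale)))
  lo <- as.integer(box_roi$lo)
  hi <- as.integer(box_roi$hi)
  d <- dim(exhale)
  if (any(lo < 1L) || any(hi > d) || any(lo > hi)) {
    stop("box ROI outside the volume", call. = FALSE)
  }
  ref <- exhale[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
  if (stats::sd(ref) == 0) {
    stop("degenerate ROI: no intensity structure to register",
         call. = FALSE)
  }
  ref <- ref - mean(ref)
  refn <- sqrt(sum(ref^2))
  shifts <- -search:search
  # valid shifts keep the moving window inside the inhale volume
  ok_axis <- function(ax) {
    shifts[lo[ax] + shifts >= 1L & hi[ax] + shifts <= d[ax]]
  }
  sx <- ok_axis(1L)
  sy <- ok_axis(2L)
  sz <- ok_axis(3L)
  cc <- array(NA_real_, c(length(sx), length(sy), length(sz)))
  for (ix in seq_along(sx)) for (iy in seq_along(sy)) {
    for (iz in seq_along(sz)) {
      win <- inhale[(lo[1L] + sx[ix]):(hi[1L] + sx[ix]),
                    (lo[2L] + sy[iy]):(hi[2L] + sy[iy]),
                    (lo[3L] + sz[iz]):(hi[3L] + sz[iz])]
      win <- win - mean(win)
      wn <- sqrt(sum(win^2))
      cc[ix, iy, iz] <- if (wn == 0) -Inf else sum(ref * win) / (refn * wn)
    }
  }
  pk <- arrayInd(which.max(cc), dim(cc))
  subpeak <- function(vals, i) {
    if (i <= 1L || i >= length(vals) || any(!is.finite(vals[(i - 1L):(i + 1L)]))) {
      return(0)
    }
    den <- vals[i - 1L] - 2 * vals[i] + vals[i + 1L]
    if (den >= 0) return(0)  # not a proper quadratic maximum
    0.5 * (vals[i - 1L] - vals[i + 1L]) / den
  }
  off <- c(subpeak(cc[, pk[2L], pk[3L]], pk[1L]),
           subpeak(cc[pk[1L], , pk[3L]], pk[2L]),
           subpeak(cc[pk[1L], pk[2L], ], pk[3L]))
  best <- c(sx[pk[1L]], sy[pk[2L]], sz[pk[3L]]) + off
  # the window moved by +s to match, so the inhale content sits at +s
  best * voxel_mm
}
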