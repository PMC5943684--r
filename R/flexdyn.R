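# Ensemble-derived flexibility statistics: trailing-window RMSF, RMSD
# series with plateau check, loop/overall ratios, delta-RMSF and the
# stability/activity region classification.

# Fit mobile frame onto ref (n x 3) using the selected atom rows; returns
# the whole transformed frame.
.fit_frame <- function(frame, ref, sel) {
  sup <- kabsch_superpose(ref[sel, , drop = FALSE],
                          frame[sel, , drop = FALSE])
  sweep(frame %*% sup$rotation, 2, sup$translation, FUN = "+")
}

.window_frames <- function(nf, window) {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  first <- floor(window[1] * nf) + 1L
  last <- round(window[2] * nf)
  if (last - first + 1 < 2) stop2("window selects %d frame(s); need >= 2",
                                  max(0, last - first + 1))
  first:last
}

#' Per-residue RMSF over a trailing frame window
#'
#' Frames in the window are least-squares fitted (Kabsch) on the fit
#' selection to their running mean in two passes, then
#' `RMSF_i = sqrt(mean_t ||r_i(t) - mean_r_i||^2)`.
#'
#' @param ens An `ensemble`.
#' @param window Fraction pair (start, end) of the trajectory; the default
#'   `c(0.7, 1)` analyzes the trailing 30% of frames, mirroring analysis of
#'   the last 30 ns of 100 ns trajectories.
#' @param fit_selection Atom-name filter used for frame fitting (default:
#'   all atoms in the ensemble, typically all C-alpha).
#' @param fit Set FALSE to skip superposition (frames already aligned).
#' @return A `flexibility_profile` data frame: key, resseq, rmsf (Angstrom);
#'   attributes temperature, window, n_frames_used, fit_selection.
#' @export
rmsf_profile <- function(ens, window = c(0.7, 1), fit_selection = NULL,
                         fit = TRUE) {
  idx <- .window_frames(n_frames(ens), window)
  na <- dim(ens$coords)[2]
  sel <- if (is.null(fit_selection)) seq_len(na) else
    which(ens$atom_meta$name %in% fit_selection)
  if (fit && length(sel) < 3) stop2("fit selection has %d atoms; need >= 3",
                                    length(sel))
  frames <- lapply(idx, function(t) ens$coords[t, , ])
  if (fit) {
    ref <- frames[[1]]
    for (pass in 1:2) {
      frames <- lapply(frames, .fit_frame, ref = ref, sel = sel)
      ref <- Reduce(`+`, frames) / length(frames)
    }
  }
  mean_pos <- Reduce(`+`, frames) / length(frames)
  msf <- Reduce(`+`, lapply(frames, function(f) {
    rowSums((f - mean_pos)^2)
  })) / length(frames)
  prof <- data.frame(key = ens$atom_meta$key, resseq = ens$atom_meta$resseq,
                     rmsf = sqrt(msf), stringsAsFactors = FALSE)
  attr(prof, "temperature") <- ens$temperature
  attr(prof, "window") <- window
  attr(prof, "n_frames_used") <- length(idx)
  attr(prof, "fit_selection") <- fit_selection %||% "all"
  class(prof) <- c("flexibility_profile", "data.frame")
  prof
}

#' Backbone RMSD series with equilibration plateau check
#'
#' Per-frame RMSD to a reference frame after Kabsch fitting. The series is
#' flagged as plateaued when the absolute slope of a linear fit over the
#' trailing window is below `tol` Angstrom per frame index.
#'
#' @param ens An `ensemble`.
#' @param reference Reference frame index (default 1).
#' @param fit_selection Atom-name filter for fitting (default all atoms).
#' @param trailing Fraction of frames used for the plateau fit (default 0.3).
#' @param tol Plateau slope tolerance, Angstrom per frame (default 1e-3).
#' @return An `rmsd_series`: list with `rmsd` (per frame), `plateau`
#'   (logical), `slope`.
#' @export
rmsd_series <- function(ens, reference = 1L, fit_selection = NULL,
                        trailing = 0.3, tol = 1e-3) {
  nf <- n_frames(ens)
  if (nf < 2) stop2("need >= 2 frames")
  na <- dim(ens$coords)[2]
  sel <- if (is.null(fit_selection)) seq_len(na) else
    which(ens$atom_meta$name %in% fit_selection)
  ref <- ens$coords[reference, , ]
  rmsd <- vapply(seq_len(nf), function(t) {
    f <- .fit_frame(ens$coords[t, , ], ref, sel)
    sqrt(mean(rowSums((f - ref)^2)))
  }, numeric(1))
  tail_idx <- .window_frames(nf, c(1 - trailing, 1))
  slope <- if (stats::sd(rmsd[tail_idx]) == 0) 0 else
    unname(stats::coef(stats::lm(rmsd[tail_idx] ~ tail_idx))[2])
  structure(list(rmsd = rmsd, plateau = abs(slope) < tol, slope = slope),
            class = "rmsd_series")
}

#' Overall-to-loop RMSF ratio
#'
#' Ratio of the mean RMSF over all residues to the mean RMSF over loop
#' residues; values below 1 quantify how much more flexible loops are than
#' the overall structure.
#'
#' @param profile A `flexibility_profile`.
#' @param loops A `loop_regions` table or a character vector of loop
#'   residue keys.
#' @return List: overall_mean, loop_mean, ratio.
#' @export
flexibility_ratio <- function(profile, loops) {
  keys <- if (is.character(loops)) loops else .expand_loop_keys(profile, loops)
  in_loop <- profile$key %in% keys
  if (!any(in_loop)) stop2("no loop residues in profile")
  overall <- mean(profile$rmsf)
  loop_mean <- mean(profile$rmsf[in_loop])
  list(overall_mean = overall, loop_mean = loop_mean,
       ratio = overall / loop_mean)
}

.expand_loop_keys <- function(profile, loops) {
  keys <- character()
  for (r in seq_len(nrow(loops))) {
    i1 <- match(loops$first_key[r], profile$key)
    i2 <- match(loops$last_key[r], profile$key)
    if (is.na(i1) || is.na(i2)) stop2("loop %s outside profile range",
                                      loops$loop_id[r])
    keys <- c(keys, profile$key[i1:i2])
  }
  keys
}

#' Difference of two RMSF profiles with optional smoothing
#'
#' Elementwise `profile_t - profile_topt`, then a centered moving average
#' of odd width (edges truncated). Window 1 is the exact difference.
#'
#' @param profile_t RMSF profile at the comparison temperature.
#' @param profile_topt RMSF profile at the optimal temperature.
#' @param smoothing_window Odd integer (default 3).
#' @return A `delta_flexibility` data frame: key, resseq, delta (Angstrom);
#'   attributes t_cmp, t_ref, smoothing_window.
#' @export
delta_rmsf <- function(profile_t, profile_topt, smoothing_window = 3L) {
  if (smoothing_window %% 2 != 1 || smoothing_window < 1) {
    stop2("smoothing_window must be odd and positive")
  }
  if (!identical(profile_t$key, profile_topt$key)) {
    stop2("profiles cover different residues")
  }
  delta <- profile_t$rmsf - profile_topt$rmsf
  if (smoothing_window > 1) {
    half <- (smoothing_window - 1) / 2
    n <- length(delta)
    delta <- vapply(seq_len(n), function(i) {
      mean(delta[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  }
  out <- data.frame(key = profile_t$key, resseq = profile_t$resseq,
                    delta = delta, stringsAsFactors = FALSE)
  attr(out, "t_cmp") <- attr(profile_t, "temperature")
  attr(out, "t_ref") <- attr(profile_topt, "temperature")
  attr(out, "smoothing_window") <- smoothing_window
  class(out) <- c("delta_flexibility", "data.frame")
  out
}

#' Classify residue runs into stability- and activity-associated regions
#'
#' Decision rule per residue, with `d_high` the RMSF change from T_opt to
#' T_high and `d_low` the change from T_opt to T_low: a residue votes
#' *stability* when `d_high > +theta` and `d_low < -theta` (more mobile
#' when heated, rigidified when cooled); it votes *activity* when
#' `d_low > +theta` (mobility increases on cooling); otherwise neutral.
#' Votes are merged into maximal runs; runs shorter than `min_run` become
#' neutral.
#'
#' @param d_high,d_low `delta_flexibility` objects sharing residues.
#' @param theta Vote threshold, Angstrom (default 0.2).
#' @param min_run Minimum run length in residues (default 3).
#' @return A `region_classification`: `labels` (per-residue), `segments`
#'   (data frame: first_key, last_key, first, last, label,
#'   mean_delta_high, mean_delta_low).
#' @export
classify_thermal_regions <- function(d_high, d_low, theta = 0.2,
                                     min_run = 3L) {
  if (theta <= 0) stop2("theta must be positive")
  if (!identical(d_high$key, d_low$key)) {
    stop2("delta profiles cover different residues")
  }
  lab <- ifelse(d_high$delta > theta & d_low$delta < -theta, "stability",
                ifelse(d_low$delta > theta, "activity", "neutral"))
  n <- length(lab)
  run_id <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (lab[idx[1]] != "neutral" && length(idx) < min_run) {
      lab[idx] <- "neutral"
    }
  }
  run_id <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  segs <- do.call(rbind, lapply(unique(run_id), function(r) {
    idx <- which(run_id == r)
    data.frame(first_key = d_high$key[idx[1]],
               last_key = d_high$key[idx[length(idx)]],
               first = idx[1], last = idx[length(idx)],
               label = lab[idx[1]],
               mean_delta_high = mean(d_high$delta[idx]),
               mean_delta_low = mean(d_low$delta[idx]),
               stringsAsFactors = FALSE)
  }))
  structure(list(labels = stats::setNames(lab, d_high$key), segments = segs,
                 theta = theta, min_run = min_run),
            class = "region_classification")
}

#' @export
print.region_classification <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("stability", "activity",
                                           "neutral")))
  cat(sprintf("region_classification (theta %.2f A, min_run %d): %d stability, %d activity, %d neutral residues\n",
              x$theta, x$min_run, tab["stability"], tab["activity"],
              tab["neutral"]))
  seg <- x$segments[x$segments$label != "neutral", , drop = FALSE]
  for (r in seq_len(nrow(seg))) {
    cat(sprintf("  %s  %s..%s (dHigh %+.2f, dLow %+.2f)\n", seg$label[r],
                seg$first_key[r], seg$last_key[r], seg$mean_delta_high[r],
                seg$mean_delta_low[r]))
  }
  invisible(x)
}
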