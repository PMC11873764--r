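#' Motion quality-control parameters
#'
#' Thresholds and windows of the volume-censoring ("scrubbing") procedure:
#' a volume is flagged when its framewise displacement exceeds
#' `fd_threshold` (strictly) or its DVARS exceeds `dvars_threshold`
#' (strictly); for every flagged volume, `n_before` preceding and `n_after`
#' following volumes are removed as well; a session is retained only when
#' at least `min_retained_fraction` of its volumes survive (inclusive
#' comparison).
#'
#' @param fd_threshold Framewise-displacement cut, mm. Default 0.5.
#' @param dvars_threshold DVARS cut, percent of mean signal. Default 3.
#' @param n_before,n_after Neighbor volumes removed around each flagged
#'   volume. Defaults 1 and 2.
#' @param min_retained_fraction Minimum fraction of volumes that must
#'   remain for inclusion. Default 0.5.
#' @param head_radius Head radius in mm used to convert rotations to arc
#'   displacement. Default 50.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(fd_threshold = 0.5, dvars_threshold = 3,
                      n_before = 1L, n_after = 2L,
                      min_retained_fraction = 0.5, head_radius = 50) {
  stopifnot(fd_threshold > 0, dvars_threshold > 0,
            n_before >= 0, n_after >= 0,
            min_retained_fraction > 0, min_retained_fraction <= 1,
            head_radius > 0)
  structure(list(fd_threshold = fd_threshold,
                 dvars_threshold = dvars_threshold,
                 n_before = as.integer(n_before),
                 n_after = as.integer(n_after),
                 min_retained_fraction = min_retained_fraction,
                 head_radius = head_radius),
            class = "qc_params")
}

#' Framewise displacement from rigid-body realignment parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius` times the sum of absolute backward
#' differences of the three rotations (radians), i.e. rotations are
#' converted to arc length on a sphere of radius `head_radius`. The first
#' volume has no predecessor and is assigned FD = 0.
#'
#' @param motion Matrix or data frame with 6 columns: 3 translations (mm)
#'   then 3 rotations (radians), one row per volume.
#' @param head_radius Sphere radius in mm. Default 50.
#' @return Numeric vector of per-volume FD (mm).
#' @export
compute_fd <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("motion trace must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  }
  if (nrow(motion) < 2) stop("motion trace needs at least 2 volumes",
                             call. = FALSE)
  bad <- which(!stats::complete.cases(motion) |
                 rowSums(!is.finite(motion)) > 0)
  if (length(bad) > 0) {
    stop("non-finite motion parameters at volume(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS of network time courses, as percent signal change
#'
#' Root-mean-square (over networks) of the backward temporal difference of
#' the signals, expressed as a percentage of the grand mean of the signal
#' matrix. The first volume is assigned 0. This is a network-level
#' approximation of the voxel-level DVARS quantity: it indexes abrupt
#' global intensity change relative to the mean signal level, so the input
#' must be un-demeaned (raw-scale) time courses.
#'
#' @param tc Time-course matrix (volumes x networks), raw scale.
#' @return Numeric vector of per-volume DVARS (% of mean signal).
#' @export
compute_dvars <- function(tc) {
  tc <- as.matrix(tc)
  if (nrow(tc) < 2) stop("need at least 2 volumes", call. = FALSE)
  gm <- mean(tc)
  scale_ref <- max(stats::sd(as.vector(tc)), 1)
  if (abs(gm) < 1e-8 * scale_ref) {
    stop("grand mean of the signal is ~0; DVARS as percent signal change ",
         "requires un-demeaned time courses", call. = FALSE)
  }
  d <- diff(tc)
  c(0, 100 * sqrt(rowMeans(d^2)) / gm)
}

#' Build the keep-mask from FD and DVARS traces
#'
#' A volume is flagged when `fd > fd_threshold` or
#' `dvars > dvars_threshold` (both strict). The removed set is the union,
#' over flagged volumes, of the volume itself with its `n_before`
#' predecessors and `n_after` successors, clipped to the valid range;
#' overlapping windows are unioned. The keep-mask is the complement.
#'
#' @param fd Per-volume framewise displacement (mm).
#' @param dvars Per-volume DVARS (%).
#' @param params A [qc_params()].
#' @return Logical vector: `TRUE` where the volume is kept.
#' @export
build_scrub_mask <- function(fd, dvars, params = qc_params()) {
  if (length(fd) != length(dvars)) {
    stop("fd and dvars must have the same length", call. = FALSE)
  }
  n <- length(fd)
  flagged <- which(fd > params$fd_threshold | dvars > params$dvars_threshold)
  removed <- unique(unlist(lapply(flagged, function(t) {
    max(1L, t - params$n_before):min(n, t + params$n_after)
  })))
  keep <- rep(TRUE, n)
  keep[removed] <- FALSE
  keep
}

#' Censor a time-course matrix with a keep-mask
#'
#' @param tc Time-course matrix (volumes x networks).
#' @param keep_mask Logical vector of length `nrow(tc)`.
#' @return The kept rows, in original temporal order, with attribute
#'   `retained_fraction`.
#' @export
apply_scrub <- function(tc, keep_mask) {
  tc <- as.matrix(tc)
  if (length(keep_mask) != nrow(tc)) {
    stop("keep_mask length (", length(keep_mask),
         ") does not match the number of volumes (", nrow(tc), ")",
         call. = FALSE)
  }
  if (sum(keep_mask) < 2) {
    stop("fewer than 2 volumes retained; downstream statistics undefined",
         call. = FALSE)
  }
  out <- tc[keep_mask, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep_mask)
  out
}

#' Retention-based inclusion rule
#'
#' A session is included when at least `min_retained_fraction` of its
#' volumes survive scrubbing (inclusive at the boundary: retaining exactly
#' the minimum fraction is sufficient).
#'
#' @param retained_fraction Fraction of volumes kept, in `[0, 1]`.
#' @param params A [qc_params()].
#' @return `TRUE` (included) or `FALSE` (excluded).
#' @export
check_inclusion <- function(retained_fraction, params = qc_params()) {
  stopifnot(retained_fraction >= 0, retained_fraction <= 1)
  retained_fraction >= params$min_retained_fraction
}

#' Scrub one session: FD + DVARS flagging, neighbor removal, inclusion
#'
#' Convenience wrapper running [compute_fd()], [compute_dvars()],
#' [build_scrub_mask()] and [apply_scrub()] on a paired time-course /
#' motion-trace session.
#'
#' @param tc Time-course matrix (volumes x networks), raw scale.
#' @param motion Motion-parameter matrix (volumes x 6).
#' @param params A [qc_params()].
#' @return A list with `timecourses` (censored matrix), `qc` (a tibble of
#'   class `qc_trace` with columns `volume`, `fd`, `dvars_pct`, `keep`),
#'   `retained_fraction` and `included`.
#' @export
scrub_session <- function(tc, motion, params = qc_params()) {
  tc <- as.matrix(tc)
  if (nrow(as.matrix(motion)) != nrow(tc)) {
    stop("motion trace length does not match the time-course length",
         call. = FALSE)
  }
  fd <- compute_fd(motion, params$head_radius)
  dvars <- compute_dvars(tc)
  keep <- build_scrub_mask(fd, dvars, params)
  qc <- tibble::tibble(volume = seq_len(nrow(tc)), fd = fd,
                       dvars_pct = dvars, keep = keep)
  class(qc) <- c("qc_trace", class(qc))
  list(timecourses = apply_scrub(tc, keep), qc = qc,
       retained_fraction = mean(keep),
       included = check_inclusion(mean(keep), params))
}

#' Scrub every session of a cohort
#'
#' Applies [scrub_session()] to each row of a manifest and reports, per
#' subject-session, the retained fraction and inclusion decision. A
#' subject whose *either* session fails the retention rule loses its
#' longitudinal pair: `pair_complete` marks subjects usable in the paired
#' analyses.
#'
#' @param manifest Data frame with columns `subject_id`, `group`,
#'   `session`, `timecourse_path`, `motion_path` (see [simulate_cohort()]
#'   or [read_manifest()]).
#' @param params A [qc_params()].
#' @param mask_dir Optional directory; when given, a one-0/1-per-line mask
#'   file is written per session.
#' @return A tibble: `subject_id`, `group`, `session`, `n_volumes`,
#'   `n_kept`, `retained_fraction`, `included`, `pair_complete`.
#' @export
qc_cohort <- function(manifest, params = qc_params(), mask_dir = NULL) {
  if (!is.null(mask_dir)) {
    dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  }
  report <- purrr::pmap(
    manifest[, c("subject_id", "group", "session",
                 "timecourse_path", "motion_path")],
    function(subject_id, group, session, timecourse_path, motion_path) {
      tc <- read_timecourses(timecourse_path)
      motion <- read_motion(motion_path)
      s <- scrub_session(tc, motion, params)
      if (!is.null(mask_dir)) {
        writeLines(as.character(as.integer(s$qc$keep)),
                   file.path(mask_dir, sprintf("mask_%s_%s.txt",
                                               subject_id, session)))
      }
      tibble::tibble(subject_id = subject_id, group = group,
                     session = session, n_volumes = nrow(s$qc),
                     n_kept = sum(s$qc$keep),
                     retained_fraction = s$retained_fraction,
                     included = s$included)
    })
  report <- dplyr::bind_rows(report)
  dplyr::mutate(
    dplyr::group_by(report, .data$subject_id),
    pair_complete = all(.data$included) & dplyr::n() == 2L) |>
    dplyr::ungroup()
}
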