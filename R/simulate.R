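#' Simulation configuration for a longitudinal two-group cohort
#'
#' Defines the data-generating conditions for a synthetic resting-state
#' cohort: two groups (music-exposed and control preterm infants), two
#' sessions (33 and 40 weeks gestational age), `n_networks` BOLD network
#' time courses of `n_volumes` volumes per subject-session. Signals are
#' stationary Gaussian AR(1) processes with instantaneous cross-network
#' correlation given by `baseline_coupling` at session 1; at session 2 the
#' sparse `maturation_delta` increments are added in both groups
#' (maturation) and `group_delta` in the music group only (intervention
#' effect). Every resulting matrix must remain a valid correlation matrix.
#'
#' @param n_music,n_control Subjects per group. Defaults 24 and 19.
#' @param n_networks Number of networks (nodes). Default 11.
#' @param n_volumes Volumes (time points) per session. Default 590.
#' @param tr_seconds Repetition time in seconds. Default 0.7.
#' @param baseline_coupling Symmetric positive semi-definite correlation
#'   matrix (`n_networks` square, unit diagonal) of session-1 inter-network
#'   coupling. Default: compound symmetry at 0.2.
#' @param maturation_delta Data frame of edges (`region_1`, `region_2`,
#'   integer node indices, and `delta`) added to the coupling of *both*
#'   groups at session 2. See [edge_deltas()]. Default: 12 edges at +0.15.
#' @param group_delta As `maturation_delta`, but added in the music group
#'   only at session 2. Default: +0.15 on edge (3, 4).
#' @param ar1_coefficient Temporal autocorrelation of each network signal,
#'   in `[0, 1)`. Default 0.4 (plausible for BOLD sampled at 0.7 s).
#' @param spike_rate Expected fraction of volumes carrying a motion spike.
#'   Default 0.03.
#' @param spike_magnitude Additive global signal offset (signal units) at a
#'   spike volume, decaying linearly over the next two volumes. Default 60
#'   (6% of the mean signal, above the 3% DVARS cut; the 2%-of-mean return
#'   steps stay below it).
#' @param fd_spike_mm Translation jump at a spike, in mm. Default 0.8.
#' @param signal_mean,signal_sd Mean level and fluctuation SD of the
#'   generated BOLD-like signal. Defaults 1000 and 10 (~1% fluctuation).
#' @param network_labels Character vector of node names; default
#'   `"N01"..."N11"`.
#' @param seed Master integer seed; all per-subject seeds derive from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [simulate_session()]
#' @export
sim_config <- function(n_music = 24L,
                       n_control = 19L,
                       n_networks = 11L,
                       n_volumes = 590L,
                       tr_seconds = 0.7,
                       baseline_coupling = NULL,
                       maturation_delta = NULL,
                       group_delta = NULL,
                       ar1_coefficient = 0.4,
                       spike_rate = 0.03,
                       spike_magnitude = 60,
                       fd_spike_mm = 0.8,
                       signal_mean = 1000,
                       signal_sd = 10,
                       network_labels = NULL,
                       seed = 1L) {
  stopifnot(n_music >= 1, n_control >= 1, n_networks >= 2, n_volumes >= 2,
            tr_seconds > 0, ar1_coefficient >= 0, ar1_coefficient < 1,
            signal_sd > 0)
  if (is.null(network_labels)) {
    network_labels <- sprintf("N%02d", seq_len(n_networks))
  }
  stopifnot(length(network_labels) == n_networks,
            !anyDuplicated(network_labels))
  if (is.null(baseline_coupling)) {
    baseline_coupling <- matrix(0.2, n_networks, n_networks)
    diag(baseline_coupling) <- 1
  }
  if (is.null(maturation_delta)) {
    maturation_delta <- default_maturation_edges(n_networks)
  }
  if (is.null(group_delta)) {
    group_delta <- if (n_networks >= 4) edge_deltas(3L, 4L, 0.15)
    else edge_deltas(1L, 2L, 0.15)
  }

  cfg <- structure(
    list(n_music = as.integer(n_music), n_control = as.integer(n_control),
         n_networks = as.integer(n_networks),
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         baseline_coupling = baseline_coupling,
         maturation_delta = as_edge_deltas(maturation_delta, n_networks),
         group_delta = as_edge_deltas(group_delta, n_networks),
         ar1_coefficient = ar1_coefficient, spike_rate = spike_rate,
         spike_magnitude = spike_magnitude, fd_spike_mm = fd_spike_mm,
         signal_mean = signal_mean, signal_sd = signal_sd,
         network_labels = network_labels, seed = as.integer(seed)),
    class = "sim_config")

  validate_correlation_matrix(baseline_coupling, "baseline_coupling")
  for (g in c("music", "control")) {
    validate_correlation_matrix(target_coupling(cfg, g, "t40"),
                                sprintf("session-2 coupling (%s group)", g))
  }
  cfg
}

#' Sparse edge-increment table
#'
#' @param region_1,region_2 Integer node indices (1-based) of each edge.
#' @param delta Correlation increment applied to each edge.
#' @return A tibble with columns `region_1`, `region_2`, `delta`.
#' @export
edge_deltas <- function(region_1 = integer(), region_2 = integer(),
                        delta = numeric()) {
  tibble::tibble(region_1 = as.integer(region_1),
                 region_2 = as.integer(region_2),
                 delta = as.numeric(delta))
}

as_edge_deltas <- function(x, n_networks) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("region_1", "region_2", "delta") %in% names(x)))
  if (nrow(x) > 0) {
    stopifnot(all(x$region_1 >= 1), all(x$region_2 >= 1),
              all(x$region_1 <= n_networks), all(x$region_2 <= n_networks),
              all(x$region_1 != x$region_2))
  }
  x
}

# A hub-like maturating circuitry: node 3 plays the thalamic-hub role,
# nodes 1, 4, 9 secondary hubs; 12 edges in all (at the default 11
# networks), mirroring the size of the circuitry the pipeline is designed
# to detect. For smaller node sets the edges referencing absent nodes are
# dropped.
default_maturation_edges <- function(n_networks = 11L) {
  e <- rbind(c(3, 4), c(3, 9), c(3, 8), c(3, 5), c(3, 1), c(1, 6),
             c(1, 2), c(1, 11), c(4, 6), c(4, 2), c(9, 8), c(9, 7))
  e <- e[e[, 1] <= n_networks & e[, 2] <= n_networks, , drop = FALSE]
  if (nrow(e) == 0) e <- cbind(1L, 2L)
  edge_deltas(e[, 1], e[, 2], rep(0.15, nrow(e)))
}

validate_correlation_matrix <- function(R, what) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(R))) stop(what, " has non-finite entries", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-10) {
    stop(what, " is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-10) {
    stop(what, " must have a unit diagonal", call. = FALSE)
  }
  if (max(abs(R)) > 1 + 1e-10) {
    stop(what, " has entries outside [-1, 1]", call. = FALSE)
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop(what, " is not positive semi-definite (smallest eigenvalue ",
         format(ev), ")", call. = FALSE)
  }
  invisible(R)
}

apply_edge_deltas <- function(R, deltas) {
  for (k in seq_len(nrow(deltas))) {
    i <- deltas$region_1[k]; j <- deltas$region_2[k]
    R[i, j] <- R[i, j] + deltas$delta[k]
    R[j, i] <- R[i, j]
  }
  R
}

#' Ground-truth coupling matrix for one group and session
#'
#' Session `"t33"` is the baseline coupling; session `"t40"` adds the
#' maturation increments (both groups) and, for the music group, the
#' group-specific increments.
#'
#' @param config A [sim_config()].
#' @param group `"music"` or `"control"`.
#' @param session `"t33"` or `"t40"`.
#' @return A correlation matrix with the configured network labels.
#' @export
target_coupling <- function(config, group, session) {
  group <- match.arg(group, c("music", "control"))
  session <- match.arg(session, c("t33", "t40"))
  R <- config$baseline_coupling
  if (session == "t40") {
    R <- apply_edge_deltas(R, config$maturation_delta)
    if (group == "music") R <- apply_edge_deltas(R, config$group_delta)
  }
  dimnames(R) <- list(config$network_labels, config$network_labels)
  R
}

# Factor F with R = F F' via eigendecomposition; tolerates singular PSD
# targets (e.g. perfectly coupled duplicate channels).
psd_factor <- function(R, what = "coupling matrix") {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(what, " is not positive semi-definite (smallest eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = ncol(R))
}

# Stationary multivariate AR(1): x_t = phi x_{t-1} + sqrt(1-phi^2) z_t with
# z_t ~ MVN(0, R) and x_1 drawn from the stationary law, so the process has
# unit marginal variance and cross-correlation exactly R at every lag 0.
rmvn_ar1 <- function(n_volumes, R, phi) {
  fac <- psd_factor(R)
  n <- ncol(R)
  Z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n) %*% t(fac)
  X <- Z
  a <- sqrt(1 - phi^2)
  for (t in seq_len(n_volumes)[-1]) {
    X[t, ] <- phi * X[t - 1, ] + a * Z[t, ]
  }
  X
}

#' Simulate one subject-session of network time courses
#'
#' Draws a `n_volumes` x `n_networks` matrix whose columns are stationary
#' Gaussian AR(1) signals with cross-network correlation equal to the
#' ground-truth coupling for `(group, session)`, then scales them onto a
#' BOLD-like level (`signal_mean` + `signal_sd` x standardized process).
#'
#' @inheritParams target_coupling
#' @param subject_seed Integer seed for this draw; the same seed reproduces
#'   the same matrix exactly.
#' @return A numeric matrix with one column per network (named).
#' @export
simulate_session <- function(config, group, session, subject_seed) {
  R <- target_coupling(config, group, session)
  set.seed(as.integer(subject_seed))
  X <- rmvn_ar1(config$n_volumes, R, config$ar1_coefficient)
  tc <- config$signal_mean + config$signal_sd * X
  colnames(tc) <- config$network_labels
  tc
}

#' Inject motion-spike artifacts into a session
#'
#' Volumes are independently selected as spikes with probability
#' `spike_rate` (volume 1 excluded: its framewise displacement and DVARS
#' are defined as 0, so a spike there would be undetectable by
#' construction). Each spike adds to all network signals a global offset of
#' `spike_magnitude` (random sign) at the spike volume that decays linearly
#' over the two following volumes (2/3, then 1/3, then 0): the onset jump
#' trips the DVARS criterion at the spike volume only, the return steps
#' stay below it, and the whole artifact lies inside the one-before /
#' two-after censoring window, so scrubbed data carry no artifact residue.
#' The motion trace receives a persistent `fd_spike_mm` translation jump
#' (heads tend to stay displaced), giving a single FD excursion. Away from
#' spikes the synthetic motion is a slow random walk with FD below 0.2 mm.
#'
#' @param tc Time-course matrix (volumes x networks).
#' @param spike_rate Spike probability per volume, in `[0, 0.5)`.
#' @param spike_magnitude Signal offset per spike (signal units).
#' @param seed Integer seed.
#' @param fd_spike_mm Translation jump per spike (mm). Default 0.8.
#' @return A list with elements `timecourses` (contaminated matrix),
#'   `motion` (volumes x 6 matrix: 3 translations in mm, 3 rotations in
#'   radians) and `spike_volumes` (integer indices).
#' @export
inject_motion_artifacts <- function(tc, spike_rate, spike_magnitude,
                                    seed, fd_spike_mm = 0.8) {
  tc <- as.matrix(tc)
  if (!is.numeric(spike_rate) || spike_rate < 0 || spike_rate >= 0.5) {
    stop("spike_rate must lie in [0, 0.5)", call. = FALSE)
  }
  n <- nrow(tc)
  set.seed(as.integer(seed))

  # baseline motion: slow random walk; worst-case FD
  # 3*0.015 + 50*3*0.0003 = 0.09 mm, safely below 0.2 mm
  d_trans <- matrix(stats::runif(n * 3, -0.015, 0.015), n, 3)
  d_rot <- matrix(stats::runif(n * 3, -3e-4, 3e-4), n, 3)
  d_trans[1, ] <- 0
  d_rot[1, ] <- 0
  motion <- cbind(apply(d_trans, 2, cumsum), apply(d_rot, 2, cumsum))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

  spikes <- which(stats::runif(n) < spike_rate)
  spikes <- setdiff(spikes, 1L)
  if (length(spikes) > 0) {
    sign_sig <- sample(c(-1, 1), length(spikes), replace = TRUE)
    sign_fd <- sample(c(-1, 1), length(spikes), replace = TRUE)
    offset <- numeric(n)
    profile <- c(1, 2 / 3, 1 / 3)
    for (k in seq_along(spikes)) {
      idx <- spikes[k]:min(n, spikes[k] + 2L)
      offset[idx] <- offset[idx] +
        spike_magnitude * sign_sig[k] * profile[seq_along(idx)]
    }
    tc <- tc + offset
    jump <- numeric(n)
    jump[spikes] <- fd_spike_mm * sign_fd
    motion[, 1] <- motion[, 1] + cumsum(jump)
  }
  list(timecourses = tc, motion = motion,
       spike_volumes = as.integer(spikes))
}

derive_seed <- function(master, counter) {
  as.integer((as.double(master) + 104729 * counter) %% 2147483647)
}

#' Simulate a full longitudinal cohort and write its files
#'
#' Generates every subject-session (two sessions per subject), injects
#' motion artifacts, and writes one time-course TSV and one SPM-style
#' `rp_*.txt` motion file per subject-session plus a cohort manifest TSV.
#' Distinct subject-sessions use distinct seeds derived from the master
#' seed by a counter scheme, so output is byte-reproducible for a given
#' `(config, seed)` and independent of cohort size ordering.
#'
#' @param config A [sim_config()].
#' @param output_dir Directory to write into (created if needed).
#' @return The manifest as a tibble of class `cohort_manifest`: columns
#'   `subject_id`, `group`, `session`, `timecourse_path`, `motion_path`,
#'   plus a `true_coupling` list-column retained for recovery tests.
#' @export
simulate_cohort <- function(config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  subjects <- tibble::tibble(
    subject_id = c(sprintf("music%02d", seq_len(config$n_music)),
                   sprintf("ctrl%02d", seq_len(config$n_control))),
    group = rep(c("music", "control"), c(config$n_music, config$n_control)))

  records <- tidyr::expand_grid(subjects, session = c("t33", "t40"))
  records$counter <- seq_len(nrow(records))

  rows <- purrr::pmap(records, function(subject_id, group, session, counter) {
    tc <- simulate_session(config, group, session,
                           derive_seed(config$seed, 2L * counter))
    art <- inject_motion_artifacts(tc, config$spike_rate,
                                   config$spike_magnitude,
                                   derive_seed(config$seed, 2L * counter + 1L),
                                   fd_spike_mm = config$fd_spike_mm)
    tc_path <- file.path(output_dir,
                         sprintf("%s_%s_timecourses.tsv", subject_id, session))
    mo_path <- file.path(output_dir,
                         sprintf("rp_%s_%s.txt", subject_id, session))
    write_timecourses(art$timecourses, tc_path)
    write_motion(art$motion, mo_path)
    tibble::tibble(subject_id = subject_id, group = group, session = session,
                   timecourse_path = tc_path, motion_path = mo_path,
                   true_coupling = list(target_coupling(config, group, session)))
  })
  manifest <- dplyr::bind_rows(rows)
  on_disk <- manifest[, c("subject_id", "group", "session",
                          "timecourse_path", "motion_path")]
  on_disk$timecourse_path <- basename(on_disk$timecourse_path)
  on_disk$motion_path <- basename(on_disk$motion_path)
  readr::write_tsv(on_disk, file.path(output_dir, "manifest.tsv"))
  class(manifest) <- c("cohort_manifest", class(manifest))
  manifest
}
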