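# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive per-element loops and no
# package internals.

# accordance/discordance by an explicit per-timepoint loop
oracle_accordance <- function(x, y, u, variant = "magnitude") {
  gate <- function(z) {
    xp <- numeric(length(z)); xm <- numeric(length(z))
    for (t in seq_along(z)) {
      if (z[t] >= u) xp[t] <- if (variant == "binary") 1 else z[t]
      if (z[t] <= -u) xm[t] <- if (variant == "binary") -1 else z[t]
    }
    list(xp = xp, xm = xm, sigma = sqrt(sum(xp^2) + sum(xm^2)))
  }
  gx <- gate(x); gy <- gate(y)
  acc <- 0; dis <- 0
  for (t in seq_along(x)) {
    acc <- acc + gx$xp[t] * gy$xp[t] + gx$xm[t] * gy$xm[t]
    dis <- dis - gx$xp[t] * gy$xm[t] - gx$xm[t] * gy$xp[t]
  }
  list(accordance = acc / (gx$sigma * gy$sigma),
       discordance = dis / (gx$sigma * gy$sigma))
}

# BH step-up by direct evaluation of min_{j>=i} m p_(j)/j
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k)) adj[i] <- min(1, min(m * ps[i:k] / (i:k)))
  out <- numeric(k)
  out[o] <- adj
  out
}

# removed-volume set by explicit union over flagged volumes
oracle_removed <- function(flagged, n, n_before = 1, n_after = 2) {
  removed <- integer(0)
  for (t in flagged) {
    removed <- union(removed, max(1, t - n_before):min(n, t + n_after))
  }
  sort(removed)
}

# standardize a vector with sample sd, independent of znormalize()
oracle_standardize <- function(x) (x - mean(x)) / stats::sd(x)

# long edge table for a whole simulated cohort, computed in memory
# (simulate -> contaminate -> scrub -> connectome), no files involved
cohort_edges_in_memory <- function(cfg, rep_seed,
                                   qc = qc_params(),
                                   acc = accordance_params()) {
  groups <- rep(c("music", "control"), c(cfg$n_music, cfg$n_control))
  ids <- sprintf("s%02d", seq_along(groups))
  rows <- vector("list", 2L * length(ids))
  k <- 0
  for (i in seq_along(ids)) {
    for (ses in c("t33", "t40")) {
      k <- k + 1
      tc <- simulate_session(cfg, groups[i], ses, rep_seed + 2 * k)
      art <- inject_motion_artifacts(tc, cfg$spike_rate,
                                     cfg$spike_magnitude,
                                     rep_seed + 2 * k + 1,
                                     cfg$fd_spike_mm)
      s <- scrub_session(art$timecourses, art$motion, qc)
      cn <- build_connectome(s$timecourses, acc)
      e <- connectome_edges(cn)
      e$subject_id <- ids[i]
      e$group <- groups[i]
      e$session <- ses
      rows[[k]] <- e
    }
  }
  dplyr::bind_rows(rows)
}

# small null configuration (no maturation, no group effect) used for
# calibration checks where only the distribution of the statistic matters
null_sim_config <- function(seed = 1L, n_per_group = 6L, n_networks = 6L,
                            n_volumes = 80L) {
  sim_config(n_music = n_per_group, n_control = n_per_group,
             n_networks = n_networks, n_volumes = n_volumes,
             maturation_delta = edge_deltas(),
             group_delta = edge_deltas(),
             spike_rate = 0, seed = seed)
}
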