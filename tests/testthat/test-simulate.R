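test_that("configuration validation rejects invalid coupling structures", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(sim_config(n_networks = 3, baseline_coupling = bad,
                          maturation_delta = edge_deltas(),
                          group_delta = edge_deltas()),
               "positive semi-definite.*eigenvalue")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(sim_config(n_networks = 3, baseline_coupling = asym,
                          maturation_delta = edge_deltas(),
                          group_delta = edge_deltas()),
               "symmetric")
  # valid baseline pushed past 1 by a session-2 increment
  expect_error(sim_config(n_networks = 3,
                          baseline_coupling = {
                            R <- matrix(0.5, 3, 3); diag(R) <- 1; R
                          },
                          maturation_delta = edge_deltas(1, 2, 0.6),
                          group_delta = edge_deltas()),
               "session-2")
  expect_error(sim_config(n_volumes = 1), "n_volumes")
})

test_that("independent channels have near-zero mean cross-correlation", {
  cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 4,
                    n_volumes = 400, baseline_coupling = diag(4),
                    maturation_delta = edge_deltas(),
                    group_delta = edge_deltas(), seed = 3)
  tc <- simulate_session(cfg, "control", "t33", 11)
  cc <- cor(tc)
  off <- cc[upper.tri(cc)]
  expect_lt(abs(mean(off)), 3 / sqrt(400))
})

test_that("perfect coupling yields duplicate channels", {
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 2,
                    n_volumes = 100, baseline_coupling = R,
                    maturation_delta = edge_deltas(),
                    group_delta = edge_deltas(), seed = 5)
  tc <- simulate_session(cfg, "music", "t33", 2)
  expect_lt(max(abs(tc[, 1] - tc[, 2])), 1e-8)
})

test_that("empirical correlation recovers the target coupling", {
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 2,
                    n_volumes = 590, baseline_coupling = R,
                    maturation_delta = edge_deltas(),
                    group_delta = edge_deltas(), seed = 1)
  cors <- vapply(seq_len(200), function(s) {
    cor(simulate_session(cfg, "control", "t33", s))[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.6), 0.02)
})

test_that("sampling error of the coupling estimate shrinks like sqrt(T)", {
  R <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  err_at <- function(T) {
    cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 2,
                      n_volumes = T, baseline_coupling = R,
                      maturation_delta = edge_deltas(),
                      group_delta = edge_deltas(), seed = 1)
    mean(vapply(seq_len(60), function(s) {
      abs(cor(simulate_session(cfg, "control", "t33", 1000 + s))[1, 2] - 0.4)
    }, numeric(1)))
  }
  e200 <- err_at(200)
  e2000 <- err_at(2000)
  expect_lt(e2000, e200 / 2)
})

test_that("cohort simulation writes a complete, reproducible manifest", {
  cfg <- sim_config(n_music = 2, n_control = 2, n_networks = 3,
                    n_volumes = 40, baseline_coupling = diag(3),
                    maturation_delta = edge_deltas(),
                    group_delta = edge_deltas(1, 2, 0.2), seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_cohort(cfg, d1)
  m2 <- simulate_cohort(cfg, d2)

  expect_equal(nrow(m1), 8)  # 4 subjects x 2 sessions
  expect_equal(sort(table(m1$subject_id)), sort(rep(2L, 4)),
               ignore_attr = TRUE)

  # byte-identical outputs under the same config + seed
  for (f in sort(basename(list.files(d1)))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  # ground-truth bookkeeping: group effect present in the manifest exactly
  tm <- m1$true_coupling[[which(m1$group == "music" & m1$session == "t40")[1]]]
  tcn <- m1$true_coupling[[which(m1$group == "control" & m1$session == "t40")[1]]]
  expect_equal(tm[1, 2] - tcn[1, 2], 0.2)

  # distinct subjects get distinct draws
  tc_a <- read_timecourses(m1$timecourse_path[1])
  tc_b <- read_timecourses(m1$timecourse_path[3])
  expect_gt(max(abs(tc_a - tc_b)), 1e-6)
})

test_that("spike injection matches its binomial expectation and flags", {
  cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 2,
                    n_volumes = 590, baseline_coupling = diag(2),
                    maturation_delta = edge_deltas(),
                    group_delta = edge_deltas(), seed = 1)
  tc <- simulate_session(cfg, "control", "t33", 4)
  counts <- vapply(seq_len(100), function(s) {
    length(inject_motion_artifacts(tc, 0.05, 60, s)$spike_volumes)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.05 * 589), 3)

  # FD exceeds 0.5 mm exactly at spikes and stays below 0.2 mm elsewhere
  art <- inject_motion_artifacts(tc, 0.05, 60, 17)
  fd <- compute_fd(art$motion)
  expect_true(all(fd[art$spike_volumes] > 0.5))
  expect_true(all(fd[-art$spike_volumes] < 0.2))

  # spike_rate = 0 is a no-op on the signal
  clean <- inject_motion_artifacts(tc, 0, 60, 3)
  expect_identical(clean$timecourses, tc)
  expect_true(all(compute_fd(clean$motion) < 0.2))

  expect_error(inject_motion_artifacts(tc, 0.7, 60, 1), "spike_rate")
})

test_that("accordance increases monotonically with generating coupling", {
  rhos <- seq(0, 0.9, by = 0.3)
  acc <- vapply(rhos, function(rho) {
    R <- matrix(c(1, rho, rho, 1), 2, 2)
    cfg <- sim_config(n_music = 1, n_control = 1, n_networks = 2,
                      n_volumes = 20000, baseline_coupling = R,
                      maturation_delta = edge_deltas(),
                      group_delta = edge_deltas(), ar1_coefficient = 0,
                      seed = 1)
    tc <- simulate_session(cfg, "control", "t33", 42)
    z <- znormalize(tc)
    accordance(z[, 1], z[, 2])
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})
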