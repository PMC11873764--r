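edge_table <- function(t33, t40, region_1 = "A", region_2 = "B",
                       ids = sprintf("s%d", seq_along(t33)),
                       group = "music") {
  dplyr::bind_rows(
    tibble::tibble(subject_id = ids, group = group, session = "t33",
                   region_1 = region_1, region_2 = region_2,
                   accordance = t33),
    tibble::tibble(subject_id = ids, group = group, session = "t40",
                   region_1 = region_1, region_2 = region_2,
                   accordance = t40))
}

test_that("BH adjustment reproduces the published multiplicity arithmetic", {
  ref <- reference_coi_table()
  out <- bh_fdr(ref$p_raw, m = 55, alpha = 0.05)
  expect_equal(round(out$p_fdr[ref$p_raw == 0.0088], 4), 0.0403)
  expect_equal(round(out$p_fdr[ref$p_raw == 0.0067], 4), 0.0368)
  expect_length(out$survivors, 12)
})

test_that("BH step-up handles hand-checked and degenerate cases", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), m = 4)
  expect_equal(out$p_fdr, rep(0.04, 4))
  expect_equal(bh_fdr(0.37, m = 1)$p_fdr, 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "at least")
})

test_that("BH implementation equals the step-up oracle on random vectors", {
  set.seed(123)
  for (rep in 1:200) {
    k <- sample(1:40, 1)
    p <- runif(k)^sample(1:3, 1)
    m <- k + sample(0:20, 1)
    expect_equal(bh_fdr(p, m = m)$p_fdr, oracle_bh(p, m), tolerance = 1e-15)
  }
})

test_that("edge-wise paired t matches the closed-form example", {
  e <- edge_table(t33 = c(0, 0, 0), t40 = c(1, 2, 3))
  st <- paired_edge_ttest(e)
  expect_equal(st$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(st$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(st$p_raw, 0.0742, tolerance = 1e-3)
  expect_equal(st$ewd, 2)
  expect_equal(st$n, 3L)

  # swapping session labels negates t
  e_sw <- e
  e_sw$session <- ifelse(e_sw$session == "t33", "t40", "t33")
  st_sw <- paired_edge_ttest(e_sw)
  expect_equal(st_sw$t_statistic, -st$t_statistic)
  expect_equal(st_sw$ewd, -st$ewd)
})

test_that("degenerate and incomplete longitudinal designs are handled", {
  # all differences zero: undefined t, flagged, never in the COI
  e0 <- edge_table(t33 = c(0.3, 0.4, 0.5), t40 = c(0.3, 0.4, 0.5))
  st0 <- paired_edge_ttest(e0)
  expect_true(is.na(st0$t_statistic))
  expect_true(is.na(st0$p_raw))
  expect_false(st0$in_coi)

  # subject missing a session is an error naming the subject
  e <- edge_table(t33 = c(0, 0, 0, 0), t40 = c(1, 2, 3, 4))
  e <- e[!(e$subject_id == "s4" & e$session == "t40"), ]
  expect_error(paired_edge_ttest(e), "s4")

  # undefined accordance drops the edge listwise with a message
  e2 <- dplyr::bind_rows(
    edge_table(t33 = c(0.1, 0.2, 0.3), t40 = c(0.3, 0.5, 0.6)),
    edge_table(t33 = c(0.1, NA, 0.3), t40 = c(0.2, 0.3, 0.9),
               region_1 = "A", region_2 = "C"))
  expect_message(st2 <- paired_edge_ttest(e2), "dropped")
  expect_equal(nrow(st2), 1)
  expect_equal(st2$region_2, "B")
})

test_that("the COI is exactly the FDR-surviving edge set", {
  set.seed(11)
  edges <- purrr::map(1:10, function(k) {
    edge_table(t33 = runif(6, 0.1, 0.3),
               t40 = runif(6, 0.1, 0.3) + ifelse(k <= 2, 0.5, 0),
               region_1 = "A", region_2 = paste0("B", k))
  })
  st <- paired_edge_ttest(dplyr::bind_rows(edges))
  expect_true(all(st$p_fdr >= st$p_raw))
  expect_identical(st$in_coi, st$p_fdr <= 0.05)
  coi <- define_coi(st)
  expect_setequal(coi$region_2, c("B1", "B2"))
  expect_named(coi, c("region_1", "region_2", "p_fdr", "p_raw", "ewd"))

  # boundary alpha = 1 admits all defined edges; all-null admits none
  st_all <- paired_edge_ttest(dplyr::bind_rows(edges),
                              stats_config(alpha = 1 - 1e-12))
  expect_equal(nrow(define_coi(st_all)), 10)
  st1 <- st
  st1$in_coi <- FALSE
  expect_warning(empty <- define_coi(st1), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("p-to-z conversion is the upper-tail normal quantile", {
  expect_equal(pval_to_z(0.5), 0)
  expect_equal(round(pval_to_z(0.1), 4), 1.2816)
  expect_equal(round(pval_to_z(0.1), 1), 1.3)
  expect_equal(pval_to_z(0.9), -pval_to_z(0.1))
  expect_error(pval_to_z(1.5), "\\[0, 1\\]")
  expect_warning(z0 <- pval_to_z(0), "clamped")
  expect_true(is.finite(z0))

  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(pval_to_z(p)) < 0))
})

test_that("the sqrt(2)-standardized difference behaves as specified", {
  expect_equal(group_z_difference(1.5, 1.5)$z_diff, 0)
  expect_equal(round(group_z_difference(1.838477, 0)$z_diff, 4), 1.3)
  expect_equal(group_z_difference(0.4, 1.9)$z_diff,
               -group_z_difference(1.9, 0.4)$z_diff)
  zd <- group_z_difference(c(1, 2), c(0.5, -1))
  expect_equal(zd$z_diff, (zd$z_pm - zd$z_pc) / sqrt(2))
  expect_equal(zd$p_diff, pnorm(zd$z_diff, lower.tail = FALSE))
})

test_that("identical groups give zero z-difference on every COI edge", {
  set.seed(3)
  base <- edge_table(t33 = runif(8, 0.1, 0.4), t40 = runif(8, 0.2, 0.5))
  ctrl <- base
  ctrl$group <- "control"
  ctrl$subject_id <- paste0("c", ctrl$subject_id)
  both <- dplyr::bind_rows(base, ctrl)
  gd <- music_effect_test(both, tibble::tibble(region_1 = "A",
                                               region_2 = "B"))
  expect_equal(gd$z_diff, 0)
  expect_equal(gd$z_pm, gd$z_pc)
  expect_false(gd$significant)
  expect_error(music_effect_test(both, tibble::tibble(region_1 = character(),
                                                      region_2 = character())),
               "empty")
})
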