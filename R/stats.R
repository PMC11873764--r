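#' Configuration of the edge-wise maturation analysis
#'
#' @param alpha FDR level for the circuitry-of-interest definition.
#'   Default 0.05.
#' @param m Size of the test family for the Benjamini-Hochberg correction.
#'   `NULL` (default) uses the number of edges actually tested; a larger
#'   `m` supports recomputation from partial tables where the remaining
#'   tests are assumed non-significant.
#' @param sides `"two_sided"` (default) or `"one_sided_increase"` for the
#'   edge-wise paired t-tests.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, m = NULL,
                         sides = c("two_sided", "one_sided_increase")) {
  stopifnot(alpha > 0, alpha < 1)
  sides <- match.arg(sides)
  structure(list(alpha = alpha, m = m, sides = sides),
            class = "stats_config")
}

#' Configuration of the group-difference (intervention-effect) test
#'
#' @param z_threshold One-sided z cut for significance of the
#'   sqrt(2)-standardized z-score difference. Default 1.3 (the normal
#'   quantile at p = 0.1, to one decimal).
#' @return A list of class `group_diff_config` carrying the equivalent
#'   one-sided p (`p_threshold`).
#' @export
group_diff_config <- function(z_threshold = 1.3) {
  stopifnot(is.finite(z_threshold))
  structure(list(z_threshold = z_threshold,
                 p_threshold = stats::pnorm(z_threshold, lower.tail = FALSE),
                 tail = "one_sided_increase"),
            class = "group_diff_config")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusts raw p-values by the BH step-up rule over a family of `m` tests:
#' the adjusted value of the i-th smallest p is
#' `min over j >= i of m * p_(j) / j`, clipped at 1, mapped back to input
#' order. Setting `m` larger than `length(p)` treats the supplied p-values
#' as the `length(p)` smallest of `m` tests (the remaining ones assumed
#' larger) — the convention needed to recompute adjusted values from a
#' published table that prints only the significant rows.
#'
#' @param p Numeric vector of raw p-values, all in `[0, 1]`.
#' @param m Family size, at least `length(p)`. Default `length(p)`.
#' @param alpha FDR level used to report survivors. Default 0.05.
#' @return A list: `p_fdr` (adjusted values, input order) and `survivors`
#'   (integer indices with `p_fdr <= alpha`).
#' @export
bh_fdr <- function(p, m = length(p), alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) {
    stop("family size m must be at least length(p)", call. = FALSE)
  }
  p_fdr <- stats::p.adjust(p, method = "BH", n = m)
  list(p_fdr = p_fdr, survivors = which(p_fdr <= alpha))
}

#' Edge-wise paired t-tests between two sessions
#'
#' For every network pair, tests the per-subject accordance differences
#' (session 2 minus session 1) with a classical paired t-test, adjusts the
#' raw p-values by Benjamini-Hochberg over the edge family, and reports
#' the edge-weight difference (EWD, the mean per-subject change). Edges
#' with an undefined accordance in any subject-session are dropped with a
#' message. Edges whose differences have zero variance get an undefined
#' (`NA`) t and p.
#'
#' @param edges Long edge table: one row per subject-session-edge with
#'   columns `subject_id`, `session`, `region_1`, `region_2`, `accordance`
#'   (see [connectome_edges()], [compute_connectomes()]).
#' @param config A [stats_config()].
#' @param session_1,session_2 Session labels; default the two sorted
#'   unique values of `edges$session` (so `"t33"` then `"t40"`).
#' @return A tibble of class `edge_stats`, one row per tested edge:
#'   `region_1`, `region_2`, `n`, `t_statistic`, `p_raw`, `p_fdr`, `ewd`,
#'   `in_coi`; attributes `alpha`, `m`, `sides`, `n_edges_dropped`.
#' @export
paired_edge_ttest <- function(edges, config = stats_config(),
                              session_1 = NULL, session_2 = NULL) {
  sessions <- sort(unique(edges$session))
  if (is.null(session_1)) session_1 <- sessions[1]
  if (is.null(session_2)) session_2 <- sessions[2]
  stopifnot(length(sessions) == 2, session_1 != session_2)

  wide <- tidyr::pivot_wider(
    edges[edges$session %in% c(session_1, session_2),
          c("subject_id", "session", "region_1", "region_2", "accordance")],
    names_from = "session", values_from = "accordance")
  # distinguish missing-session subjects (error) from undefined edges (drop)
  per_subj <- dplyr::summarise(
    dplyr::group_by(edges, .data$subject_id),
    has_both = all(c(session_1, session_2) %in% .data$session))
  if (any(!per_subj$has_both)) {
    stop("subject(s) without both sessions: ",
         paste(per_subj$subject_id[!per_subj$has_both], collapse = ", "),
         call. = FALSE)
  }
  wide$d <- wide[[session_2]] - wide[[session_1]]

  # listwise drop (per edge) of edges with any undefined accordance
  edge_ok <- dplyr::summarise(
    dplyr::group_by(wide, .data$region_1, .data$region_2),
    ok = !anyNA(.data$d))
  n_dropped <- sum(!edge_ok$ok)
  if (n_dropped > 0) {
    message(n_dropped, " edge(s) dropped: undefined accordance in >=1 subject")
  }
  wide <- dplyr::semi_join(wide, edge_ok[edge_ok$ok, ],
                           by = c("region_1", "region_2"))

  alt <- if (config$sides == "one_sided_increase") "greater" else "two.sided"
  t_stat <- function(d) {
    if (stats::sd(d) == 0) NA_real_
    else unname(stats::t.test(d, alternative = alt)$statistic)
  }
  t_p <- function(d) {
    if (stats::sd(d) == 0) NA_real_
    else stats::t.test(d, alternative = alt)$p.value
  }
  res <- dplyr::summarise(
    dplyr::group_by(wide, .data$region_1, .data$region_2),
    n = dplyr::n(),
    ewd = mean(.data$d),
    t_statistic = t_stat(.data$d),
    p_raw = t_p(.data$d),
    .groups = "drop")
  if (any(res$n < 3)) {
    stop("paired t-test needs at least 3 complete pairs per edge",
         call. = FALSE)
  }

  m <- if (is.null(config$m)) nrow(res) else config$m
  defined <- !is.na(res$p_raw)
  p_fdr <- rep(NA_real_, nrow(res))
  if (any(defined)) {
    p_fdr[defined] <- bh_fdr(res$p_raw[defined], m = max(m, sum(defined)),
                             alpha = config$alpha)$p_fdr
  }
  out <- tibble::tibble(region_1 = res$region_1, region_2 = res$region_2,
                        n = res$n, t_statistic = res$t_statistic,
                        p_raw = res$p_raw,
                        p_fdr = p_fdr, ewd = res$ewd,
                        in_coi = !is.na(p_fdr) & p_fdr <= config$alpha)
  out <- dplyr::arrange(out, .data$region_1, .data$region_2)
  structure(out, class = c("edge_stats", class(out)),
            alpha = config$alpha, m = max(m, sum(defined)),
            sides = config$sides, n_edges_dropped = n_dropped)
}

#' Extract the circuitry of interest (COI)
#'
#' The COI is the set of edges whose FDR-adjusted paired-test p-value is
#' at most `alpha` — the maturating connections. Returns a report in the
#' conventional published layout (regions, adjusted p, raw p, EWD).
#'
#' @param edge_stats An `edge_stats` table from [paired_edge_ttest()].
#' @return A tibble sorted by region labels: `region_1`, `region_2`,
#'   `p_fdr`, `p_raw`, `ewd`. Empty (with a warning) when no edge
#'   survives.
#' @export
define_coi <- function(edge_stats) {
  coi <- edge_stats[edge_stats$in_coi, c("region_1", "region_2",
                                         "p_fdr", "p_raw", "ewd")]
  coi <- dplyr::arrange(tibble::as_tibble(coi),
                        .data$region_1, .data$region_2)
  if (nrow(coi) == 0) {
    warning("no edge survives FDR correction: empty circuitry of interest",
            call. = FALSE)
  }
  coi
}

#' Convert one-sided p-values to z-scores
#'
#' `z = qnorm(1 - p)`: the standard-normal quantile of the upper-tail
#' probability, strictly decreasing in p. Under the null hypothesis a
#' uniformly distributed p maps to a standard-normal z. Values outside
#' `(eps, 1 - eps)` are clamped with a warning so the quantile stays
#' finite.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param eps Clamping bound. Default `1e-15`.
#' @return Numeric vector of z-scores.
#' @export
pval_to_z <- function(p, eps = 1e-15) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p < eps) || any(p > 1 - eps)) {
    warning("p-value(s) clamped to [", format(eps), ", 1 - ", format(eps),
            "] before quantile transform", call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stats::qnorm(p, lower.tail = FALSE)
}

#' sqrt(2)-standardized z-score difference between groups
#'
#' For independent group z-scores (each standard normal under the null),
#' the difference has variance 2 by the variance-sum law, so
#' `z_diff = (z_pm - z_pc) / sqrt(2)` is standard normal under the null of
#' no group difference. `p_diff` is its upper-tail probability.
#'
#' @param z_pm,z_pc Numeric vectors: z-scores of the music (intervention)
#'   and control groups.
#' @return A tibble: `z_pm`, `z_pc`, `z_diff`, `p_diff`.
#' @export
group_z_difference <- function(z_pm, z_pc) {
  stopifnot(all(is.finite(z_pm)), all(is.finite(z_pc)),
            length(z_pm) == length(z_pc))
  z_diff <- (z_pm - z_pc) / sqrt(2)
  tibble::tibble(z_pm = z_pm, z_pc = z_pc, z_diff = z_diff,
                 p_diff = stats::pnorm(z_diff, lower.tail = FALSE))
}

#' Intervention-effect test on the circuitry of interest
#'
#' For each COI edge, runs within-group paired t-tests of the session-2
#' vs session-1 accordance (one-sided, testing an increase) separately in
#' the music and control groups, converts the p-values to z-scores with
#' [pval_to_z()], and standardizes their difference by sqrt(2)
#' ([group_z_difference()]). An edge is significant when
#' `z_diff >= z_threshold` (inclusive).
#'
#' @param edges Long edge table with columns `subject_id`, `group`,
#'   `session`, `region_1`, `region_2`, `accordance`.
#' @param coi Data frame of COI edges (`region_1`, `region_2`), e.g. from
#'   [define_coi()].
#' @param config A [group_diff_config()].
#' @param session_1,session_2 Session labels; defaults as in
#'   [paired_edge_ttest()].
#' @return A tibble of class `group_diff`, one row per COI edge:
#'   `region_1`, `region_2`, `z_pm`, `z_pc`, `z_diff`, `p_diff`,
#'   `significant`.
#' @export
music_effect_test <- function(edges, coi, config = group_diff_config(),
                              session_1 = NULL, session_2 = NULL) {
  if (nrow(coi) == 0) stop("the circuitry of interest is empty",
                           call. = FALSE)
  stopifnot(all(c("music", "control") %in% edges$group))
  one_group <- function(g) {
    sub <- dplyr::semi_join(edges[edges$group == g, ], coi,
                            by = c("region_1", "region_2"))
    paired_edge_ttest(sub, stats_config(sides = "one_sided_increase"),
                      session_1 = session_1, session_2 = session_2)
  }
  zm <- one_group("music")
  zc <- one_group("control")
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(zm), "region_1", "region_2",
                  p_music = "p_raw"),
    dplyr::select(tibble::as_tibble(zc), "region_1", "region_2",
                  p_control = "p_raw"),
    by = c("region_1", "region_2"))
  zd <- group_z_difference(pval_to_z(joined$p_music),
                           pval_to_z(joined$p_control))
  out <- dplyr::bind_cols(joined[, c("region_1", "region_2")], zd)
  out$significant <- out$z_diff >= config$z_threshold
  out <- dplyr::arrange(out, .data$region_1, .data$region_2)
  structure(out, class = c("group_diff", class(out)),
            z_threshold = config$z_threshold)
}
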