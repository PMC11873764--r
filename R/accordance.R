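#' Accordance estimation parameters
#'
#' The accordance statistic gates each standardized signal at a symmetric
#' pair of thresholds `(+u, -u)` where `u` is the standard-normal quantile
#' of `quantile_prob` (default 0.8, so u ~= 0.8416). The `magnitude`
#' variant keeps the signal values of the supra-/sub-threshold samples;
#' the `binary` variant replaces them by +/-1 indicators.
#'
#' @param quantile_prob Normal quantile probability defining the
#'   activation threshold, in (0.5, 1). Default 0.8.
#' @param variant `"magnitude"` (default) or `"binary"`.
#' @return A list of class `accordance_params` with the derived threshold
#'   `u`.
#' @export
accordance_params <- function(quantile_prob = 0.8,
                              variant = c("magnitude", "binary")) {
  stopifnot(quantile_prob > 0.5, quantile_prob < 1)
  variant <- match.arg(variant)
  structure(list(quantile_prob = quantile_prob,
                 u = stats::qnorm(quantile_prob),
                 variant = variant),
            class = "accordance_params")
}

#' Z-normalize network time courses
#'
#' Centers each column to mean 0 and scales it to unit *sample* standard
#' deviation (denominator `n - 1`).
#'
#' @param tc Time-course matrix (volumes x networks).
#' @return Matrix of the same shape, columns standardized.
#' @export
znormalize <- function(tc) {
  tc <- as.matrix(tc)
  if (nrow(tc) < 2) stop("need at least 2 volumes", call. = FALSE)
  sds <- apply(tc, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0) {
    nm <- colnames(tc)
    lab <- if (is.null(nm)) as.character(zero) else nm[zero]
    stop("zero-variance network(s): ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  scale(tc, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Threshold-gate a standardized signal
#'
#' Splits a standardized signal into its suprathreshold positive part
#' `x_plus` (values `>= u`, zero elsewhere) and subthreshold negative part
#' `x_minus` (values `<= -u`), with the thresholded energy
#' `sigma = sqrt(<x+,x+> + <x-,x->)`. In the `binary` variant the retained
#' samples are replaced by +1 / -1.
#'
#' @param z Standardized numeric vector.
#' @param params An [accordance_params()].
#' @return A list of class `thresholded_signal`: `x_plus`, `x_minus`,
#'   `sigma`.
#' @export
threshold_signal <- function(z, params = accordance_params()) {
  z <- as.numeric(z)
  u <- params$u
  if (params$variant == "binary") {
    x_plus <- as.numeric(z >= u)
    x_minus <- -as.numeric(z <= -u)
  } else {
    x_plus <- ifelse(z >= u, z, 0)
    x_minus <- ifelse(z <= -u, z, 0)
  }
  structure(list(x_plus = x_plus, x_minus = x_minus,
                 sigma = sqrt(sum(x_plus^2) + sum(x_minus^2))),
            class = "thresholded_signal")
}

as_thresholded <- function(x, params) {
  if (inherits(x, "thresholded_signal")) x else threshold_signal(x, params)
}

#' Accordance between two signals
#'
#' Accordance measures coactivation plus codeactivation: the inner product
#' of the positive (suprathreshold) parts plus the inner product of the
#' negative (subthreshold) parts, normalized by the product of thresholded
#' energies, `a = (<x+_i, x+_j> + <x-_i, x-_j>) / (sigma_i sigma_j)`. It
#' is symmetric, lies in `[0, 1]`, and equals 1 for a signal with itself.
#'
#' @param s_i,s_j `thresholded_signal` objects (or standardized numeric
#'   vectors, thresholded on the fly with `params`).
#' @param params An [accordance_params()]; used only when inputs are
#'   numeric vectors.
#' @return A scalar in `[0, 1]`, or `NA` (with a warning) when either
#'   signal never crosses its thresholds.
#' @export
accordance <- function(s_i, s_j, params = accordance_params()) {
  s_i <- as_thresholded(s_i, params)
  s_j <- as_thresholded(s_j, params)
  if (s_i$sigma == 0 || s_j$sigma == 0) {
    warning("zero thresholded energy: accordance undefined", call. = FALSE)
    return(NA_real_)
  }
  (sum(s_i$x_plus * s_j$x_plus) + sum(s_i$x_minus * s_j$x_minus)) /
    (s_i$sigma * s_j$sigma)
}

#' Discordance between two signals
#'
#' The anti-coupling complement of [accordance()]: cross-sign threshold
#' exceedances, `d = -(<x+_i, x-_j> + <x-_i, x+_j>) / (sigma_i sigma_j)`,
#' in `[0, 1]`. `discordance(x, y)` equals `accordance(x, -y)`.
#'
#' @inheritParams accordance
#' @return A scalar in `[0, 1]`, or `NA` when either energy is zero.
#' @export
discordance <- function(s_i, s_j, params = accordance_params()) {
  s_i <- as_thresholded(s_i, params)
  s_j <- as_thresholded(s_j, params)
  if (s_i$sigma == 0 || s_j$sigma == 0) {
    warning("zero thresholded energy: discordance undefined", call. = FALSE)
    return(NA_real_)
  }
  -(sum(s_i$x_plus * s_j$x_minus) + sum(s_i$x_minus * s_j$x_plus)) /
    (s_i$sigma * s_j$sigma)
}

#' Accordance connectome of one subject-session
#'
#' Standardizes the time courses, threshold-gates each network signal, and
#' fills the symmetric N x N matrix of pairwise accordance values; the
#' diagonal is excluded (set `NA`). Networks whose signal never crosses
#' the threshold yield undefined (`NA`) edges with a warning — they are
#' excluded from downstream statistics rather than imputed.
#'
#' @param tc Time-course matrix (volumes x networks, named columns).
#' @param params An [accordance_params()].
#' @param subject_id,session Optional identifiers stored as attributes.
#' @return An N x N matrix of class `connectome` with network dimnames and
#'   attributes `subject_id`, `session`, `params`.
#' @export
build_connectome <- function(tc, params = accordance_params(),
                             subject_id = NULL, session = NULL) {
  tc <- as.matrix(tc)
  if (is.null(colnames(tc))) {
    colnames(tc) <- sprintf("N%02d", seq_len(ncol(tc)))
  }
  z <- znormalize(tc)
  u <- params$u
  if (params$variant == "binary") {
    xp <- (z >= u) + 0
    xm <- -((z <= -u) + 0)
  } else {
    xp <- z * (z >= u)
    xm <- z * (z <= -u)
  }
  sigma <- sqrt(colSums(xp^2) + colSums(xm^2))
  dead <- which(sigma == 0)
  if (length(dead) > 0) {
    warning("network(s) with zero thresholded energy (edges undefined): ",
            paste(colnames(tc)[dead], collapse = ", "), call. = FALSE)
    sigma[dead] <- NA_real_
  }
  acc <- (crossprod(xp) + crossprod(xm)) / tcrossprod(sigma)
  diag(acc) <- NA_real_
  dimnames(acc) <- list(colnames(tc), colnames(tc))
  structure(acc, class = c("connectome", "matrix"),
            subject_id = subject_id, session = session, params = params)
}

#' Mean connectome across subjects
#'
#' Elementwise mean of a list of connectomes sharing identical network
#' labels in identical order; undefined edges are ignored per element
#' (mean over the subjects where the edge is defined).
#'
#' @param connectomes List of `connectome` matrices.
#' @return A `connectome` matrix of the elementwise means.
#' @export
group_average_connectome <- function(connectomes) {
  stopifnot(length(connectomes) >= 1)
  labels <- colnames(connectomes[[1]])
  for (k in seq_along(connectomes)) {
    if (!identical(colnames(connectomes[[k]]), labels)) {
      stop("connectome ", k, " has mismatched network labels; ",
           "inputs are not reordered silently", call. = FALSE)
    }
  }
  arr <- simplify2array(lapply(connectomes, unclass))
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  diag(avg) <- NA_real_
  structure(avg, class = c("connectome", "matrix"),
            subject_id = NULL, session = attr(connectomes[[1]], "session"),
            params = attr(connectomes[[1]], "params"))
}

#' Long-format edge table of a connectome
#'
#' @param x A `connectome` matrix.
#' @return A tibble with one row per unordered network pair (upper
#'   triangle): `region_1`, `region_2`, `accordance`.
#' @export
connectome_edges <- function(x) {
  labels <- colnames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(region_1 = labels[idx[, 1]],
                 region_2 = labels[idx[, 2]],
                 accordance = unclass(x)[idx])
}

#' @export
print.connectome <- function(x, digits = 3, ...) {
  sid <- attr(x, "subject_id"); ses <- attr(x, "session")
  cat(sprintf("<connectome> %d networks, %d edges%s%s\n",
              ncol(x), ncol(x) * (ncol(x) - 1) / 2,
              if (!is.null(sid)) paste0(", subject ", sid) else "",
              if (!is.null(ses)) paste0(", session ", ses) else ""))
  print(round(unclass(x), digits), ...)
  invisible(x)
}
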