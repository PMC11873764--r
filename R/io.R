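#' Read a network time-course TSV
#'
#' Expects a tab-separated file with a header row of network labels and
#' one numeric row per volume.
#'
#' @param path File path.
#' @return Numeric matrix (volumes x networks) with named columns.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "numeric"),
    error = function(e) {
      stop("cannot parse time-course file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  as.matrix(df)
}

#' Write a network time-course TSV
#'
#' @param tc Matrix (volumes x networks) with column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tc, path) {
  tc <- as.matrix(tc)
  header <- paste(colnames(tc), collapse = "\t")
  body <- apply(tc, 1, function(r) paste(sprintf("%.17g", r),
                                         collapse = "\t"))
  ok <- tryCatch({
    writeLines(c(header, body), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read an SPM-style realignment parameter file
#'
#' Six whitespace-separated numeric columns per volume (3 translations in
#' mm, 3 rotations in radians), no header — the `rp_*.txt` dialect.
#'
#' @param path File path.
#' @return Numeric matrix (volumes x 6) with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) {
      stop("cannot parse motion file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (ncol(df) != 6) {
    stop("motion file ", path, " has ", ncol(df),
         " columns; expected 6 (3 translations, 3 rotations)",
         call. = FALSE)
  }
  m <- as.matrix(df)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write an SPM-style realignment parameter file
#'
#' @param motion Matrix (volumes x 6).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  body <- apply(motion, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = "  "))
  writeLines(body, path)
  invisible(path)
}

#' Read a cohort manifest TSV
#'
#' @param path Manifest path; columns `subject_id`, `group`, `session`,
#'   `timecourse_path`, `motion_path`. Relative file paths are resolved
#'   against the manifest's directory.
#' @return A tibble of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "session",
            "timecourse_path", "motion_path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  root <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  man$timecourse_path <- fix(man$timecourse_path)
  man$motion_path <- fix(man$motion_path)
  class(man) <- c("cohort_manifest", class(man))
  man
}

#' Write a connectome as a labeled square-matrix TSV
#'
#' @param x A `connectome` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  labels <- colnames(x)
  header <- paste(c("", labels), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(labels[i], sprintf("%.17g", unclass(x)[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labeled square-matrix connectome TSV
#'
#' @param path File path (as written by [write_connectome()]).
#' @return A `connectome` matrix.
#' @export
read_connectome <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("file is not a labeled square connectome matrix: ", path,
         call. = FALSE)
  }
  structure(m, class = c("connectome", "matrix"))
}
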