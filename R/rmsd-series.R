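#' Inclusive frame window
#'
#' A contiguous analysis interval over trajectory frames, such as the
#' equilibrated tail of a run used for energy averaging.
#'
#' @param start_frame,end_frame inclusive frame indices, `start <= end`.
#' @param start_ns,end_ns optional times of the window bounds.
#' @return object of class `frame_window`.
#' @export
frame_window <- function(start_frame, end_frame, start_ns = NA_real_, end_ns = NA_real_) {
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (is.na(start_frame) || is.na(end_frame) || start_frame > end_frame) {
    abort("frame_window requires start_frame <= end_frame")
  }
  structure(
    list(
      start_frame = start_frame, end_frame = end_frame,
      start_ns = start_ns, end_ns = end_ns
    ),
    class = "frame_window"
  )
}

#' @export
print.frame_window <- function(x, ...) {
  cat(sprintf(
    "<frame_window [%d, %d]%s>\n", x$start_frame, x$end_frame,
    if (!is.na(x$start_ns)) sprintf(" (%.4g-%.4g ns)", x$start_ns, x$end_ns) else ""
  ))
  invisible(x)
}

#' Per-frame Calpha RMSD against a reference frame
#'
#' Each frame is rigidly superposed onto the reference before the RMSD is
#' taken, so global rotation and translation of a frame contribute nothing.
#'
#' @param traj a `btb_trajectory`.
#' @param reference_frame 1-based frame index of the reference (default 1).
#' @param selection atom names entering the fit; default `"CA"`.
#' @return tibble of class `rmsd_series` with columns `frame` (1-based),
#'   `time_ns`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = "CA") {
  sel <- which(traj$topology$atom %in% selection)
  if (length(sel) == 0) abort("selection matches no atoms")
  ref <- traj$coords[[reference_frame]][sel, , drop = FALSE]
  r <- vapply(
    traj$coords,
    function(m) kabsch_superpose(m[sel, , drop = FALSE], ref)$rmsd,
    0
  )
  out <- tibble(frame = seq_along(traj$coords), time_ns = traj$times, rmsd = r)
  class(out) <- c("rmsd_series", class(tibble()))
  out
}

#' Detect the equilibrated window of an RMSD series
#'
#' A stable interval is a contiguous stretch whose RMSD values span at most
#' `tol_angstrom` (default 1 Angstrom). The longest such window ending at the
#' final frame is returned, reflecting the convention that production
#' analysis uses the equilibrated tail of a run. If that terminal window is
#' shorter than `min_fraction` of the series, the longest stable window
#' anywhere is returned instead, with a warning (ties broken toward the
#' latest end).
#'
#' @param rmsd an `rmsd_series` tibble or a bare numeric vector.
#' @param tol_angstrom maximum allowed max-min spread (Angstrom).
#' @param min_fraction minimum acceptable terminal-window length as a
#'   fraction of the series length.
#' @return a [frame_window()] in the series' frame numbering, or `NULL` when
#'   no window of length >= 2 satisfies the tolerance (widen `tol_angstrom`).
#' @export
find_equilibrated_window <- function(rmsd, tol_angstrom = 1.0, min_fraction = 0.2) {
  if (is.data.frame(rmsd)) {
    frames <- rmsd$frame
    times <- rmsd$time_ns
    x <- rmsd$rmsd
  } else {
    x <- as.numeric(rmsd)
    frames <- seq_along(x)
    times <- rep(NA_real_, length(x))
  }
  n <- length(x)
  if (n < 2) abort("RMSD series must have at least 2 values")

  # longest suffix window: spread is monotone as the window grows backward
  lo <- x[n]
  hi <- x[n]
  s <- n
  while (s > 1) {
    nlo <- min(lo, x[s - 1])
    nhi <- max(hi, x[s - 1])
    if (nhi - nlo > tol_angstrom) break
    lo <- nlo
    hi <- nhi
    s <- s - 1
  }
  terminal_len <- n - s + 1

  if (terminal_len >= 2 && terminal_len >= min_fraction * n) {
    return(frame_window(frames[s], frames[n], times[s], times[n]))
  }

  best <- longest_stable_window(x, tol_angstrom)
  if (is.null(best)) {
    if (terminal_len >= 2) {
      return(frame_window(frames[s], frames[n], times[s], times[n]))
    }
    return(NULL)
  }
  if (terminal_len >= best["len"]) {
    if (terminal_len < 2) return(NULL)
    return(frame_window(frames[s], frames[n], times[s], times[n]))
  }
  warn(sprintf(
    "terminal stable window is short (%d of %d frames); returning the longest stable window anywhere",
    terminal_len, n
  ))
  i <- best["start"]
  j <- best["end"]
  frame_window(frames[i], frames[j], times[i], times[j])
}

# longest window with max-min <= tol, length >= 2; ties -> latest end.
longest_stable_window <- function(x, tol) {
  n <- length(x)
  best_len <- 1
  best <- NULL
  i <- 1
  lo <- x[1]
  hi <- x[1]
  j <- 1
  # grow-and-rescan two-pointer: on violation restart bounds from new start
  for (start in seq_len(n)) {
    if (start > 1) {
      if (j < start) {
        j <- start
      }
      lo <- min(x[start:j])
      hi <- max(x[start:j])
    }
    while (j < n && max(hi, x[j + 1]) - min(lo, x[j + 1]) <= tol) {
      j <- j + 1
      lo <- min(lo, x[j])
      hi <- max(hi, x[j])
    }
    len <- j - start + 1
    if (len >= 2 && len >= best_len) {
      best_len <- len
      best <- c(start = start, end = j, len = len)
    }
    if (j == n) break
  }
  best
}

#' @exportS3Method ggplot2::autoplot
autoplot.rmsd_series <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ns, .data$rmsd)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (ns)", y = "RMSD (Å)") +
    ggplot2::theme_classic()
  if (!is.null(window)) {
    t0 <- object$time_ns[match(window$start_frame, object$frame)]
    t1 <- object$time_ns[match(window$end_frame, object$frame)]
    p <- p + ggplot2::annotate("rect",
      xmin = t0, xmax = t1, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "steelblue"
    )
  }
  p
}
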