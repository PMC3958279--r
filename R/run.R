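#' Run fall detection over a frame sequence
#'
#' Drives the whole pipeline over an ordered list of raw depth frames.  If
#' no reference frame is supplied, the first `ref_frames` frames (which
#' must show the empty scene) are preprocessed and their pixel-wise median
#' becomes the reference; all frames, including those, are then processed.
#'
#' @param frames List of `depth_frame`s in stage `DF`.
#' @param cfg A [system_config()].
#' @param rf Optional reference frame (`depth_frame`, stage `RF`).
#' @param ref_frames Number of leading frames used to capture the
#'   reference when `rf` is `NULL`.
#' @return A `fall_run` object: list with `events`, `heights` (per frame
#'   and person), `info` (per-frame tracking conditions), `n_frames`,
#'   `config` and the final `registry`.  Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_fall_detection <- function(frames, cfg = system_config(), rf = NULL,
                               ref_frames = 5L) {
  stopifnot(length(frames) > 0)
  if (is.null(rf)) {
    n0 <- min(ref_frames, length(frames))
    cfs <- lapply(frames[seq_len(n0)],
                  function(f) fill_nulls(clamp_floor(f, cfg), cfg))
    rf <- capture_reference(cfs)
  }
  state <- pipeline_state(rf, cfg)
  events <- list(); heights <- list(); info <- list()
  for (i in seq_along(frames)) {
    out <- process_frame(frames[[i]], state)
    state <- out$state
    events[[i]] <- out$events
    heights[[i]] <- out$heights
    if (nrow(out$info)) info[[i]] <- mutate(out$info, frame_index = i)
  }
  structure(list(
    events = bind_rows(events),
    heights = bind_rows(heights),
    info = bind_rows(info),
    n_frames = length(frames),
    config = cfg,
    registry = state$registry
  ), class = "fall_run")
}

#' @export
print.fall_run <- function(x, ...) {
  cat(sprintf("<fall_run: %d frames, %d person(s) tracked, %d fall event(s)>\n",
              x$n_frames, length(unique(x$heights$person_id)),
              nrow(x$events)))
  if (nrow(x$events)) {
    cat("events:\n")
    print(as.data.frame(x$events))
  }
  invisible(x)
}

#' Tidy a fall-detection run
#'
#' `tidy()` returns the fall events, one row per event; `glance()` returns
#' a one-row summary of the run.
#'
#' @param x A `fall_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fall_run <- function(x, ...) x$events

#' @rdname tidy.fall_run
#' @export
glance.fall_run <- function(x, ...) {
  tibble(n_frames = x$n_frames,
         n_persons = length(unique(x$heights$person_id)),
         n_events = nrow(x$events),
         frames_below = sum(x$heights$below))
}

#' Plot the tracked height trace of a run
#'
#' Height of each tracked person's central point above the floor over
#' time, with below-threshold frames highlighted and fall events marked —
#' the standard way to read a monitoring session at a glance.
#'
#' @param object A `fall_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fall_run <- function(object, ...) {
  h <- mutate(object$heights,
              time_s = .data$frame_index / object$config$fps,
              person = factor(.data$person_id))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$time_s,
                                       y = .data$height_mm,
                                       group = .data$person)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$below), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "red"),
      labels = c(`FALSE` = "tracking", `TRUE` = "below threshold"),
      name = NULL) +
    ggplot2::geom_hline(yintercept = object$config$fall_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "central-point height (mm)")
  if (nrow(object$events)) {
    ev <- mutate(object$events, time_s = .data$frame_index / object$config$fps)
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "red", alpha = 0.5)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

## Contiguous TRUE runs of `flag` as (start, end) frame intervals.
flag_intervals <- function(frames, flag) {
  if (length(frames) == 0L || !any(flag)) {
    return(tibble(start = integer(), end = integer()))
  }
  o <- order(frames)
  frames <- frames[o]; flag <- flag[o]
  f <- frames[flag]
  brk <- c(TRUE, diff(f) > 1L)
  grp <- cumsum(brk)
  tibble(start = as.integer(tapply(f, grp, min)),
         end = as.integer(tapply(f, grp, max)))
}

#' Score detected fall events against ground truth
#'
#' Each ground-truth fall interval (consecutive frames with the fallen
#' flag set, per actor) counts as detected if some event falls inside the
#' interval dilated by `tol` frames; events matching no dilated interval
#' are false alarms.  Latency is the first matching event frame minus the
#' interval start (negative when the alarm fires during the fall motion,
#' just before the body settles).
#'
#' @param events Events tibble (`frame_index`, ...), e.g. `tidy(run)`.
#' @param truth Ground-truth tibble with columns `frame_index`, `actor`,
#'   `fallen` (as produced by the simulator).
#' @param tol Latency tolerance in frames.
#' @return List with `intervals` (per ground-truth interval: detected,
#'   latency) and `summary` (one row: detections, misses, false alarms).
#' @export
evaluate_events <- function(events, truth, tol = 5L) {
  empty_ivs <- tibble(start = integer(), end = integer(), actor = integer(),
                      detected = logical(), latency = integer())
  ivs <- if (!all(c("actor", "frame_index", "fallen") %in% names(truth)) ||
             nrow(truth) == 0) empty_ivs else {
    bind_rows(lapply(split(truth, truth$actor), function(tr) {
      mutate(flag_intervals(tr$frame_index, tr$fallen), actor = tr$actor[1])
    }))
  }
  if (nrow(ivs) == 0) ivs <- empty_ivs
  if (nrow(ivs)) {
    ivs$detected <- FALSE
    ivs$latency <- NA_integer_
    for (i in seq_len(nrow(ivs))) {
      hit <- events$frame_index >= ivs$start[i] - tol &
        events$frame_index <= ivs$end[i] + tol
      ivs$detected[i] <- any(hit)
      if (any(hit)) {
        ivs$latency[i] <- min(events$frame_index[hit]) - ivs$start[i]
      }
    }
  }
  false_alarm <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(ivs))) {
    false_alarm <- false_alarm &
      !(events$frame_index >= ivs$start[i] - tol &
        events$frame_index <= ivs$end[i] + tol)
  }
  list(intervals = ivs,
       summary = tibble(n_intervals = nrow(ivs),
                        detections = sum(ivs$detected),
                        misses = sum(!ivs$detected),
                        false_alarms = sum(false_alarm)))
}
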