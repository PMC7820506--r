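#' Assign events to known target positions
#'
#' Each event is assigned to the nearest target within `radius`; events
#' farther than `radius` from every target are retained as orphans. In
#' synthetic data target positions are known, so no clustering is performed.
#'
#' @param events Data frame with `x_nm`, `y_nm` columns (binding events or
#'   linked localization events).
#' @param targets Data frame with `target_id`, `x_nm`, `y_nm`.
#' @param radius Assignment radius in nm.
#' @return An object of class `target_assignment`: list with `assigned`
#'   (events plus `target_id` column), `orphans` (unassigned events),
#'   `targets`, `radius`.
#' @export
assign_events <- function(events, targets, radius = 50) {
  stopifnot(is.data.frame(events), is.data.frame(targets), radius > 0,
            all(c("x_nm", "y_nm") %in% names(events)),
            all(c("target_id", "x_nm", "y_nm") %in% names(targets)))
  if (anyDuplicated(targets[, c("x_nm", "y_nm")]))
    stop("duplicate target positions")
  n <- nrow(events)
  if (n == 0L) {
    assigned <- cbind(events, target_id = integer(0))
    return(structure(list(assigned = assigned, orphans = events,
                          targets = targets, radius = radius),
                     class = "target_assignment"))
  }
  # nearest target by squared distance
  d2 <- outer(events$x_nm, targets$x_nm, "-")^2 +
    outer(events$y_nm, targets$y_nm, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(n), j)]
  hit <- dmin <= radius^2
  assigned <- events[hit, , drop = FALSE]
  assigned$target_id <- targets$target_id[j[hit]]
  structure(list(assigned = assigned,
                 orphans = events[!hit, , drop = FALSE],
                 targets = targets, radius = radius),
            class = "target_assignment")
}

#' @export
print.target_assignment <- function(x, ...) {
  cat(sprintf("<target_assignment> %d events on %d targets (radius %g nm), %d orphans\n",
              nrow(x$assigned), nrow(x$targets), x$radius, nrow(x$orphans)))
  invisible(x)
}

#' Mean event rate per target
#'
#' Events per second per target (e.g. per microsphere or per origami tile),
#' counting zero for targets without any assigned event.
#'
#' @param assignment A [assign_events()] result.
#' @param duration Acquisition duration in seconds (> 0).
#' @return List with `per_target` (data frame `target_id`, `n_events`,
#'   `rate`), `mean_rate`, `sd_rate`.
#' @export
event_rate_per_target <- function(assignment, duration) {
  stopifnot(inherits(assignment, "target_assignment"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  ids <- assignment$targets$target_id
  cnt <- table(factor(assignment$assigned$target_id, levels = ids))
  per <- data.frame(target_id = ids, n_events = as.integer(cnt),
                    rate = as.integer(cnt) / duration)
  list(per_target = per, mean_rate = mean(per$rate), sd_rate = stats::sd(per$rate))
}

event_start_frames <- function(events, frame_time) {
  if ("start_frame" %in% names(events)) return(events$start_frame)
  if ("t_start" %in% names(events)) {
    if (is.na(frame_time)) stop("frame_time needed to convert event times to frames")
    return(floor(events$t_start / frame_time))
  }
  stop("events need a 'start_frame' or 't_start' column")
}

#' Count targets detected in a frame window
#'
#' A target counts as detected when at least `min_events` of its assigned
#' events start inside the half-open frame window `[from, to)`.
#'
#' @param assignment A [assign_events()] result.
#' @param frame_window Integer length-2, `c(from, to)` in frames.
#' @param min_events Minimum events for detection (>= 1).
#' @param frame_time Seconds per frame (needed when events carry `t_start`
#'   rather than `start_frame`).
#' @return Integer count of detected targets.
#' @export
detected_sites <- function(assignment, frame_window, min_events = 1L,
                           frame_time = NA_real_) {
  stopifnot(inherits(assignment, "target_assignment"), min_events >= 1)
  if (length(frame_window) != 2L || frame_window[2] <= frame_window[1])
    stop("empty frame window")
  ev <- assignment$assigned
  f <- event_start_frames(ev, frame_time)
  inw <- f >= frame_window[1] & f < frame_window[2]
  cnt <- table(factor(ev$target_id[inw],
                      levels = assignment$targets$target_id))
  sum(cnt >= min_events)
}

#' Photoinduced site loss between two frame windows
#'
#' Compares the number of targets detected in two observation windows
#' (typically the first and second 20,000 frames of a 40,000-frame run) and
#' reports the percentage lost, `100 * (w1 - w2) / w1`.
#'
#' @param assignment A [assign_events()] result.
#' @param windows List of two frame windows, each `c(from, to)`.
#' @param min_events Detection rule, minimum events per window.
#' @param frame_time Seconds per frame (see [detected_sites()]).
#' @return An object of class `site_loss_report`: list with `n_targets`,
#'   `sites_detected_window1`, `sites_detected_window2`, `percent_loss`.
#' @export
site_loss_percent <- function(assignment, windows, min_events = 1L,
                              frame_time = NA_real_) {
  stopifnot(is.list(windows), length(windows) == 2L)
  w1 <- detected_sites(assignment, windows[[1]], min_events, frame_time)
  w2 <- detected_sites(assignment, windows[[2]], min_events, frame_time)
  structure(list(n_targets = nrow(assignment$targets),
                 sites_detected_window1 = w1, sites_detected_window2 = w2,
                 percent_loss = if (w1 > 0) 100 * (w1 - w2) / w1 else NA_real_),
            class = "site_loss_report")
}

#' @export
print.site_loss_report <- function(x, ...) {
  cat(sprintf("<site_loss_report> %d targets: %d -> %d detected sites (%.2f%% loss)\n",
              x$n_targets, x$sites_detected_window1, x$sites_detected_window2,
              x$percent_loss))
  invisible(x)
}

#' Measured non-specific event fraction
#'
#' Empirical counterpart of [nonspecific_fraction()]: the share of events not
#' assigned to any known target, `orphans / (assigned + orphans)`.
#'
#' @param assignment A [assign_events()] result.
#' @return Fraction in \[0, 1\].
#' @export
measured_nonspecific_fraction <- function(assignment) {
  stopifnot(inherits(assignment, "target_assignment"))
  n_a <- nrow(assignment$assigned)
  n_o <- nrow(assignment$orphans)
  if (n_a + n_o == 0L) stop("no events")
  n_o / (n_a + n_o)
}

#' Serialize a site-loss report
#'
#' @param report A `site_loss_report`.
#' @param path Output path (`.json` or `.csv` by extension).
#' @export
write_site_loss_report <- function(report, path) {
  stopifnot(inherits(report, "site_loss_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(unclass(report)), path, row.names = FALSE)
  }
  invisible(path)
}
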