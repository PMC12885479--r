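#' Qualifying residue set for inaccessibility
#'
#' The C-terminal tail residues whose salt bridges classify a tail as
#' inaccessible: the glutamates E445, E446, E447, E449, E450 by default,
#' optionally extended with the C-terminal residue 451. (The two published
#' descriptions of this set differ — "E445-E450" versus "E445 to Y451" —
#' so the C-terminus is an explicit opt-in.)
#'
#' @param include_cterm Add residue 451.
#' @return An integer vector of residue numbers with attribute
#'   `include_cterm`.
#' @export
qualifying_set <- function(include_cterm = FALSE) {
  res <- c(445L, 446L, 447L, 449L, 450L)
  if (isTRUE(include_cterm)) res <- c(res, 451L)
  attr(res, "include_cterm") <- isTRUE(include_cterm)
  res
}

glutamate_rows <- function() c(441L, 443L, 445L, 446L, 447L, 449L, 450L)

#' Interaction-rate matrix of tail residues with the four body sites
#'
#' For each tail residue and site, the fraction of analysed frames in which
#' that residue forms at least one salt bridge with that site, pooled over
#' all tails (the default "occupancy" estimator). An alternative
#' events-per-ns estimator counts binding events (maximal runs of
#' consecutive bound frames per tail/residue/site) divided by the total
#' trajectory time.
#'
#' @param contacts Contacts tibble from [detect_contacts()] /
#'   [detect_salt_bridges()].
#' @param n_frames Total number of analysed frames (including frames with
#'   no contacts).
#' @param rows Tail residues to report; default the seven alphaCTT
#'   glutamates.
#' @param sites Site ids to report (default 1:4).
#' @param condition_tag `"GDP"`, `"GTP"` or `"other"`.
#' @param estimator `"occupancy"` (fraction of frames) or
#'   `"events_per_ns"`.
#' @param per_tail Keep a `tail_id` column instead of pooling.
#' @param total_time_ns Trajectory length, required for the event
#'   estimator.
#' @return An `interaction_rate` object wrapping a tidy tibble
#'   (`tail_residue`, `site_id`, `rate`) over the full residue x site grid.
#' @export
interaction_rate <- function(contacts, n_frames,
                             rows = glutamate_rows(), sites = 1:4,
                             condition_tag = "other",
                             estimator = c("occupancy", "events_per_ns"),
                             per_tail = FALSE, total_time_ns = NULL) {
  estimator <- match.arg(estimator)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (nrow(contacts) > 0L && any(contacts$frame >= n_frames)) {
    abort("Contacts reference frames >= n_frames; inconsistent input.")
  }
  keep <- contacts |>
    dplyr::filter(.data$tail_residue %in% rows, .data$site_id %in% sites)
  grid_by <- if (per_tail) c("tail_id", "tail_residue", "site_id")
             else c("tail_residue", "site_id")
  if (estimator == "occupancy") {
    cells <- keep |>
      dplyr::select(dplyr::all_of(c(grid_by, "frame"))) |>
      dplyr::distinct() |>
      dplyr::summarise(n_bound = dplyr::n(), .by = dplyr::all_of(grid_by)) |>
      dplyr::mutate(rate = .data$n_bound / n_frames) |>
      dplyr::select(-"n_bound")
  } else {
    if (is.null(total_time_ns) || total_time_ns <= 0) {
      abort("`total_time_ns` is required for the events-per-ns estimator.")
    }
    cells <- keep |>
      dplyr::distinct(.data$tail_id, .data$tail_residue, .data$site_id,
                      .data$frame) |>
      dplyr::arrange(.data$tail_id, .data$tail_residue, .data$site_id,
                     .data$frame) |>
      dplyr::mutate(
        new_event = is.na(dplyr::lag(.data$frame)) |
          .data$frame != dplyr::lag(.data$frame) + 1L,
        .by = c("tail_id", "tail_residue", "site_id")) |>
      dplyr::summarise(n_events = sum(.data$new_event),
                       .by = dplyr::all_of(c(grid_by))) |>
      dplyr::mutate(rate = .data$n_events / total_time_ns) |>
      dplyr::select(-"n_events")
  }
  grid <- tidyr::expand_grid(tail_residue = rows, site_id = as.integer(sites))
  if (per_tail) {
    tails <- unique(contacts$tail_id)
    grid <- tidyr::expand_grid(tail_id = tails, grid)
  }
  table <- grid |>
    dplyr::left_join(cells, by = grid_by) |>
    dplyr::mutate(rate = dplyr::coalesce(.data$rate, 0))
  structure(
    list(table = as_tibble(table), n_frames = n_frames,
         condition_tag = condition_tag, estimator = estimator,
         per_tail = per_tail),
    class = "interaction_rate"
  )
}

#' @export
print.interaction_rate <- function(x, ...) {
  cat(sprintf("<interaction_rate> %s | %s | %d frames\n",
              x$condition_tag, x$estimator, x$n_frames))
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.interaction_rate <- function(x, ...) {
  tb <- x$table
  if (x$per_tail) {
    tb <- tb |> dplyr::summarise(rate = mean(.data$rate),
                                 .by = c("tail_residue", "site_id"))
  }
  wide <- tb |>
    dplyr::arrange(.data$tail_residue, .data$site_id) |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "rate",
                       names_prefix = "site_")
  m <- as.matrix(wide[, -1])
  rownames(m) <- paste0("E", wide$tail_residue)
  m
}

#' Per-frame inaccessibility of the tails
#'
#' A tail is inaccessible in a frame if it has at least one salt bridge
#' whose tail residue belongs to the qualifying set (any site). The series
#' is the instantaneous fraction of inaccessible tails per frame; set
#' `cumulative = TRUE` for the ever-bound variant (a tail stays counted
#' after its first qualifying contact).
#'
#' @param contacts Contacts tibble.
#' @param times Frame times in ns (length = total frame count; frames
#'   without contacts count as fully accessible).
#' @param n_tails Number of simulated/analysed tails.
#' @param qset Qualifying residues, see [qualifying_set()].
#' @param condition_tag `"GDP"`, `"GTP"` or `"other"`.
#' @param cumulative Use the cumulative ever-bound definition.
#' @return An `accessibility_series` object wrapping a tibble
#'   (`frame`, `time_ns`, `inaccessible_fraction`).
#' @export
inaccessibility_series <- function(contacts, times, n_tails,
                                   qset = qualifying_set(),
                                   condition_tag = "other",
                                   cumulative = FALSE) {
  n_tails <- as.integer(n_tails)
  if (n_tails < 1L) abort("`n_tails` must be >= 1.")
  nf <- length(times)
  if (nrow(contacts) > 0L && any(contacts$frame >= nf)) {
    abort("Contacts reference frames beyond the supplied time axis.")
  }
  qual <- contacts |>
    dplyr::filter(.data$tail_residue %in% qset) |>
    dplyr::distinct(.data$frame, .data$tail_id)
  if (cumulative) {
    first_bound <- qual |>
      dplyr::summarise(first = min(.data$frame), .by = "tail_id")
    counts <- vapply(seq_len(nf) - 1L,
                     function(f) sum(first_bound$first <= f), integer(1))
  } else {
    tab <- qual |> dplyr::count(.data$frame)
    counts <- integer(nf)
    counts[tab$frame + 1L] <- tab$n
  }
  table <- tibble(frame = seq_len(nf) - 1L, time_ns = times,
                  inaccessible_fraction = counts / n_tails)
  structure(
    list(table = table, n_tails = n_tails, qset = qset,
         smoothing_window = 0L, condition_tag = condition_tag,
         cumulative = cumulative),
    class = "accessibility_series"
  )
}

#' @export
print.accessibility_series <- function(x, ...) {
  cat(sprintf(
    "<accessibility_series> %s | %d frames | %d tails | mean %.3f%s\n",
    x$condition_tag, nrow(x$table), x$n_tails,
    mean(x$table$inaccessible_fraction),
    if (x$smoothing_window > 0) sprintf(" | smoothed w=%d", x$smoothing_window) else ""))
  invisible(x)
}

#' Smooth an accessibility series with a centered running mean
#'
#' Window is the full width in frames; edges use the truncated window.
#' Window 0 returns the series unchanged.
#'
#' @param series An `accessibility_series`.
#' @param window Window width in frames (odd widths are symmetric).
#' @return A smoothed `accessibility_series`.
#' @export
smooth_series <- function(series, window) {
  stopifnot(inherits(series, "accessibility_series"))
  window <- as.integer(window)
  if (window < 0L) abort("`window` must be >= 0.")
  n <- nrow(series$table)
  if (window > n) {
    abort(sprintf("`window` (%d) must not exceed the series length (%d).",
                  window, n))
  }
  if (window == 0L) return(series)
  h <- window %/% 2L
  v <- series$table$inaccessible_fraction
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  series$table$inaccessible_fraction <- sm
  series$smoothing_window <- window
  series
}

#' Aggregate replicate series
#'
#' Combines independent trajectories of one condition: per-replicate
#' curves, a pooled mean defined on the common time support (series are
#' truncated to the shortest replicate; no interpolation), and an
#' unweighted time-averaged scalar per replicate.
#'
#' @param replicates A list of `accessibility_series` sharing a
#'   `condition_tag`.
#' @return A `replicate_summary` list with `per_replicate`, `pooled`
#'   (tibble over the common support) and `scalars` tibbles.
#' @export
aggregate_replicates <- function(replicates) {
  if (length(replicates) < 1L) abort("Need at least one replicate.")
  stopifnot(all(vapply(replicates, inherits, logical(1), "accessibility_series")))
  tags <- unique(vapply(replicates, function(r) r$condition_tag, character(1)))
  if (length(tags) != 1L) {
    abort(paste0("Replicates mix condition tags: ", paste(tags, collapse = ", ")))
  }
  per <- purrr::imap_dfr(replicates, function(r, i) {
    dplyr::mutate(r$table, replicate = i, .before = 1L)
  })
  n_min <- min(vapply(replicates, function(r) nrow(r$table), integer(1)))
  pooled <- per |>
    dplyr::filter(.data$frame < n_min) |>
    dplyr::summarise(
      inaccessible_fraction = mean(.data$inaccessible_fraction),
      time_ns = .data$time_ns[1],
      .by = "frame") |>
    dplyr::select("frame", "time_ns", "inaccessible_fraction")
  scalars <- per |>
    dplyr::summarise(mean_fraction = mean(.data$inaccessible_fraction),
                     n_frames = dplyr::n(), .by = "replicate")
  structure(
    list(condition_tag = tags, per_replicate = per, pooled = pooled,
         scalars = scalars),
    class = "replicate_summary"
  )
}

# CSV writer preserving full double precision for exact round-trips.
write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the analysis report
#'
#' Writes the interaction-rate matrix (rows = tail residues, columns =
#' site_1..site_4), the inaccessibility series (`time_ns`, `fraction`) and
#' a plain-text summary of the run to a directory.
#'
#' @param rate An `interaction_rate` object.
#' @param series An `accessibility_series` object.
#' @param path Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_report <- function(rate, series, path) {
  stopifnot(inherits(rate, "interaction_rate"),
            inherits(series, "accessibility_series"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", path))
  }
  m <- as.matrix(rate)
  mat_df <- data.frame(tail_residue = rownames(m), m, check.names = FALSE)
  f_matrix <- file.path(path, "rate_matrix.csv")
  f_series <- file.path(path, "series.csv")
  f_summary <- file.path(path, "summary.txt")
  write_csv_full(mat_df, f_matrix)
  write_csv_full(
    data.frame(time_ns = series$table$time_ns,
               fraction = series$table$inaccessible_fraction), f_series)
  qn <- paste0("E", series$qset)
  writeLines(c(
    "mtctt analysis summary",
    sprintf("condition: %s", series$condition_tag),
    sprintf("n_frames: %d", nrow(series$table)),
    sprintf("n_tails: %d", series$n_tails),
    sprintf("rate_estimator: %s", rate$estimator),
    sprintf("qualifying_set: {%s}", paste(qn, collapse = ",")),
    sprintf("smoothing_window: %d", series$smoothing_window),
    sprintf("mean_inaccessible_fraction: %.6f",
            mean(series$table$inaccessible_fraction))
  ), f_summary)
  invisible(c(matrix = f_matrix, series = f_series, summary = f_summary))
}
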