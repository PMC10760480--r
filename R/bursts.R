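#' Segment an event table into bursts
#'
#' A burst is a run of openings separated by closed gaps shorter than the
#' critical time `t_c`; any closed gap `>= t_c` (and the record edges)
#' terminates a burst. Burst length runs from the first opening to the end
#' of the last opening of the burst.
#'
#' @param events An `event_table` (alternating open/closed events).
#' @param t_c Critical time in seconds (see [critical_time()]).
#' @return A `burst_table`: tibble with columns `burst` (index), `start`
#'   (s), `length` (s), `n_openings`, `open_time` (s), plus attribute `t_c`.
#' @export
segment_bursts <- function(events, t_c) {
  stopifnot(is.data.frame(events), t_c > 0)
  op <- which(events$class == "open")
  if (length(op) == 0) {
    out <- tibble::tibble(burst = integer(), start = numeric(),
                          length = numeric(), n_openings = integer(),
                          open_time = numeric())
    attr(out, "t_c") <- t_c
    class(out) <- c("burst_table", class(out))
    return(out)
  }
  # gap between consecutive openings = the closed time separating them
  gap_start <- events$start[op[-length(op)]] + events$duration[op[-length(op)]]
  gap <- events$start[op[-1]] - gap_start
  new_burst <- c(TRUE, gap >= t_c)
  id <- cumsum(new_burst)
  open_start <- events$start[op]
  open_end <- open_start + events$duration[op]
  out <- tibble::tibble(open_start, open_end, dur = events$duration[op], id) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      start = min(.data$open_start),
      length = max(.data$open_end) - min(.data$open_start),
      n_openings = dplyr::n(),
      open_time = sum(.data$dur),
      .groups = "drop"
    ) |>
    dplyr::rename(burst = "id")
  attr(out, "t_c") <- t_c
  class(out) <- c("burst_table", class(out))
  out
}
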