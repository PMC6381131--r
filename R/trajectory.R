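#' Cell trajectory
#'
#' One cell's time-ordered positions in physical units — the atom of all
#' migration statistics.
#'
#' @param track_id integer id.
#' @param t_min numeric vector of times in minutes, strictly increasing.
#' @param x_um,y_um positions in micrometres (mathematical convention,
#'   y up), same length as `t_min`.
#' @return a data.frame of class `"trajectory"` with columns
#'   `track_id, t_min, x_um, y_um`.
#' @export
trajectory <- function(track_id, t_min, x_um, y_um) {
  n <- length(t_min)
  if (length(x_um) != n || length(y_um) != n)
    stop("t_min, x_um, y_um must have equal length", call. = FALSE)
  stop_if_not_finite(t_min, "t_min")
  stop_if_not_finite(x_um, "x_um")
  stop_if_not_finite(y_um, "y_um")
  if (n >= 2 && any(diff(t_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(
    data.frame(track_id = as.integer(track_id), t_min = t_min,
               x_um = x_um, y_um = y_um),
    class = c("trajectory", "data.frame")
  )
}

#' Bind trajectories into one long table
#' @param tracks list of [trajectory()] objects.
#' @return data.frame with columns `track_id, frame, t_min, x_um, y_um`.
#' @export
tracks_to_df <- function(tracks) {
  stopifnot(is.list(tracks))
  out <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = seq_len(nrow(tr)) - 1L,
               t_min = tr$t_min, x_um = tr$x_um, y_um = tr$y_um)
  }))
  rownames(out) <- NULL
  out
}

#' Split a long track table into trajectory objects
#' @param df data.frame with columns `track_id, t_min, x_um, y_um`.
#' @return list of [trajectory()] objects, ordered by track_id.
#' @export
df_to_tracks <- function(df) {
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(df$track_id))
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$t_min), , drop = FALSE]
    trajectory(id, sub$t_min, sub$x_um, sub$y_um)
  })
}

#' Write / read a tracks CSV (track_id, frame, t_min, x_um, y_um)
#' @param tracks list of trajectories.
#' @param path file path.
#' @return `read_tracks_csv` returns a list of trajectories.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks_to_df(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df_to_tracks(utils::read.csv(path))
}
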