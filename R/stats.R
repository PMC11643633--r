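## Trajectory directionality statistics for 2D cell tracks.
##
## A track is an ordered polyline (t_i, x_i, y_i) in minutes and micrometres
## (or consistent simulation units). The up-gradient direction is +y
## throughout. Conventions:
##   yFMI        = (y_end - y_start) / total path length, in [-1, 1]
##   persistence = |r_end - r_start| / total path length, in [0, 1]
##   velocity    = total path length / elapsed time
##   angular displacement = angle of r_end - r_start measured from +y,
##                          clockwise positive, in (-180, 180] degrees.
## |yFMI| <= persistence always (triangle inequality), with equality only for
## motion along the +-y axis.

asTrackMatrix <- function(track) {
  if (is.data.frame(track)) {
    stopifnot(all(c("t", "x", "y") %in% names(track)))
    track <- as.matrix(track[, c("t", "x", "y")])
  }
  stopifnot(is.matrix(track), ncol(track) == 3)
  dimnames(track) <- NULL
  if (nrow(track) < 2) stop("a track needs at least 2 points")
  if (any(diff(track[, 1]) <= 0)) stop("track times must be strictly increasing")
  if (!all(is.finite(track))) stop("track contains non-finite values")
  track
}

pathLength <- function(tm) {
  sum(sqrt(diff(tm[, 2])^2 + diff(tm[, 3])^2))
}

#' Forward migration index along the gradient (yFMI)
#'
#' Net displacement along the up-gradient (+y) axis divided by the total
#' path length the cell travelled.
#'
#' @param track data.frame with columns `t`, `x`, `y` (or a 3-column matrix).
#' @return scalar in `[-1, 1]`; `NA` for a zero-length path.
#' @export
trackYfmi <- function(track) {
  tm <- asTrackMatrix(track)
  L <- pathLength(tm)
  if (!(L > 0)) return(NA_real_)
  (tm[nrow(tm), 3] - tm[1, 3]) / L
}

#' Migration persistence (directionality ratio)
#'
#' Net displacement magnitude divided by total path length.
#'
#' @inheritParams trackYfmi
#' @return scalar in `[0, 1]`; `NA` for a zero-length path.
#' @export
trackPersistence <- function(track) {
  tm <- asTrackMatrix(track)
  L <- pathLength(tm)
  if (!(L > 0)) return(NA_real_)
  n <- nrow(tm)
  sqrt((tm[n, 2] - tm[1, 2])^2 + (tm[n, 3] - tm[1, 3])^2) / L
}

#' Mean migration velocity
#'
#' Total path length divided by elapsed time (path-based speed, decoupled
#' from directionality).
#'
#' @inheritParams trackYfmi
#' @return scalar speed (length unit per time unit).
#' @export
trackVelocity <- function(track) {
  tm <- asTrackMatrix(track)
  dt <- tm[nrow(tm), 1] - tm[1, 1]
  if (!(dt > 0)) stop("track has zero duration")
  pathLength(tm) / dt
}

#' Angular displacement
#'
#' Angle of the net displacement vector measured from the up-gradient +y
#' axis, clockwise positive, in `(-180, 180]` degrees: 0 is straight
#' up-gradient, 90 is +x, 180 is straight down-gradient.
#'
#' @inheritParams trackYfmi
#' @return angle in degrees; `NA` for zero net displacement.
#' @export
trackAngularDisplacement <- function(track) {
  tm <- asTrackMatrix(track)
  n <- nrow(tm)
  dx <- tm[n, 2] - tm[1, 2]; dy <- tm[n, 3] - tm[1, 3]
  if (dx == 0 && dy == 0) return(NA_real_)
  ang <- atan2(dx, dy) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Per-track and ensemble migration statistics
#'
#' Computes yFMI, velocity, persistence and angular displacement for every
#' track in a pooled track table and summarises the ensemble (mean, SEM, n).
#' Tracks with fewer than 2 points or zero path length are excluded and
#' counted, not errored.
#'
#' @param tracks data.frame with columns `track_id`, `t`, `x`, `y`.
#' @return list of class `dg_migration_stats` with `per_track` (data.frame),
#'   `ensemble` (data.frame of mean/SEM/n per statistic) and `n_excluded`.
#' @export
summarizeTracks <- function(tracks) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  ids <- unique(tracks$track_id)
  if (length(ids) < 1) stop("no tracks supplied")
  rows <- list(); excluded <- 0
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, c("t", "x", "y")]
    if (nrow(tr) < 2 || !(pathLength(asTrackMatrixSafe(tr)) > 0)) {
      excluded <- excluded + 1
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      track_id = id,
      yfmi = trackYfmi(tr),
      velocity = trackVelocity(tr),
      persistence = trackPersistence(tr),
      angular_displacement = trackAngularDisplacement(tr))
  }
  if (!length(rows)) stop("all tracks were degenerate")
  per <- do.call(rbind, rows)
  ens <- do.call(rbind, lapply(c("yfmi", "velocity", "persistence",
                                 "angular_displacement"), function(stat) {
    v <- per[[stat]]
    v <- v[is.finite(v)]
    data.frame(stat = stat, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  structure(list(per_track = per, ensemble = ens, n_excluded = excluded),
            class = "dg_migration_stats")
}

asTrackMatrixSafe <- function(tr) {
  tm <- as.matrix(tr[, c("t", "x", "y")])
  tm
}

#' @export
print.dg_migration_stats <- function(x, ...) {
  cat(sprintf("migration statistics over %d tracks (%d excluded)\n",
              length(unique(x$per_track$track_id)), x$n_excluded))
  print(x$ensemble, row.names = FALSE)
  invisible(x)
}

#' Rose-plot bin counts of angular displacements
#'
#' @param angles vector of angular displacements in degrees, `(-180, 180]`.
#' @param bin_width bin width in degrees (must divide 360).
#' @return data.frame with `bin_start_deg`, `bin_end_deg`, `count`.
#' @export
roseBins <- function(angles, bin_width = 20) {
  stopifnot(360 %% bin_width == 0)
  angles <- angles[is.finite(angles)]
  breaks <- seq(-180, 180, by = bin_width)
  # shift (-180, 180] onto the bin lattice
  idx <- findInterval(angles, breaks, left.open = TRUE, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_start_deg = breaks[-length(breaks)],
             bin_end_deg = breaks[-1], count = counts)
}

#' Read / write the shared track CSV dialect
#'
#' Columns `track_id`, `t`, `x`, `y`; comment lines (`#`) may carry units.
#'
#' @param path CSV file path.
#' @return `readTracks`: data.frame of tracks.
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(df)))
  df
}

#' @rdname readTracks
#' @param tracks data.frame with columns `track_id`, `t`, `x`, `y`.
#' @param units optional comment string recorded in the header.
#' @export
writeTracks <- function(tracks, path, units = "t in min, x/y in um") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", units), con)
  utils::write.csv(tracks[, c("track_id", "t", "x", "y")], con,
                   row.names = FALSE)
  invisible(path)
}
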