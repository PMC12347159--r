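# circular moving mean with window in degrees (odd number of samples)
circ_smooth <- function(v, theta, window_deg = 11) {
  step <- theta[2] - theta[1]
  half <- max(0L, floor(window_deg / step / 2))
  if (half == 0) return(v)
  n <- length(v)
  idx <- outer(seq_len(n), -half:half, `+`)
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(v[idx], nrow = n))
}

#' Detect peaks and troughs of a circular density profile
#'
#' Local maxima and minima of the periodically smoothed profile (circular
#' moving mean, default window 11 degrees), honoring wrap-around.
#' Alternation around the circle is enforced by discarding the lesser of two
#' adjacent same-type extrema. Profiles whose angular coefficient of
#' variation is below 1% carry no reliable angular structure and yield an
#' explicit flat result.
#'
#' @param profile A `circular_profile` with at least 90 angular samples.
#' @param smooth_window Smoothing window (degrees), default 11.
#' @return List with `flat` (logical), `peaks`, `troughs` (positions,
#'   degrees), `theta`, `smoothed` (the smoothed profile used).
#' @export
detect_peaks_troughs <- function(profile, smooth_window = 11) {
  stopifnot(inherits(profile, "circular_profile"))
  if (length(profile$theta) < 90)
    stop("at least 90 angular samples are required")
  v <- circ_smooth(profile$density, profile$theta, smooth_window)
  th <- profile$theta
  if (stats::sd(v) / mean(v) < 0.01)
    return(list(flat = TRUE, peaks = numeric(0), troughs = numeric(0),
                theta = th, smoothed = v))
  n <- length(v)
  d <- v[c(2:n, 1)] - v            # forward circular difference
  s <- sign(d)
  # carry the previous nonzero sign through plateaus
  nz <- which(s != 0)
  if (!length(nz)) return(list(flat = TRUE, peaks = numeric(0),
                               troughs = numeric(0), theta = th, smoothed = v))
  filled <- s
  last <- s[nz[length(nz)]]
  for (i in seq_len(n)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  prev <- filled[c(n, 1:(n - 1))]
  peaks <- which(prev > 0 & filled < 0)
  troughs <- which(prev < 0 & filled > 0)
  # enforce alternation: walk extrema in angular order, merge same-type runs
  ext <- rbind(data.frame(i = peaks, type = "peak"),
               data.frame(i = troughs, type = "trough"))
  ext <- ext[order(ext$i), ]
  if (nrow(ext) >= 2) {
    repeat {
      types <- ext$type
      nxt <- c(2:nrow(ext), 1)
      same <- which(types == types[nxt] & seq_len(nrow(ext)) != nxt)
      if (!length(same) || nrow(ext) <= 1) break
      j <- same[1]; k <- nxt[j]
      vi <- v[ext$i[j]]; vk <- v[ext$i[k]]
      drop <- if (types[j] == "peak") { if (vi >= vk) k else j
      } else { if (vi <= vk) k else j }
      ext <- ext[-drop, , drop = FALSE]
    }
  }
  list(flat = FALSE,
       peaks = th[ext$i[ext$type == "peak"]],
       troughs = th[ext$i[ext$type == "trough"]],
       theta = th, smoothed = v)
}

#' Half-height angular widths of peaks and troughs
#'
#' For each flank between a peak and its adjacent trough, the half-height
#' crossing is the angle where the smoothed density equals the mean of the
#' peak and trough values (linear interpolation between samples). A peak's
#' width spans its two flank crossings; likewise for troughs; widths tile
#' the circle (sum 360 degrees).
#'
#' @param extrema Result of [detect_peaks_troughs()] (non-flat, alternating).
#' @return List with `peak_widths`, `trough_widths` (degrees, in the order
#'   of `extrema$peaks` / `extrema$troughs`).
#' @export
half_height_widths <- function(extrema) {
  if (isTRUE(extrema$flat)) stop("flat profile has no extrema")
  np <- length(extrema$peaks); nt <- length(extrema$troughs)
  if (np < 1 || nt < 1 || np != nt)
    stop("extrema must alternate (equal numbers of peaks and troughs)")
  th <- extrema$theta; v <- extrema$smoothed
  n <- length(th); step <- th[2] - th[1]
  pos <- c(extrema$peaks, extrema$troughs)
  type <- rep(c("peak", "trough"), c(np, nt))
  o <- order(pos)
  pos <- pos[o]; type <- type[o]
  m <- length(pos)
  val_at <- function(p) v[which.min(ang_diff(th, p))]
  # crossing on the arc from extremum i to extremum i+1 (circular)
  crossings <- numeric(m)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    half <- (val_at(pos[i]) + val_at(pos[j])) / 2
    arc_len <- (pos[j] - pos[i]) %% 360
    k_seq <- seq(0, arc_len, by = step)
    ang <- (pos[i] + k_seq) %% 360
    idx <- round(ang / step) %% n + 1
    vv <- v[idx]
    sgn <- sign(vv - half)
    chg <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-1] != sgn[-length(sgn)])
    if (!length(chg)) {
      crossings[i] <- (pos[i] + arc_len / 2) %% 360
    } else {
      a <- chg[1]
      v1 <- vv[a]; v2 <- vv[a + 1]
      frac <- if (v2 == v1) 0.5 else (half - v1) / (v2 - v1)
      crossings[i] <- (pos[i] + k_seq[a] + frac * step) %% 360
    }
  }
  # width of extremum i spans crossing[i-1] .. crossing[i]
  widths <- numeric(m)
  for (i in seq_len(m)) {
    prev <- if (i == 1) m else i - 1
    widths[i] <- (crossings[i] - crossings[prev]) %% 360
  }
  list(peak_widths = widths[type == "peak"][order(order(extrema$peaks))],
       trough_widths = widths[type == "trough"][order(order(extrema$troughs))])
}

#' Rugosity: combined trough/peak width ratio
#'
#' The rugosity of a circular density profile is the sum of its trough
#' half-height widths divided by the sum of its peak half-height widths. A
#' value above one indicates a horizontal ridge of elevated density (wide
#' troughs above and below, narrow peaks left and right).
#'
#' @param widths Result of [half_height_widths()].
#' @return Rugosity (unitless, `> 0`).
#' @export
rugosity <- function(widths) {
  if (!length(widths$peak_widths) || !length(widths$trough_widths))
    stop("rugosity requires at least one peak and one trough")
  sum(widths$trough_widths) / sum(widths$peak_widths)
}

#' Rugosity analysis of a density map across eccentricities
#'
#' Extracts D0-normalized circular profiles at the requested eccentricities,
#' detects peaks and troughs, and computes half-height widths and the
#' rugosity ratio per eccentricity.
#'
#' @param map A `density_map`.
#' @param cdc CDC location `(x, y)` in um.
#' @param d0 Central density used for normalization (cones/mm^2).
#' @param eccentricities Circle radii (um); default
#'   `c(15, 40, 65, 90, 115, 140, 165, 190, 215, 240)`.
#' @param angular_step Angular sampling step (degrees), default 1.
#' @return A data frame with one row per eccentricity: `eccentricity`,
#'   `flat`, `n_peaks`, `rugosity`, and JSON-encoded `peaks`, `troughs`,
#'   `peak_widths`, `trough_widths`.
#' @export
analyze_rugosity <- function(map, cdc, d0,
                             eccentricities = c(15, 40, 65, 90, 115, 140,
                                                165, 190, 215, 240),
                             angular_step = 1) {
  rows <- lapply(eccentricities, function(ecc) {
    cp <- circular_profile(map, cdc, ecc, angular_step)
    cp$density <- cp$density / d0
    cp$normalized <- TRUE
    ex <- detect_peaks_troughs(cp)
    if (ex$flat)
      return(data.frame(eccentricity = ecc, flat = TRUE, n_peaks = 0L,
                        rugosity = NA_real_, peaks = "[]", troughs = "[]",
                        peak_widths = "[]", trough_widths = "[]"))
    w <- half_height_widths(ex)
    data.frame(eccentricity = ecc, flat = FALSE,
               n_peaks = length(ex$peaks),
               rugosity = rugosity(w),
               peaks = as.character(jsonlite::toJSON(ex$peaks, digits = NA)),
               troughs = as.character(jsonlite::toJSON(ex$troughs, digits = NA)),
               peak_widths = as.character(jsonlite::toJSON(w$peak_widths, digits = NA)),
               trough_widths = as.character(jsonlite::toJSON(w$trough_widths, digits = NA)))
  })
  do.call(rbind, rows)
}
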