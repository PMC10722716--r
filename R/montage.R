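#' Standard 19-channel 10-20 montage on the unit sphere
#'
#' Builds the International 10-20 electrode set (Fp1, Fp2, F3, F4, C3, C4, P3,
#' P4, O1, O2, F7, F8, T3, T4, T5, T6, Fz, Cz, Pz) at ideal angular placements
#' on a unit sphere. The coordinate frame is head-centred: +x toward the right
#' ear, +y toward the nasion, +z toward the vertex. Nasion, inion and the
#' preauricular points sit on the equator; midline and ear-to-ear arcs are
#' divided in the canonical 10/20 percent steps, and F3/F4, P3/P4 are geodesic
#' midpoints of their neighbouring 10-20 sites, which is the ideal-sphere
#' construction for those positions.
#'
#' @param reference Reference label carried with the montage. The default
#'   "linked-ear" matches a recording referenced to the ears; "common-average"
#'   is produced by [rereference()].
#' @return An object of class `eeg_montage`: list with `channel_names`
#'   (character, length 19), `positions` (19 x 3 matrix of unit vectors, rows
#'   named by channel) and `reference`.
#' @examples
#' m <- montage_1020()
#' nrow(m$positions)  # 19
#' @export
montage_1020 <- function(reference = "linked-ear") {
  deg <- pi / 180
  # (inclination from vertex, azimuth from nasion direction; +azimuth = left)
  sph <- function(incl, azim, left = NA) {
    th <- incl * deg; ph <- azim * deg
    # azimuth measured from +y (nasion), positive toward left (-x)
    c(x = -sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
  }
  pos <- list(
    Fz  = sph(36, 0),    Cz = sph(0, 0),     Pz = sph(36, 180),
    C3  = sph(36, 90),   C4 = sph(36, -90),
    Fp1 = sph(72, 18),   Fp2 = sph(72, -18),
    F7  = sph(72, 54),   F8 = sph(72, -54),
    T3  = sph(72, 90),   T4 = sph(72, -90),
    T5  = sph(72, 126),  T6 = sph(72, -126),
    O1  = sph(72, 162),  O2 = sph(72, -162)
  )
  mid <- function(a, b) { v <- (pos[[a]] + pos[[b]]) / 2; v / sqrt(sum(v^2)) }
  pos$F3 <- mid("Fz", "F7"); pos$F4 <- mid("Fz", "F8")
  pos$P3 <- mid("Pz", "T5"); pos$P4 <- mid("Pz", "T6")
  names_1020 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                  "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                  "Fz", "Cz", "Pz")
  P <- do.call(rbind, pos[names_1020])
  rownames(P) <- names_1020
  colnames(P) <- c("x", "y", "z")
  structure(list(channel_names = names_1020, positions = P,
                 reference = reference),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_names), " channels, reference: ",
      x$reference, "\n", sep = "")
  invisible(x)
}

#' EEG recording container
#'
#' Multichannel EEG as a channels x samples matrix in microvolts, with its
#' sampling rate and montage.
#'
#' @param data Numeric matrix, channels x samples (uV). Row count must match
#'   the montage.
#' @param rate Sampling rate in samples/s (default 500).
#' @param montage An `eeg_montage`.
#' @param events Optional data.frame of events with columns `time_s` and
#'   `label` (used for cue-locked segmentation).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate = 500, montage = montage_1020(),
                          events = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(montage$channel_names))
    stop("data has ", nrow(data), " rows but the montage defines ",
         length(montage$channel_names), " channels")
  if (!all(is.finite(data))) stop("EEG data must be finite")
  rownames(data) <- montage$channel_names
  structure(list(data = data, rate = rate, montage = montage,
                 duration_s = ncol(data) / rate, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$rate, " Hz (", round(x$duration_s, 2), " s)\n", sep = "")
  invisible(x)
}
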