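# Rotational-state analysis of a two-helix transmembrane dimer: the
# azimuth of a designated sensor residue around each helix axis, measured
# toward the partner helix, classifies each frame as facing-facing, mixed,
# or away-away; state populations carry percentile-bootstrap CIs.

#' Principal axis of a helix backbone
#'
#' Fits the principal axis through an ordered backbone point set by SVD and
#' orients it N-terminus to C-terminus.
#'
#' @param backbone ordered n x 3 coordinate matrix, n >= 4.
#' @return list with unit \code{axis} and \code{centroid}.
#' @export
helix_axis <- function(backbone) {
  stop_if(!is.matrix(backbone) || ncol(backbone) != 3 || nrow(backbone) < 4,
          "backbone must be an n x 3 matrix with n >= 4")
  ctr <- colMeans(backbone)
  x <- sweep(backbone, 2, ctr)
  a <- svd(x, nu = 0, nv = 1)$v[, 1]
  span <- backbone[nrow(backbone), ] - backbone[1, ]
  if (sum(a * span) < 0) a <- -a
  list(axis = a, centroid = ctr)
}

#' Azimuth of the sensor residue toward the partner helix
#'
#' Projects the sensor residue's position onto the plane normal to its
#' helix axis and measures the signed angle between that radial vector and
#' the inter-axis connector pointing toward the partner helix: 0 degrees
#' means the sensor points straight at the partner, 180 degrees straight
#' away.
#'
#' @param frame list with CA coordinate matrices \code{A} and \code{B}.
#' @param protomer 1 (helix A) or 2 (helix B).
#' @param sensor_index residue index of the sensor side chain.
#' @return azimuth in degrees, in (-180, 180].
#' @export
sensor_azimuth <- function(frame, protomer, sensor_index) {
  .azimuth_one(frame, protomer, sensor_index,
               helix_axis(frame$A), helix_axis(frame$B))
}

.azimuth_one <- function(frame, protomer, sensor_index, ax_a, ax_b) {
  this <- if (protomer == 1) frame$A else frame$B
  ax <- if (protomer == 1) ax_a else ax_b
  ax_o <- if (protomer == 1) ax_b else ax_a
  stop_if(sensor_index < 1 || sensor_index > nrow(this),
          "sensor_index out of range")
  conn <- ax_o$centroid - ax$centroid
  conn_perp <- conn - sum(conn * ax$axis) * ax$axis
  stop_if(sqrt(sum(conn_perp^2)) < 1e-9,
          "helix axes coincide; azimuth undefined")
  u <- conn_perp / sqrt(sum(conn_perp^2))
  p <- this[sensor_index, ]
  r <- p - (ax$centroid + sum((p - ax$centroid) * ax$axis) * ax$axis)
  stop_if(sqrt(sum(r^2)) < 1e-9, "sensor residue lies on the helix axis")
  r <- r / sqrt(sum(r^2))
  cross <- c(u[2] * r[3] - u[3] * r[2],
             u[3] * r[1] - u[1] * r[3],
             u[1] * r[2] - u[2] * r[1])
  ang <- atan2(sum(cross * ax$axis), sum(u * r)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify the dimer rotational state from two sensor azimuths
#'
#' Both sensors within \code{facing_threshold} of 0 degrees: the residues
#' face each other across the dimer interface (\code{facing-facing}). Both
#' beyond 180 - threshold: they point away from each other
#' (\code{away-away}). Anything else, including both pointing the same lab
#' direction, is \code{mixed}.
#'
#' @param phi1,phi2 azimuths in degrees (vectorized).
#' @param facing_threshold half-width of the facing sector, degrees.
#' @return character vector of state labels.
#' @export
classify_state <- function(phi1, phi2, facing_threshold = 60) {
  a1 <- abs(phi1); a2 <- abs(phi2)
  out <- rep("mixed", length(a1))
  out[a1 < facing_threshold & a2 < facing_threshold] <- "facing-facing"
  out[a1 > 180 - facing_threshold & a2 > 180 - facing_threshold] <- "away-away"
  out
}

rotamer_states <- c("facing-facing", "mixed", "away-away")

#' Per-frame rotational-state series of a dimer trajectory
#'
#' Computes both sensor azimuths for every frame, flags frames whose helix
#' axes cross at more than \code{max_crossing_angle} (the azimuth
#' definition degrades for strongly non-parallel helices; such frames get
#' state \code{NA}), and classifies the rest.
#'
#' @param dtraj a \code{dimer_trajectory}.
#' @param facing_threshold see \code{\link{classify_state}}.
#' @param max_crossing_angle flag frames with larger inter-axis angle
#'   (degrees).
#' @return a \code{rotamer_state_series} data frame with \code{frame},
#'   \code{phi1}, \code{phi2}, \code{state}, \code{flagged}.
#' @export
analyze_dimer <- function(dtraj, facing_threshold = 60,
                          max_crossing_angle = 45) {
  stopifnot(inherits(dtraj, "dimer_trajectory"))
  n <- length(dtraj$frames)
  phi1 <- phi2 <- cross <- numeric(n)
  for (f in seq_len(n)) {
    fr <- dtraj$frames[[f]]
    ax_a <- helix_axis(fr$A); ax_b <- helix_axis(fr$B)
    phi1[f] <- .azimuth_one(fr, 1, dtraj$sensor_index, ax_a, ax_b)
    phi2[f] <- .azimuth_one(fr, 2, dtraj$sensor_index, ax_a, ax_b)
    ca <- abs(sum(ax_a$axis * ax_b$axis))
    cross[f] <- acos(pmin(1, ca)) * 180 / pi
  }
  flagged <- cross > max_crossing_angle
  state <- classify_state(phi1, phi2, facing_threshold)
  state[flagged] <- NA_character_
  out <- data.frame(frame = seq_len(n), phi1 = phi1, phi2 = phi2,
                    state = state, flagged = flagged)
  class(out) <- c("rotamer_state_series", "data.frame")
  out
}

#' Rotational-state populations with bootstrap confidence intervals
#'
#' Empirical fraction of unflagged frames in each of the three states,
#' with a percentile bootstrap CI over frames.
#'
#' @param series a \code{rotamer_state_series} (or any data frame with a
#'   \code{state} column).
#' @param n_boot bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling.
#' @param conf confidence level.
#' @return data frame with \code{state}, \code{fraction}, \code{ci_lo},
#'   \code{ci_hi}; fractions sum to 1.
#' @export
state_populations <- function(series, n_boot = 1000, seed = 1L,
                              conf = 0.95) {
  stop_if(n_boot < 1, "n_boot must be >= 1")
  st <- series$state[!is.na(series$state)]
  stop_if(length(st) == 0, "no classified frames")
  frac <- vapply(rotamer_states, function(s) mean(st == s), numeric(1))
  boots <- with_seed(seed, {
    replicate(n_boot, {
      r <- st[sample.int(length(st), replace = TRUE)]
      vapply(rotamer_states, function(s) mean(r == s), numeric(1))
    })
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  data.frame(state = rotamer_states, fraction = unname(frac),
             ci_lo = unname(ci[1, ]), ci_hi = unname(ci[2, ]),
             row.names = NULL)
}
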