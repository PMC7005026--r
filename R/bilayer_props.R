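# Standard per-composition bilayer descriptors: area per lipid, membrane
# thickness from the headgroup reference planes, and acyl-chain order
# parameters S = <(3 cos^2 theta - 1)/2> against the bilayer normal (+z).

#' Area per lipid
#'
#' Lateral box area divided by the number of lipids per leaflet, averaged
#' over frames. If the leaflets hold unequal lipid counts, per-leaflet
#' values are returned instead of a single number.
#'
#' @param traj a \code{bilayer_trajectory}.
#' @return list with \code{mean} and \code{sd} in Angstrom^2 (per-leaflet
#'   named vectors when the leaflets differ).
#' @export
area_per_lipid <- function(traj) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  n_up <- length(unique(traj$atoms$lipid_id[traj$atoms$leaflet == "upper"]))
  n_lo <- length(unique(traj$atoms$lipid_id[traj$atoms$leaflet == "lower"]))
  stop_if(n_up == 0 || n_lo == 0, "a leaflet contains no lipids")
  area <- traj$box[1] * traj$box[2]
  per_frame <- rep(area, traj$n_frames)   # box is constant per trajectory
  if (n_up == n_lo) {
    apl <- per_frame / n_up
    list(mean = mean(apl), sd = stats::sd(apl))
  } else {
    list(mean = c(upper = mean(per_frame / n_up),
                  lower = mean(per_frame / n_lo)),
         sd = c(upper = stats::sd(per_frame / n_up),
                lower = stats::sd(per_frame / n_lo)))
  }
}

#' Membrane thickness
#'
#' Frame-averaged distance between the mean z of the reference atoms
#' (phosphate-analog headgroup plane by default) of the upper and lower
#' leaflets.
#'
#' @param traj a \code{bilayer_trajectory}.
#' @param reference_role atom role defining the reference planes.
#' @return list with \code{mean} and \code{sd} in Angstrom.
#' @export
thickness <- function(traj, reference_role = "headgroup") {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  up <- traj$atoms$role == reference_role & traj$atoms$leaflet == "upper"
  lo <- traj$atoms$role == reference_role & traj$atoms$leaflet == "lower"
  stop_if(!any(up) || !any(lo),
          paste0("both leaflets need atoms with role '", reference_role, "'"))
  th <- vapply(traj$frames,
               function(p) mean(p[up, 3]) - mean(p[lo, 3]), numeric(1))
  list(mean = mean(th), sd = stats::sd(th))
}

#' Acyl-chain order parameters
#'
#' Per segment index, \eqn{S = \langle (3\cos^2\theta - 1)/2 \rangle} with
#' theta the angle between a chain vector and the bilayer normal (+z after
#' centering). The \code{segment} convention takes the vector from segment
#' i-1 to segment i+1 (standard for reduced chain representations without
#' hydrogens); the \code{bond} convention takes segment i to i+1. S is
#' averaged over chains and lipids within each frame; the SEM is taken over
#' frame means. Zero-length vectors are skipped and counted in the
#' \code{n_degenerate} attribute with a warning.
#'
#' @param traj a \code{bilayer_trajectory}.
#' @param vector_convention \code{"segment"} or \code{"bond"}.
#' @return data frame (class \code{order_profile}) with \code{segment},
#'   \code{S} and \code{sem}; S is bounded in [-0.5, 1].
#' @export
order_parameters <- function(traj, vector_convention = c("segment", "bond")) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  vector_convention <- match.arg(vector_convention)
  at <- traj$atoms
  is_chain <- at$role == "chain"
  stop_if(!any(is_chain), "trajectory has no chain atoms")
  nseg <- max(at$segment[is_chain])
  stop_if(vector_convention == "segment" && nseg < 3,
          "segment convention needs chains with >= 3 segments")
  # atoms are emitted per chain in segment order; recover chain runs
  key <- paste(at$lipid_id, at$leaflet, at$chain, sep = "/")[is_chain]
  idx_chain <- which(is_chain)
  ord <- order(key, at$segment[is_chain])
  idx_sorted <- idx_chain[ord]
  key_sorted <- key[ord]
  runs <- split(idx_sorted, key_sorted)

  mids <- if (vector_convention == "segment") 2:(nseg - 1) else 1:(nseg - 1)
  n_degenerate <- 0L
  per_frame <- matrix(NA_real_, nrow = traj$n_frames, ncol = length(mids))
  for (f in seq_len(traj$n_frames)) {
    p <- traj$frames[[f]]
    acc <- numeric(length(mids)); cnt <- integer(length(mids))
    for (run in runs) {
      q <- p[run, , drop = FALSE]
      v <- if (vector_convention == "segment")
        q[3:nrow(q), , drop = FALSE] - q[1:(nrow(q) - 2), , drop = FALSE]
      else q[2:nrow(q), , drop = FALSE] - q[1:(nrow(q) - 1), , drop = FALSE]
      len <- sqrt(rowSums(v^2))
      ok <- len > 1e-12
      n_degenerate <- n_degenerate + sum(!ok)
      cth2 <- (v[, 3] / len)^2
      s <- (3 * cth2 - 1) / 2
      acc[ok] <- acc[ok] + s[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    per_frame[f, ] <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " degenerate zero-length chain vectors skipped")
  S <- colMeans(per_frame, na.rm = TRUE)
  sem <- apply(per_frame, 2, stats::sd, na.rm = TRUE) /
    sqrt(colSums(!is.na(per_frame)))
  out <- data.frame(segment = mids, S = S, sem = sem)
  attr(out, "n_degenerate") <- n_degenerate
  attr(out, "vector_convention") <- vector_convention
  class(out) <- c("order_profile", "data.frame")
  out
}
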