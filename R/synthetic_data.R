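# Seeded generators for every input the pipeline consumes: bilayer atom
# clouds, TMH-dimer trajectories, emission spectra, FCS autocorrelation
# curves and first-derivative cwEPR spectra. Each generator exposes the
# ground-truth parameters so downstream estimators can be tested against
# known truth. No force fields, no integrators: chains are jointed segment
# sticks whose depth distribution responds to kink parameters the way
# cis/trans/saturated acyl chains shape the packing profile.

# fixed internal geometry (Angstrom): phosphate-analog headgroup plane,
# chain anchor depth and per-segment rise of an extended acyl chain
.bilayer_geom <- list(
  z_head     = 18.5,  # first headgroup atom (reference plane for thickness)
  z_glycerol = 17.2,
  z_chain0   = 16.0,  # first chain segment
  rise       = 1.27   # z-drop per segment of an extended (all-trans) chain
)

#' Specification for a synthetic bilayer
#'
#' Describes a two-leaflet bilayer of jointed-stick lipids: each lipid has a
#' stack of headgroup pseudo-atoms, one glycerol atom, and
#' \code{chains_per_lipid} acyl chains of \code{chain_segments} pseudo-atoms
#' descending toward the midplane with a 1.27 Angstrom rise per segment. A
#' "kinked" chain (cis-double-bond analog) bends by \code{kink_angle} at
#' \code{kink_position}, so its tail descends more slowly and places fewer
#' segments in the deep 3--10 Angstrom band than a straight chain
#' (saturated / trans analog) does. A smaller
#' \code{headgroup_atom_count} together with a reduced \code{area_per_lipid}
#' emulates a PE-for-PC headgroup swap.
#'
#' @param lipids_per_leaflet number of lipids in each leaflet.
#' @param area_per_lipid lateral area per lipid in Angstrom^2.
#' @param chain_segments pseudo-atoms per acyl chain.
#' @param chains_per_lipid acyl chains per lipid.
#' @param fraction_kinked_chains fraction of all chains carrying a kink, in
#'   [0, 1].
#' @param kink_position segment index at which a kinked chain bends
#'   (Delta-6 vs Delta-9 analog).
#' @param kink_angle bend in degrees from the membrane normal after the
#'   kink; large for a cis analog, small for a trans analog.
#' @param headgroup_atom_count pseudo-atoms in the headgroup stack
#'   (PC-analog larger than PE-analog).
#' @param thermal_noise_sd per-frame isotropic positional noise, Angstrom.
#' @param seed integer seed making the generator reproducible.
#' @return an object of class \code{bilayer_gen_spec}.
#' @export
bilayer_gen_spec <- function(lipids_per_leaflet,
                             area_per_lipid = 64,
                             chain_segments = 12,
                             chains_per_lipid = 2,
                             fraction_kinked_chains = 0,
                             kink_position = 4,
                             kink_angle = 70,
                             headgroup_atom_count = 8,
                             thermal_noise_sd = 0.5,
                             seed = 1L) {
  stop_if(lipids_per_leaflet < 1, "lipids_per_leaflet must be >= 1")
  stop_if(area_per_lipid <= 0, "area_per_lipid must be > 0")
  stop_if(chain_segments < 3, "chain_segments must be >= 3")
  stop_if(chains_per_lipid < 1, "chains_per_lipid must be >= 1")
  stop_if(fraction_kinked_chains < 0 || fraction_kinked_chains > 1,
          "fraction_kinked_chains must be in [0, 1]")
  stop_if(kink_position < 2 || kink_position >= chain_segments,
          "kink_position must lie strictly inside the chain")
  stop_if(headgroup_atom_count < 1, "headgroup_atom_count must be >= 1")
  stop_if(thermal_noise_sd < 0, "thermal_noise_sd must be >= 0")
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 area_per_lipid = area_per_lipid,
                 chain_segments = as.integer(chain_segments),
                 chains_per_lipid = as.integer(chains_per_lipid),
                 fraction_kinked_chains = fraction_kinked_chains,
                 kink_position = as.integer(kink_position),
                 kink_angle = kink_angle,
                 headgroup_atom_count = as.integer(headgroup_atom_count),
                 thermal_noise_sd = thermal_noise_sd,
                 seed = as.integer(seed)),
            class = "bilayer_gen_spec")
}

# single-lipid template in its own frame: origin at the lipid's lateral
# center, upper leaflet orientation (headgroup up, chains descending)
.lipid_template <- function(spec, kinked_chains, kink_azimuths) {
  g <- .bilayer_geom
  pos <- list(); role <- character(); chain <- integer(); segment <- integer()
  for (h in seq_len(spec$headgroup_atom_count)) {
    pos[[length(pos) + 1L]] <- c(0, 0, g$z_head + (h - 1))
    role <- c(role, "headgroup"); chain <- c(chain, NA_integer_)
    segment <- c(segment, NA_integer_)
  }
  pos[[length(pos) + 1L]] <- c(0, 0, g$z_glycerol)
  role <- c(role, "glycerol"); chain <- c(chain, NA_integer_)
  segment <- c(segment, NA_integer_)
  for (ch in seq_len(spec$chains_per_lipid)) {
    ang <- 2 * pi * (ch - 1) / spec$chains_per_lipid
    base <- c(1.2 * cos(ang), 1.2 * sin(ang), g$z_chain0)
    dirn <- c(0, 0, -1)
    p <- base
    for (s in seq_len(spec$chain_segments)) {
      if (s > 1) {
        if (kinked_chains[ch] && s == spec$kink_position + 1L) {
          th <- spec$kink_angle * pi / 180
          ps <- kink_azimuths[ch]
          dirn <- c(sin(th) * cos(ps), sin(th) * sin(ps), -cos(th))
        }
        p <- p + dirn * g$rise
      }
      pos[[length(pos) + 1L]] <- p
      role <- c(role, "chain"); chain <- c(chain, ch)
      segment <- c(segment, s)
    }
  }
  list(pos = do.call(rbind, pos), role = role, chain = chain,
       segment = segment)
}

#' Generate a synthetic bilayer trajectory
#'
#' Builds a two-leaflet bilayer mirrored about z = 0 from a
#' \code{\link{bilayer_gen_spec}} and samples \code{n_frames} frames by
#' adding seeded isotropic positional noise to the base structure. By
#' construction, straight chains place their tail segments deeper than
#' kinked chains, so a fully saturated-analog bilayer has a strictly higher
#' lipid-atom density in the 3--10 Angstrom band than a fully cis-analog
#' bilayer at the same area per lipid.
#'
#' @param spec a \code{\link{bilayer_gen_spec}}.
#' @param n_frames number of frames to generate.
#' @param label composition label stored with the trajectory.
#' @return a \code{bilayer_trajectory}: list with \code{frames} (list of
#'   n_atoms x 3 coordinate matrices, Angstrom), \code{box} (x, y, z edge
#'   lengths; lateral coordinates live in [0, L), z is centered on the
#'   midplane), and \code{atoms} (data frame with \code{atom_id},
#'   \code{lipid_id}, \code{leaflet}, \code{role}, \code{chain},
#'   \code{segment}, \code{include_in_density}).
#' @export
generate_bilayer <- function(spec, n_frames = 1, label = "synthetic") {
  stopifnot(inherits(spec, "bilayer_gen_spec"))
  stop_if(n_frames < 1, "n_frames must be >= 1")
  n <- spec$lipids_per_leaflet
  L <- sqrt(n * spec$area_per_lipid)
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  g <- .bilayer_geom
  z_top <- g$z_head + spec$headgroup_atom_count - 1
  Lz <- 2 * ceiling(z_top + 3)

  with_seed(spec$seed, {
    n_chain_tot <- n * spec$chains_per_lipid
    n_kink <- round(spec$fraction_kinked_chains * n_chain_tot)
    kink_idx <- if (n_kink > 0) sample.int(n_chain_tot, n_kink) else integer()
    kinked <- rep(FALSE, n_chain_tot); kinked[kink_idx] <- TRUE
    azim <- stats::runif(n_chain_tot, 0, 2 * pi)

    pos_list <- list(); tab_list <- list(); lipid_id <- 0L
    for (i in seq_len(n)) {
      lipid_id <- lipid_id + 1L
      cx <- ((i - 1) %% nx + 0.5) * L / nx
      cy <- ((i - 1) %/% nx + 0.5) * L / ny
      ch0 <- (i - 1) * spec$chains_per_lipid
      tmpl <- .lipid_template(spec,
                              kinked[ch0 + seq_len(spec$chains_per_lipid)],
                              azim[ch0 + seq_len(spec$chains_per_lipid)])
      p <- tmpl$pos; p[, 1] <- p[, 1] + cx; p[, 2] <- p[, 2] + cy
      pos_list[[i]] <- p
      tab_list[[i]] <- data.frame(lipid_id = lipid_id, leaflet = "upper",
                                  role = tmpl$role, chain = tmpl$chain,
                                  segment = tmpl$segment,
                                  stringsAsFactors = FALSE)
    }
    upper_pos <- do.call(rbind, pos_list)
    upper_tab <- do.call(rbind, tab_list)
    # lower leaflet: exact mirror through the midplane
    lower_pos <- upper_pos; lower_pos[, 3] <- -lower_pos[, 3]
    lower_tab <- upper_tab
    lower_tab$lipid_id <- lower_tab$lipid_id + n
    lower_tab$leaflet <- "lower"
    base <- rbind(upper_pos, lower_pos)
    atoms <- rbind(upper_tab, lower_tab)
    atoms <- cbind(atom_id = seq_len(nrow(atoms)), atoms,
                   include_in_density = TRUE)
    box <- c(L, L, Lz)

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      p <- base
      if (spec$thermal_noise_sd > 0)
        p <- p + matrix(stats::rnorm(length(p), 0, spec$thermal_noise_sd),
                        ncol = 3)
      p[, 1] <- p[, 1] %% L
      p[, 2] <- p[, 2] %% L
      frames[[f]] <- p
    }
    bilayer_trajectory(frames, box, atoms, label)
  })
}

#' Construct a bilayer trajectory from coordinates and an atom table
#'
#' Validates that every frame is an n x 3 matrix with a consistent atom
#' count, positions are finite, box edges positive, and every atom carries
#' a leaflet label.
#'
#' @param frames list of n_atoms x 3 coordinate matrices, Angstrom.
#' @param box x, y, z box edge lengths, Angstrom.
#' @param atoms data frame with \code{atom_id}, \code{lipid_id},
#'   \code{leaflet}, \code{role}, and optionally \code{chain},
#'   \code{segment}, \code{include_in_density}.
#' @param label composition label.
#' @return a \code{bilayer_trajectory}.
#' @export
bilayer_trajectory <- function(frames, box, atoms, label = "") {
  stop_if(length(frames) < 1, "trajectory needs at least one frame")
  stop_if(any(box <= 0), "box edges must be > 0")
  n <- nrow(frames[[1]])
  for (f in frames) {
    stop_if(!is.matrix(f) || ncol(f) != 3 || nrow(f) != n,
            "all frames must be n x 3 matrices with consistent atom count")
    stop_if(any(!is.finite(f)), "all positions must be finite")
  }
  stop_if(nrow(atoms) != n, "atom table does not match coordinates")
  stop_if(!all(atoms$leaflet %in% c("upper", "lower")),
          "leaflet labels must be 'upper' or 'lower'")
  structure(list(frames = frames, box = box, atoms = atoms,
                 n_frames = length(frames), label = label),
            class = "bilayer_trajectory")
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat("bilayer_trajectory:", nrow(x$atoms), "atoms,", x$n_frames,
      "frame(s), box", paste(signif(x$box, 4), collapse = " x "),
      "A, label:", x$label, "\n")
  invisible(x)
}

#' Specification for a synthetic TMH-dimer trajectory
#'
#' Each frame holds two parallel ideal alpha-helices; a dimer rotational
#' state is drawn from \code{state_weights} and both protomers' sensor
#' residues are rotated so their azimuths (measured toward the partner
#' helix) scatter around that state's center angle with circular spread
#' \code{angular_sd}. Default centers 0 / 90 / 180 degrees correspond to
#' the sensor residues facing each other, pointing the same way, and
#' pointing away from each other.
#'
#' @param state_weights three probabilities summing to 1.
#' @param state_center_angles center azimuth (degrees) of each state.
#' @param angular_sd wrapped-normal spread in degrees.
#' @param n_frames frames to generate (>= 1).
#' @param helix_separation inter-axis distance, Angstrom.
#' @param sensor_residue_index residue carrying the sensor side chain.
#' @param n_residues residues per helix.
#' @param seed integer seed.
#' @return an object of class \code{dimer_gen_spec}.
#' @export
dimer_gen_spec <- function(state_weights,
                           state_center_angles = c(0, 90, 180),
                           angular_sd = 10,
                           n_frames = 1000,
                           helix_separation = 9,
                           sensor_residue_index = 15,
                           n_residues = 30,
                           seed = 1L) {
  stop_if(length(state_weights) != 3, "state_weights must have length 3")
  stop_if(abs(sum(state_weights) - 1) > 1e-6,
          "state_weights must sum to 1")
  stop_if(any(state_weights < 0), "state_weights must be nonnegative")
  stop_if(n_frames < 1, "n_frames must be >= 1")
  stop_if(sensor_residue_index < 1 || sensor_residue_index > n_residues,
          "sensor_residue_index out of range")
  structure(list(state_weights = state_weights,
                 state_center_angles = state_center_angles,
                 angular_sd = angular_sd, n_frames = as.integer(n_frames),
                 helix_separation = helix_separation,
                 sensor_residue_index = as.integer(sensor_residue_index),
                 n_residues = as.integer(n_residues),
                 seed = as.integer(seed)),
            class = "dimer_gen_spec")
}

# ideal CA-trace helix around +z: radius 2.3 A, 1.5 A rise, 100 deg/residue
.ideal_helix <- function(n_res, phase = 0) {
  i <- seq_len(n_res) - 1
  ang <- phase + i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

#' Generate a synthetic TMH-dimer trajectory
#'
#' @param spec a \code{\link{dimer_gen_spec}}.
#' @return a \code{dimer_trajectory}: list with \code{frames} (each a list
#'   of two n_res x 3 CA coordinate matrices \code{A} and \code{B}),
#'   \code{sensor_index}, \code{times}, and the ground-truth per-frame
#'   \code{true_state} labels.
#' @export
generate_dimer <- function(spec) {
  stopifnot(inherits(spec, "dimer_gen_spec"))
  with_seed(spec$seed, {
    nr <- spec$n_residues; si <- spec$sensor_residue_index
    base <- .ideal_helix(nr)
    # azimuth of the sensor residue in the unrotated template
    alpha <- atan2(base[si, 2], base[si, 1])
    states <- sample.int(3, spec$n_frames, replace = TRUE,
                         prob = spec$state_weights)
    frames <- vector("list", spec$n_frames)
    sep <- spec$helix_separation
    for (f in seq_len(spec$n_frames)) {
      ctr <- spec$state_center_angles[states[f]] * pi / 180
      sd <- spec$angular_sd * pi / 180
      phi1 <- ctr + if (sd > 0) stats::rnorm(1, 0, sd) else 0
      phi2 <- ctr + if (sd > 0) stats::rnorm(1, 0, sd) else 0
      # protomer A: partner direction +x, so lab azimuth of sensor = phi1
      A <- .rotate_z(base, phi1 - alpha)
      # protomer B: partner direction -x (lab azimuth pi), sensor at pi - phi2
      B <- .rotate_z(base, (pi - phi2) - alpha)
      B[, 1] <- B[, 1] + sep
      frames[[f]] <- list(A = A, B = B)
    }
    structure(list(frames = frames, sensor_index = si,
                   times = seq_len(spec$n_frames),
                   true_state = c("facing-facing", "mixed",
                                  "away-away")[states],
                   n_frames = spec$n_frames),
              class = "dimer_trajectory")
  })
}

.rotate_z <- function(p, ang) {
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  p %*% t(R)
}

#' Generate a Gaussian-band emission spectrum
#'
#' Sum of Gaussian emission bands on a wavelength grid, plus optional
#' Gaussian noise, clipped at zero. Used as a fixture for generalized
#' polarization and ratiometric FRET reductions.
#'
#' @param bands list of numeric triplets \code{c(center_nm, width_nm,
#'   amplitude)}; \code{width_nm} is the Gaussian sigma.
#' @param grid strictly increasing wavelength grid, nm.
#' @param noise_sd additive noise SD in intensity units.
#' @param seed integer seed.
#' @param excitation excitation wavelength recorded with the spectrum, nm.
#' @return an \code{emission_spectrum}.
#' @export
generate_emission_spectrum <- function(bands, grid = seq(400, 600, by = 1),
                                       noise_sd = 0, seed = 1L,
                                       excitation = 375) {
  stop_if(length(bands) == 0, "band list must not be empty")
  stop_if(any(diff(grid) <= 0), "wavelength grid must be strictly increasing")
  intensity <- rep(0, length(grid))
  for (b in bands) {
    stop_if(length(b) != 3, "each band is c(center, width, amplitude)")
    stop_if(b[2] <= 0, "band width must be > 0")
    intensity <- intensity + b[3] * exp(-(grid - b[1])^2 / (2 * b[2]^2))
  }
  if (noise_sd > 0)
    intensity <- with_seed(seed,
      intensity + stats::rnorm(length(grid), 0, noise_sd))
  emission_spectrum(grid, pmax(intensity, 0), excitation = excitation)
}

#' Generate a 2D + triplet FCS autocorrelation curve
#'
#' Evaluates the two-dimensional diffusion plus triplet-blinking model
#' \deqn{G(\tau) = \left(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right)
#'   \frac{1}{N} \frac{1}{1 + \tau/\tau_D}}
#' on a lag grid and adds multiplicative Gaussian noise
#' (\code{G * (1 + eps)}, \code{eps ~ N(0, noise_sd)}), emulating the
#' relative noise of averaged membrane FCS curves.
#'
#' @param N mean number of fluorophores in the detection area.
#' @param tau_D diffusion time, seconds.
#' @param T triplet fraction in [0, 1).
#' @param tau_T triplet relaxation time, seconds.
#' @param lag_grid strictly increasing positive lag times, seconds.
#' @param noise_sd relative (multiplicative) noise SD.
#' @param seed integer seed.
#' @return a \code{correlation_curve}.
#' @export
generate_fcs_curve <- function(N, tau_D, T = 0, tau_T = 5e-6,
                               lag_grid = 10^seq(-6, 0, length.out = 120),
                               noise_sd = 0, seed = 1L) {
  stop_if(N <= 0, "N must be > 0")
  stop_if(tau_D <= 0, "tau_D must be > 0")
  stop_if(T < 0 || T >= 1, "triplet fraction T must satisfy 0 <= T < 1")
  stop_if(tau_T <= 0, "tau_T must be > 0")
  G <- fcs_model(lag_grid, N, tau_D, T, tau_T)
  if (noise_sd > 0)
    G <- with_seed(seed, G * (1 + stats::rnorm(length(G), 0, noise_sd)))
  correlation_curve(lag_grid, G)
}

#' Generate a three-line first-derivative cwEPR spectrum
#'
#' Builds a nitroxide-like triplet of first-derivative Gaussian lines. The
#' \code{broadening} parameter emulates dipolar spin--spin broadening: it
#' widens the outer (low- and high-field) lines by a factor (1 + b) and
#' attenuates their derivative amplitude by 1/(1 + b), so the low-field to
#' mid-field amplitude ratio decreases monotonically with b. The proximity
#' index read from these spectra is therefore monotone in b by
#' construction.
#'
#' @param broadening nonnegative outer-line broadening factor b.
#' @param amplitudes positive-lobe heights of the three lines at b = 0.
#' @param field_grid strictly increasing magnetic-field axis, mT.
#' @param centers line centers, mT, ordered low to high field.
#' @param width base Gaussian sigma of each line, mT.
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @return an \code{epr_spectrum}.
#' @export
generate_epr_spectrum <- function(broadening = 0,
                                  amplitudes = c(0.8, 1.0, 0.6),
                                  field_grid = seq(330, 342, by = 0.01),
                                  centers = c(334, 336, 338),
                                  width = 0.3, noise_sd = 0, seed = 1L) {
  stop_if(any(diff(field_grid) <= 0), "field grid must be strictly increasing")
  stop_if(length(amplitudes) != 3, "amplitudes must have length 3")
  stop_if(length(centers) != 3 || any(diff(centers) <= 0),
          "3 line centers must be ordered low-field to high-field")
  stop_if(broadening < 0, "broadening must be >= 0")
  amp <- rep(0, length(field_grid))
  for (i in 1:3) {
    s <- if (i == 2) width else width * (1 + broadening)
    a <- if (i == 2) amplitudes[i] else amplitudes[i] / (1 + broadening)
    # derivative line shape normalized to unit positive-lobe height
    x <- (field_grid - centers[i]) / s
    amp <- amp + a * (-x) * exp(-x^2 / 2) * exp(0.5)
  }
  if (noise_sd > 0)
    amp <- with_seed(seed, amp + stats::rnorm(length(amp), 0, noise_sd))
  epr_spectrum(field_grid, amp)
}
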