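# Shared fixtures, all built in code.

# trajectory with explicit coordinates: 1-atom-per-"lipid", both leaflets
make_point_traj <- function(positions, box, leaflet = NULL, role = "chain") {
  n <- nrow(positions)
  if (is.null(leaflet)) leaflet <- ifelse(positions[, 3] >= 0, "upper", "lower")
  atoms <- data.frame(atom_id = seq_len(n), lipid_id = seq_len(n),
                      leaflet = leaflet, role = role,
                      chain = NA_integer_, segment = NA_integer_,
                      include_in_density = TRUE)
  bilayer_trajectory(list(positions), box, atoms)
}

# trajectory holding a single acyl chain whose bond vectors are prescribed:
# unit_dirs is an n x 3 matrix of (not necessarily unit) step directions
make_chain_traj <- function(unit_dirs) {
  steps <- rbind(c(0, 0, 0), unit_dirs)
  pos <- apply(steps, 2, cumsum)
  n <- nrow(pos)
  atoms <- data.frame(atom_id = seq_len(n), lipid_id = 1L,
                      leaflet = "upper", role = "chain",
                      chain = 1L, segment = seq_len(n),
                      include_in_density = TRUE)
  box <- c(1, 1, 1) * (max(abs(pos)) * 2 + 10)
  bilayer_trajectory(list(pos), box, atoms)
}

# emission spectrum that is flat at i1 over the 400-460 nm channel and flat
# at i2 over 470-530 nm (zero elsewhere), on a 0.5 nm grid
make_two_channel_spectrum <- function(i1, i2) {
  wl <- seq(395, 540, by = 0.5)
  intensity <- ifelse(wl >= 400 & wl <= 460, i1,
                      ifelse(wl >= 470 & wl <= 530, i2, 0))
  emission_spectrum(wl, intensity)
}

# small noise-free bilayers for ordering checks
quick_bilayer <- function(fraction_kinked, n_frames = 2, noise = 0,
                          seed = 11, ...) {
  spec <- bilayer_gen_spec(lipids_per_leaflet = 25,
                           fraction_kinked_chains = fraction_kinked,
                           thermal_noise_sd = noise, seed = seed, ...)
  generate_bilayer(spec, n_frames = n_frames)
}
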