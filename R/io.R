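# Readers and writers for the standard on-disk forms: multi-model PDB or
# XYZ frames plus a lipid-topology CSV (atom_id, lipid_id, leaflet, role,
# chain, segment, include_in_density), and 2-column CSVs with unit headers
# for emission spectra, FCS curves and EPR spectra. Coordinates are
# Angstrom internally; readers reject malformed input loudly.

#' Write a bilayer trajectory to disk
#'
#' Coordinates go to a multi-model PDB (with a CRYST1 box record) or an
#' XYZ file (box on the comment line), chosen by the file extension; the
#' atom table goes to a topology CSV.
#'
#' @param traj a \code{bilayer_trajectory}.
#' @param path output coordinate file (.pdb or .xyz).
#' @param topology_path output topology CSV.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, topology_path) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    n <- nrow(traj$atoms)
    xyz <- do.call(rbind, lapply(traj$frames, function(p) as.numeric(t(p))))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = traj$atoms$lipid_id %% 10000L,
                     resid = substr(toupper(traj$atoms$role), 1, 3),
                     elety = rep("C", n))
    lines <- readLines(path)
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     traj$box[1], traj$box[2], traj$box[3])
    writeLines(c(cryst, lines), path)
  } else if (ext == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    for (p in traj$frames) {
      writeLines(as.character(nrow(p)), con)
      writeLines(sprintf("box %.6f %.6f %.6f", traj$box[1], traj$box[2],
                         traj$box[3]), con)
      writeLines(sprintf("C %.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]), con)
    }
  } else stop("unsupported trajectory format: .", ext, call. = FALSE)
  utils::write.csv(traj$atoms, topology_path, row.names = FALSE)
  invisible(path)
}

#' Read a bilayer trajectory
#'
#' Accepts a multi-model PDB or a concatenated-frame XYZ file plus the
#' topology CSV mapping each atom to its lipid, leaflet and role. Atom
#' counts must be consistent across frames and match the topology; the
#' first offending atom is named otherwise.
#'
#' @param path coordinate file (.pdb or .xyz).
#' @param topology_path topology CSV written by
#'   \code{\link{write_trajectory}} (or hand-made with the same columns).
#' @param label composition label to attach.
#' @return a \code{bilayer_trajectory}.
#' @export
read_trajectory <- function(path, topology_path, label = basename(path)) {
  atoms <- utils::read.csv(topology_path, stringsAsFactors = FALSE)
  req <- c("atom_id", "lipid_id", "leaflet", "role")
  stop_if(!all(req %in% names(atoms)),
          paste("topology CSV needs columns:", paste(req, collapse = ", ")))
  if (is.null(atoms$include_in_density)) atoms$include_in_density <- TRUE
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    lines <- readLines(path, n = 200)
    cl <- grep("^CRYST1", lines, value = TRUE)
    stop_if(length(cl) == 0, "PDB lacks a CRYST1 box record")
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    n <- ncol(xyz) / 3
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  } else if (ext == "xyz") {
    lines <- readLines(path)
    frames <- list(); box <- NULL; i <- 1
    while (i <= length(lines)) {
      n <- suppressWarnings(as.integer(lines[i]))
      stop_if(is.na(n), paste("malformed XYZ atom count at line", i))
      stop_if(i + 1 + n > length(lines), "truncated XYZ frame")
      cm <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      if (length(cm) == 4 && cm[1] == "box")
        box <- as.numeric(cm[2:4])
      body <- lines[(i + 2):(i + 1 + n)]
      parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
      stop_if(ncol(parts) < 4, "malformed XYZ atom line")
      frames[[length(frames) + 1L]] <-
        matrix(as.numeric(parts[, 2:4]), ncol = 3)
      i <- i + 2 + n
    }
    stop_if(is.null(box), "XYZ comment lines carry no box record")
    n <- nrow(frames[[1]])
  } else stop("unsupported trajectory format: .", ext, call. = FALSE)
  if (n != nrow(atoms)) {
    bad <- max(n, nrow(atoms))
    stop("coordinate/topology mismatch: ", n, " atoms in frames vs ",
         nrow(atoms), " topology rows (first unmatched atom ",
         min(n, nrow(atoms)) + 1, " of ", bad, ")", call. = FALSE)
  }
  bilayer_trajectory(frames, box, atoms, label)
}

#' Write a dimer trajectory as a two-chain multi-model PDB
#'
#' @param dtraj a \code{dimer_trajectory}.
#' @param path output PDB path.
#' @return \code{path}, invisibly.
#' @export
write_dimer_pdb <- function(dtraj, path) {
  stopifnot(inherits(dtraj, "dimer_trajectory"))
  nr <- nrow(dtraj$frames[[1]]$A)
  xyz <- do.call(rbind, lapply(dtraj$frames, function(fr)
    as.numeric(t(rbind(fr$A, fr$B)))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = rep(seq_len(nr), 2),
                   resid = rep("ALA", 2 * nr),
                   chain = rep(c("A", "B"), each = nr),
                   elety = rep("CA", 2 * nr))
  invisible(path)
}

#' Read a two-chain multi-model PDB as a dimer trajectory
#'
#' @param path PDB with chains A and B, CA trace (or any per-residue
#'   backbone point set).
#' @param sensor_index residue index of the sensor side chain.
#' @return a \code{dimer_trajectory}.
#' @export
read_dimer_pdb <- function(path, sensor_index) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  ch <- pdb$atom$chain
  stop_if(!all(c("A", "B") %in% ch), "PDB must contain chains A and B")
  ia <- which(ch == "A"); ib <- which(ch == "B")
  stop_if(length(ia) != length(ib),
          "chains A and B must have the same residue count")
  frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    list(A = m[ia, , drop = FALSE], B = m[ib, , drop = FALSE])
  })
  stop_if(sensor_index < 1 || sensor_index > length(ia),
          "sensor_index out of range")
  structure(list(frames = frames, sensor_index = as.integer(sensor_index),
                 times = seq_along(frames), true_state = NULL,
                 n_frames = length(frames)),
            class = "dimer_trajectory")
}

# 2-column CSV with unit headers --------------------------------------------

.read_two_col <- function(path, col1, col2) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c(col1, col2) %in% names(d)),
          paste0("expected columns '", col1, "' and '", col2, "' in ", path))
  stop_if(any(!is.finite(d[[col1]])) || any(!is.finite(d[[col2]])),
          paste("non-finite values in", path))
  d
}

#' Read / write emission spectra, FCS curves and EPR spectra as CSV
#'
#' Column headers carry the units: \code{wavelength_nm,intensity_au} for
#' emission spectra, \code{lag_s,G} for correlation curves,
#' \code{field_mT,amplitude_au} for EPR spectra.
#'
#' @param path CSV path.
#' @return the corresponding container object.
#' @export
read_emission_csv <- function(path) {
  d <- .read_two_col(path, "wavelength_nm", "intensity_au")
  emission_spectrum(d$wavelength_nm, d$intensity_au)
}

#' @rdname read_emission_csv
#' @export
read_fcs_csv <- function(path) {
  d <- .read_two_col(path, "lag_s", "G")
  correlation_curve(d$lag_s, d$G, sd = d$sd)
}

#' @rdname read_emission_csv
#' @export
read_epr_csv <- function(path) {
  d <- .read_two_col(path, "field_mT", "amplitude_au")
  epr_spectrum(d$field_mT, d$amplitude_au)
}

#' @rdname read_emission_csv
#' @param x the spectrum or curve object to write.
#' @export
write_spectrum_csv <- function(x, path) {
  d <- if (inherits(x, "emission_spectrum"))
    data.frame(wavelength_nm = x$wavelength, intensity_au = x$intensity)
  else if (inherits(x, "correlation_curve")) {
    out <- data.frame(lag_s = x$lag, G = x$G)
    if (!is.null(x$sd)) out$sd <- x$sd
    out
  } else if (inherits(x, "epr_spectrum"))
    data.frame(field_mT = x$field, amplitude_au = x$amplitude)
  else stop("unsupported object for CSV export", call. = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a density map to long-format CSV plus JSON metadata
#'
#' @param map a \code{density_map} or \code{density_difference_map}.
#' @param csv_path long-format CSV (x, y, z voxel centers and density).
#' @param meta_path optional JSON metadata sidecar.
#' @return \code{csv_path}, invisibly.
#' @export
write_density_csv <- function(map, csv_path, meta_path = NULL) {
  stopifnot(inherits(map, c("density_map", "density_difference_map")))
  d <- dim(map$density)
  ve <- map$voxel_edge
  grid <- expand.grid(
    x = map$origin[1] + (seq_len(d[1]) - 0.5) * ve,
    y = map$origin[2] + (seq_len(d[2]) - 0.5) * ve,
    z = map$origin[3] + (seq_len(d[3]) - 0.5) * ve)
  grid$density <- as.numeric(map$density)
  utils::write.csv(grid, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- map[setdiff(names(map), "density")]
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
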