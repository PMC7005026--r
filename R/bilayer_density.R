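# Frame-averaged local lipid-atom number-density maps on a voxel grid
# (default 1 A edge), their depth x lateral projections and depth profiles,
# and signed difference maps between compositions. The 3--10 A band
# statistic quantifies packing in the region probed by the sensory
# tryptophan.

#' Center a bilayer on its midplane and wrap laterally
#'
#' For every frame, translates z so the midplane (the mean of the two
#' per-leaflet mean headgroup z coordinates) sits at z = 0, and wraps x and
#' y into [0, box edge). Makes "distance from bilayer center" well defined
#' before any density calculation.
#'
#' @param traj a \code{bilayer_trajectory}.
#' @return the centered, wrapped trajectory.
#' @export
center_and_wrap <- function(traj) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  hg_up <- traj$atoms$role == "headgroup" & traj$atoms$leaflet == "upper"
  hg_lo <- traj$atoms$role == "headgroup" & traj$atoms$leaflet == "lower"
  stop_if(!any(hg_up) || !any(hg_lo),
          "each leaflet needs at least one headgroup atom to define the midplane")
  traj$frames <- lapply(traj$frames, function(p) {
    mid <- (mean(p[hg_up, 3]) + mean(p[hg_lo, 3])) / 2
    p[, 3] <- p[, 3] - mid
    p[, 1] <- p[, 1] %% traj$box[1]
    p[, 2] <- p[, 2] %% traj$box[2]
    p
  })
  traj
}

#' Voxelized lipid-atom number density
#'
#' Bins the atoms flagged \code{include_in_density} of every frame into
#' cubic voxels (half-open \code{[k, k+1)} intervals, box-anchored at
#' \code{(0, 0, -Lz/2)}) and averages the per-voxel counts over frames,
#' normalized to atoms per cubic Angstrom. Atoms landing exactly on the
#' upper box face wrap to the first voxel. Frames are binned on the stored
#' box; the grid spans the box.
#'
#' @param traj a centered \code{bilayer_trajectory}.
#' @param voxel_edge voxel edge length, Angstrom.
#' @return a \code{density_map}: 3D array \code{density} (atoms/A^3),
#'   \code{origin}, \code{voxel_edge}, \code{n_frames}, mean included atom
#'   count \code{n_atoms_mean}, and the composition \code{label}.
#' @export
voxel_density <- function(traj, voxel_edge = 1) {
  stopifnot(inherits(traj, "bilayer_trajectory"))
  stop_if(voxel_edge <= 0, "voxel_edge must be > 0")
  stop_if(traj$n_frames < 1, "trajectory has no frames")
  keep <- traj$atoms$include_in_density
  stop_if(!any(keep), "no atoms flagged include_in_density")
  box <- traj$box
  nvox <- pmax(1L, floor(box / voxel_edge + 1e-9))
  origin <- c(0, 0, -box[3] / 2)
  counts <- array(0, dim = nvox)
  for (p in traj$frames) {
    q <- p[keep, , drop = FALSE]
    q[, 1] <- q[, 1] %% box[1]
    q[, 2] <- q[, 2] %% box[2]
    q[, 3] <- (q[, 3] - origin[3]) %% box[3]
    ix <- pmin(1L + floor(q[, 1] / voxel_edge), nvox[1])
    iy <- pmin(1L + floor(q[, 2] / voxel_edge), nvox[2])
    iz <- pmin(1L + floor(q[, 3] / voxel_edge), nvox[3])
    lin <- ix + nvox[1] * (iy - 1L) + nvox[1] * nvox[2] * (iz - 1L)
    counts <- counts + array(tabulate(lin, nbins = prod(nvox)), dim = nvox)
  }
  dens <- counts / traj$n_frames / voxel_edge^3
  structure(list(density = dens, origin = origin, voxel_edge = voxel_edge,
                 n_frames = traj$n_frames, n_atoms_mean = sum(keep),
                 label = traj$label, box = box),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", paste(dim(x$density), collapse = " x "),
      "voxels of", x$voxel_edge, "A,", x$n_frames, "frame(s), label:",
      x$label, "\n")
  invisible(x)
}

# z coordinates of voxel centers, relative to the bilayer midplane
.z_centers <- function(map) {
  map$origin[3] + (seq_len(dim(map$density)[3]) - 0.5) * map$voxel_edge
}

#' Project a density map to depth x lateral coordinates
#'
#' Averages the 3D map over the second lateral axis (y), leaving a 2D map
#' of density against distance from the bilayer center (z, rows) and
#' lateral position (x, columns) -- the representation used to visualize
#' where packing changes localize.
#'
#' @param map a \code{density_map} or \code{density_difference_map}.
#' @return list with matrix \code{density} (z by x), \code{z} voxel-center
#'   depths and \code{x} voxel-center lateral positions.
#' @export
project_depth_lateral <- function(map) {
  stopifnot(inherits(map, c("density_map", "density_difference_map")))
  m <- apply(map$density, c(1, 3), mean)   # x by z
  list(density = t(m),
       z = .z_centers(map),
       x = map$origin[1] + (seq_len(dim(map$density)[1]) - 0.5) *
         map$voxel_edge)
}

#' Depth profile of lipid-atom density
#'
#' Lateral (x, y) average of the map per z bin. With \code{symmetrize},
#' bins at +z and -z whose centers share the same distance from the
#' midplane are averaged, exploiting leaflet mirror symmetry.
#'
#' @param map a \code{density_map} or \code{density_difference_map}.
#' @param symmetrize average z and -z bins.
#' @return data frame with \code{z} (depth, or |z| when symmetrized) and
#'   \code{density} (atoms/A^3).
#' @export
depth_profile <- function(map, symmetrize = FALSE) {
  stopifnot(inherits(map, c("density_map", "density_difference_map")))
  prof <- apply(map$density, 3, mean)
  z <- .z_centers(map)
  if (!symmetrize)
    return(data.frame(z = z, density = prof))
  bin <- floor(abs(z) / map$voxel_edge)
  agg <- tapply(prof, bin, mean)
  zs <- (as.numeric(names(agg)) + 0.5) * map$voxel_edge
  data.frame(z = zs, density = as.numeric(agg))
}

#' Signed difference between two density maps
#'
#' Voxel-wise \code{a - b} after cropping both maps to their common grid
#' extent (laterally from the box anchor, in z symmetrically about the
#' midplane). Positive values mark regions where composition \code{a}
#' packs more lipid atoms than composition \code{b}.
#'
#' @param map_a,map_b \code{density_map}s with identical voxel edge.
#' @return a \code{density_difference_map} recording both labels.
#' @export
difference_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  stop_if(abs(map_a$voxel_edge - map_b$voxel_edge) > 1e-9,
          "voxel edges differ; maps are not comparable")
  da <- dim(map_a$density); db <- dim(map_b$density)
  nd <- pmin(da, db)
  crop <- function(map, nd) {
    d <- dim(map$density)
    # z cropped centrally so both grids stay anchored on the midplane
    z0 <- (d[3] - nd[3]) %/% 2
    stop_if((d[3] - nd[3]) %% 2 != 0,
            "z grids cannot be aligned on the midplane by cropping")
    map$density[seq_len(nd[1]), seq_len(nd[2]), z0 + seq_len(nd[3]),
                drop = FALSE]
  }
  a <- crop(map_a, nd); b <- crop(map_b, nd)
  origin <- map_a$origin
  origin[3] <- -nd[3] * map_a$voxel_edge / 2
  structure(list(density = a - b, origin = origin,
                 voxel_edge = map_a$voxel_edge,
                 n_frames = c(map_a$n_frames, map_b$n_frames),
                 label_a = map_a$label, label_b = map_b$label),
            class = "density_difference_map")
}

#' @export
print.density_difference_map <- function(x, ...) {
  cat("density_difference_map:", x$label_a, "-", x$label_b, ",",
      paste(dim(x$density), collapse = " x "), "voxels\n")
  invisible(x)
}

#' Density statistic over the sensor band
#'
#' Mean and SD of the (signed) density over all voxels whose centers lie at
#' \code{z_min <= |z| <= z_max} -- both leaflets. The default 3--10
#' Angstrom band is the region of the hydrophobic core probed by the
#' sensory tryptophan of the saturation sensor.
#'
#' @param map a \code{density_map} or \code{density_difference_map}.
#' @param z_min,z_max band limits in Angstrom from the bilayer center.
#' @return list with \code{mean}, \code{sd} (atoms/A^3) and \code{n_voxels}.
#' @export
band_statistic <- function(map, z_min = 3, z_max = 10) {
  stopifnot(inherits(map, c("density_map", "density_difference_map")))
  stop_if(z_min >= z_max, "z_min must be < z_max")
  z <- .z_centers(map)
  sel <- abs(z) >= z_min & abs(z) <= z_max
  stop_if(!any(sel), "band lies outside the map's z grid")
  stop_if(max(abs(z)) < z_max - map$voxel_edge,
          "band extends beyond the map's z grid")
  vals <- map$density[, , sel]
  list(mean = mean(vals), sd = stats::sd(as.numeric(vals)),
       n_voxels = length(vals))
}
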