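# Back-of-envelope liposome arithmetic: from vesicle geometry and lipid
# composition to lipid counts, bilayer volume, and the molar concentration
# of unsaturated acyl chains inside that volume -- the numbers behind the
# ON/OFF switching of the saturation sensor (~1.9 M OFF, ~1.3 M ON).

AVOGADRO <- 6.02214076e23

#' Liposome geometry and composition specification
#'
#' Defaults (4 nm bilayer, 0.65 nm^2 per lipid) reproduce the canonical
#' figures for a 200 nm vesicle: about 3.7e5 lipids and a membrane volume
#' of about 4.8e-19 L.
#'
#' @param diameter_nm outer vesicle diameter, nm.
#' @param thickness_nm bilayer thickness, nm.
#' @param area_per_lipid_nm2 area per lipid, nm^2.
#' @param composition data frame with one row per lipid species:
#'   \code{species}, \code{mol_fraction} (summing to 1), \code{chains}
#'   (acyl chains per lipid) and \code{unsat_chains} (unsaturated chains
#'   per lipid).
#' @param lipid_count optional explicit lipid count overriding geometry.
#' @param membrane_volume_l optional explicit bilayer volume (liters)
#'   overriding geometry.
#' @return a \code{liposome_spec}.
#' @export
liposome_spec <- function(diameter_nm = 200, thickness_nm = 4,
                          area_per_lipid_nm2 = 0.65,
                          composition = data.frame(
                            species = "POPC", mol_fraction = 1,
                            chains = 2, unsat_chains = 1),
                          lipid_count = NULL, membrane_volume_l = NULL) {
  stop_if(diameter_nm <= 0, "diameter must be > 0")
  stop_if(thickness_nm < 0, "thickness must be >= 0")
  stop_if(thickness_nm >= diameter_nm / 2,
          "bilayer thickness must be smaller than the vesicle radius")
  stop_if(area_per_lipid_nm2 <= 0, "area per lipid must be > 0")
  req <- c("species", "mol_fraction", "chains", "unsat_chains")
  stop_if(!all(req %in% names(composition)),
          paste("composition needs columns:", paste(req, collapse = ", ")))
  stop_if(abs(sum(composition$mol_fraction) - 1) > 1e-6,
          "mol fractions must sum to 1")
  stop_if(any(composition$unsat_chains > composition$chains),
          "unsaturated chains cannot exceed chains per lipid")
  stop_if(any(composition$chains < 0) || any(composition$unsat_chains < 0),
          "chain counts must be >= 0")
  structure(list(diameter_nm = diameter_nm, thickness_nm = thickness_nm,
                 area_per_lipid_nm2 = area_per_lipid_nm2,
                 composition = composition, lipid_count = lipid_count,
                 membrane_volume_l = membrane_volume_l),
            class = "liposome_spec")
}

#' Bilayer (membrane) volume of a liposome
#'
#' Spherical-shell volume \eqn{(4/3)\pi(r_{out}^3 - r_{in}^3)} with
#' \eqn{r_{in} = r_{out} - t}, converted to liters (1 nm^3 = 1e-24 L). An
#' explicit \code{membrane_volume_l} in the spec is returned verbatim.
#'
#' @param spec a \code{liposome_spec}.
#' @return volume in liters.
#' @export
membrane_volume <- function(spec) {
  stopifnot(inherits(spec, "liposome_spec"))
  if (!is.null(spec$membrane_volume_l)) return(spec$membrane_volume_l)
  r_out <- spec$diameter_nm / 2
  r_in <- r_out - spec$thickness_nm
  (4 / 3) * pi * (r_out^3 - r_in^3) * 1e-24
}

#' Number of lipids in a liposome
#'
#' Sum of the outer and inner leaflet areas divided by the area per lipid.
#' The inner leaflet is evaluated either at the inner shell radius
#' \code{r_in = r_out - t} (default; two-leaflet mode) or both leaflets at
#' the bilayer midplane radius.
#'
#' @param spec a \code{liposome_spec}.
#' @param leaflet_mode \code{"two-leaflet"} or \code{"midplane"}.
#' @return lipid count (not rounded).
#' @export
lipid_count <- function(spec, leaflet_mode = c("two-leaflet", "midplane")) {
  stopifnot(inherits(spec, "liposome_spec"))
  leaflet_mode <- match.arg(leaflet_mode)
  if (!is.null(spec$lipid_count)) return(spec$lipid_count)
  stop_if(spec$area_per_lipid_nm2 <= 0, "area per lipid must be > 0")
  r_out <- spec$diameter_nm / 2
  r_in <- r_out - spec$thickness_nm
  area <- if (leaflet_mode == "two-leaflet")
    4 * pi * (r_out^2 + r_in^2)
  else
    2 * 4 * pi * ((r_out + r_in) / 2)^2
  area / spec$area_per_lipid_nm2
}

#' Molar concentration of unsaturated acyl chains in the bilayer volume
#'
#' \deqn{c = \frac{n_{lipids} \sum_s f_s u_s}{N_A V_{membrane}}}
#' with \eqn{f_s} the mol fraction and \eqn{u_s} the unsaturated chains
#' per lipid of species s. For a 200 nm vesicle this yields ~1.3 M for
#' pure POPC (50\% unsaturated chains) and ~1.9 M for 1:1 DOPC:POPC
#' (75\% unsaturated chains) -- the concentrations between which the
#' sense-and-response system switches ON and OFF.
#'
#' @param spec a \code{liposome_spec}.
#' @param leaflet_mode passed to \code{\link{lipid_count}}.
#' @return concentration in mol/L.
#' @export
unsaturated_chain_molarity <- function(spec,
                                       leaflet_mode = "two-leaflet") {
  stopifnot(inherits(spec, "liposome_spec"))
  v <- membrane_volume(spec)
  stop_if(v <= 0, "membrane volume is zero")
  n_lip <- lipid_count(spec, leaflet_mode)
  unsat_per_lipid <- sum(spec$composition$mol_fraction *
                           spec$composition$unsat_chains)
  n_lip * unsat_per_lipid / AVOGADRO / v
}
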