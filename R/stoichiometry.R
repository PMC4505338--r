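## Molecules-per-cluster stoichiometry: standard curve -> copies per cell ->
## surface fraction -> cell surface area -> clusters per cell -> molecules
## per cluster.

## Mass of one molecule of given molar mass, in pg: kDa x 1000 g/mol divided
## by Avogadro's number, converted to pg.
.PG_PER_KDA <- 1e3 / 6.02214076e23 * 1e12  # = 1.66054e-9 pg per kDa

#' Fit a densitometric standard curve
#'
#' Ordinary least-squares line through titration points of recombinant
#' protein: signal = slope x mass + intercept. The inverse,
#' \code{invertMass}, converts a measured band signal to protein mass.
#'
#' @param points data.frame with columns \code{mass_pg} and \code{signal},
#'   or two numeric vectors via \code{mass_pg} and \code{signal}.
#' @param mass_pg,signal alternative vector interface.
#' @return a \linkS4class{StandardCurve}.
#' @export
fitStandardCurve <- function(points = NULL, mass_pg = NULL, signal = NULL) {
  if (is.null(points)) points <- data.frame(mass_pg = mass_pg, signal = signal)
  stopifnot(all(c("mass_pg", "signal") %in% names(points)))
  if (nrow(points) < 3L) .stopf("a standard curve needs at least 3 points")
  if (length(unique(points$mass_pg)) < 2L)
    .stopf("degenerate design: all standard masses are equal")
  fit <- stats::lm(signal ~ mass_pg, data = points)
  co <- stats::coef(fit)
  if (co[["mass_pg"]] <= 0) .stopf("fitted slope is not positive; not a valid standard curve")
  sm <- suppressWarnings(summary(fit))  # exact titrations trip the perfect-fit warning
  new("StandardCurve", points = points, slope = unname(co[["mass_pg"]]),
      intercept = unname(co[["(Intercept)"]]), r2 = sm$r.squared,
      slopeSe = unname(sm$coefficients["mass_pg", "Std. Error"]))
}

#' @rdname fitStandardCurve
#' @param curve a \linkS4class{StandardCurve}.
#' @return \code{invertMass}: inferred mass in pg.
#' @export
invertMass <- function(curve, signal) {
  stopifnot(is(curve, "StandardCurve"))
  mass <- (signal - curve@intercept) / curve@slope
  if (any(mass < 0)) .stopf("inferred mass is negative; signal below the curve intercept")
  mass
}

#' Molecules per cell from total protein mass
#'
#' Divides the per-cell protein mass by the mass of one molecule
#' (molar mass in kDa converted via Avogadro's number:
#' 1 kDa = 1.66054e-9 pg).
#'
#' @param massPg total protein mass in the lysate, pg (>= 0).
#' @param nCells number of cells in the lysate (> 0).
#' @param massKDa molecular mass, kDa (> 0).
#' @return molecule count per cell.
#' @export
moleculesPerCell <- function(massPg, nCells, massKDa) {
  if (massPg < 0 || nCells <= 0 || massKDa <= 0)
    .stopf("massPg must be >= 0 and nCells, massKDa > 0")
  (massPg / nCells) / (massKDa * .PG_PER_KDA)
}

#' Surface fraction from isotype-corrected flow cytometry
#'
#' Fraction of a protein on the plasma membrane:
#' 100 x (surface MFI - surface isotype) / (total MFI - total isotype),
#' where surface staining is without and total staining with
#' permeabilization.
#'
#' @param surfaceMfi,totalMfi geometric mean fluorescence intensities.
#' @param surfaceIso,totalIso matched isotype-control MFIs.
#' @return percentage.
#' @export
surfaceFraction <- function(surfaceMfi, totalMfi, surfaceIso = 0, totalIso = 0) {
  denom <- totalMfi - totalIso
  if (denom <= 0) .stopf("total MFI must exceed its isotype control")
  100 * (surfaceMfi - surfaceIso) / denom
}

#' Mean cell surface area from equatorial radii
#'
#' Sphere model of cytoskeleton-disrupted, hypotonically swollen cells:
#' the mean over cells of 4 pi r^2 (not 4 pi (mean r)^2, which differs for
#' dispersed samples by Jensen's inequality).
#'
#' @param radiiUm equatorial radii, um (all > 0).
#' @return mean surface area, um^2.
#' @export
cellSurfaceArea <- function(radiiUm) {
  if (length(radiiUm) < 1L || any(radiiUm <= 0)) .stopf("need >= 1 positive radius")
  mean(4 * pi * radiiUm^2)
}

#' Molecules per cluster
#'
#' Completes the stoichiometry chain: surface molecules = molecules/cell x
#' surface fraction; clusters/cell = surface area x cluster density;
#' molecules/cluster = surface molecules / clusters/cell. All intermediates
#' are reported and the chain identity holds to machine precision.
#'
#' @param moleculesPerCell total copies per cell.
#' @param surfaceFractionPct percentage of copies on the plasma membrane.
#' @param surfaceAreaUm2 mean cell surface area, um^2 (> 0).
#' @param clusterDensity cluster density on the membrane, clusters/um^2 (> 0).
#' @param notes optional provenance notes carried into the result.
#' @return a \linkS4class{StoichiometryResult}.
#' @examples
#' moleculesPerCluster(53185, 30.12, 1040, 4.4)
#' @export
moleculesPerCluster <- function(moleculesPerCell, surfaceFractionPct,
                                surfaceAreaUm2, clusterDensity,
                                notes = character(0)) {
  if (surfaceAreaUm2 <= 0 || clusterDensity <= 0)
    .stopf("surface area and cluster density must be positive")
  if (moleculesPerCell < 0 || surfaceFractionPct < 0)
    .stopf("molecules per cell and surface fraction must be >= 0")
  surfaceMolecules <- moleculesPerCell * surfaceFractionPct / 100
  clustersPerCell <- surfaceAreaUm2 * clusterDensity
  new("StoichiometryResult",
      moleculesPerCell = moleculesPerCell,
      surfaceFractionPct = surfaceFractionPct,
      surfaceAreaUm2 = surfaceAreaUm2,
      clusterDensity = clusterDensity,
      surfaceMolecules = surfaceMolecules,
      clustersPerCell = clustersPerCell,
      moleculesPerCluster = surfaceMolecules / clustersPerCell,
      notes = notes)
}

#' Full stoichiometry chain from raw measurements
#'
#' Convenience wrapper running the whole chain from primary measurements:
#' standard-curve inversion of the lysate band signal, copies per cell,
#' isotype-corrected surface fraction, sphere-model surface area, and the
#' molecules-per-cluster estimate.
#'
#' @param curve a \linkS4class{StandardCurve}.
#' @param lysateSignal densitometric signal of the lysate band.
#' @param nCells cells in the lysate.
#' @param massKDa molecular mass of the (unglycosylated) protein, kDa.
#' @param surfaceMfi,totalMfi,surfaceIso,totalIso flow-cytometry MFIs.
#' @param radiiUm equatorial cell radii, um.
#' @param clusterDensity cluster density, clusters/um^2.
#' @return a \linkS4class{StoichiometryResult}.
#' @export
stoichiometryChain <- function(curve, lysateSignal, nCells, massKDa,
                               surfaceMfi, totalMfi, surfaceIso = 0,
                               totalIso = 0, radiiUm, clusterDensity) {
  massPg <- invertMass(curve, lysateSignal)
  mpc <- moleculesPerCell(massPg, nCells, massKDa)
  frac <- surfaceFraction(surfaceMfi, totalMfi, surfaceIso, totalIso)
  area <- cellSurfaceArea(radiiUm)
  moleculesPerCluster(mpc, frac, area, clusterDensity,
                      notes = sprintf("lysate mass %.1f pg from standard curve (R^2 = %.4f)",
                                      massPg, curve@r2))
}

#' Serialize a stoichiometry result to JSON
#'
#' Writes every intermediate of the chain plus provenance notes.
#'
#' @param result a \linkS4class{StoichiometryResult}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStoichiometry <- function(result, path) {
  stopifnot(is(result, "StoichiometryResult"))
  out <- list(molecules_per_cell = result@moleculesPerCell,
              surface_fraction_pct = result@surfaceFractionPct,
              surface_area_um2 = result@surfaceAreaUm2,
              cluster_density_per_um2 = result@clusterDensity,
              surface_molecules = result@surfaceMolecules,
              clusters_per_cell = result@clustersPerCell,
              molecules_per_cluster = result@moleculesPerCluster,
              notes = as.character(result@notes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
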