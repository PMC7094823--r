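#' @useDynLib SpliceCell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd setNames t.test cor.test ks.test
#' @importFrom utils write.table read.table packageVersion
NULL

## Site-type codes are fixed, 0-based, and shared with the C++ engine.
.SITE_TYPES <- c(
  "extracellular" = 0L, "plasma_membrane" = 1L, "cytoplasm" = 2L,
  "nuclear_membrane" = 3L, "nucleoplasm" = 4L, "cajal" = 5L,
  "speckle" = 6L, "npc" = 7L, "mitochondria" = 8L, "golgi" = 9L, "er" = 10L
)

#' Names of the 11 lattice site types
#'
#' The single compartment label carried by each lattice site; it controls
#' which species may occupy the site and which reactions may fire there.
#'
#' @return Character vector of the 11 site-type names, in code order.
#' @export
siteTypeNames <- function() names(.SITE_TYPES)

.AVOGADRO <- 6.02214076e23

#' Voxelized cell geometry
#'
#' A cubic lattice of site-type codes with spacing `spacing` (micrometres),
#' the substrate for diffusion and compartment-restricted reactions.
#' Physical position of site `(i, j, k)` (1-based) is `(i - 0.5) * spacing`
#' along each axis; the box boundary is reflective.
#'
#' @slot sites 3-D integer array of site-type codes (0-10, see
#'   [siteTypeNames()]).
#' @slot spacing lattice spacing in micrometres.
#' @slot edge box edge length in micrometres.
#' @slot placedObjects data.frame of stenciled primitives
#'   (kind, site_type, cx, cy, cz, d1, d2, d3).
#' @slot genePositions integer matrix (n x 3) of 1-based lattice coordinates
#'   of active gene sites, with a `speckle` assignment and realized
#'   `distance` attribute columns kept in `geneInfo`.
#' @slot geneInfo data.frame with columns speckle, distance (um).
#' @slot config list echo of the [geometryConfig()] used to build it.
#' @slot seed integer seed the build was made with.
#' @export
setClass("SiteLattice", representation(
  sites = "array",
  spacing = "numeric",
  edge = "numeric",
  placedObjects = "data.frame",
  genePositions = "matrix",
  geneInfo = "data.frame",
  config = "list",
  seed = "integer"
))

setValidity("SiteLattice", function(object) {
  d <- dim(object@sites)
  if (length(d) != 3L) return("sites must be a 3-D array")
  if (object@spacing <= 0) return("spacing must be positive")
  rng <- range(object@sites)
  if (rng[1] < 0L || rng[2] > 10L) {
    return(sprintf("unknown site-type code %d (codes must be 0..10)",
                   if (rng[1] < 0) rng[1] else rng[2]))
  }
  if (nrow(object@genePositions) > 0) {
    idx <- object@genePositions
    codes <- object@sites[cbind(idx[, 1], idx[, 2], idx[, 3])]
    if (!all(codes == .SITE_TYPES[["nucleoplasm"]]))
      return("gene positions must lie on nucleoplasm sites")
  }
  TRUE
})

#' Reaction network with spatial species attributes
#'
#' Species carry diffusion coefficients, allowed site types and initial
#' conditions; reactions are mass-action with compartment restrictions
#' (site-type sets). The transition bias holds the per-species
#' boundary-crossing probability multipliers P_n (nucleoplasm to speckle)
#' and P_s (speckle to nucleoplasm) that realize speckle partitioning.
#'
#' @slot species data.frame: name, D (um^2/s), allowed (comma-separated
#'   site types), pool (logical; abundant background species), init_mode
#'   ("count" or "conc"), init_value, init_where (site type or "genes").
#' @slot reactions data.frame: name, r1, r2 (NA for first order), products
#'   (comma-separated), rate, units ("s-1" or "M-1s-1"), where
#'   (comma-separated site types the reaction may fire in).
#' @slot bias data.frame: species, Pn, Ps.
#' @slot variant character tag ("table2", "table2_nucleus_only", "table3",
#'   "table3_cotx").
#' @slot params list of the rate parameters used to build the network.
#' @export
setClass("ReactionNetwork", representation(
  species = "data.frame",
  reactions = "data.frame",
  bias = "data.frame",
  variant = "character",
  params = "list"
))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species$name
  for (i in seq_len(nrow(object@reactions))) {
    rx <- object@reactions[i, ]
    refs <- c(rx$r1, rx$r2, .splitNames(rx$products))
    refs <- refs[!is.na(refs) & nzchar(refs)]
    if (!all(refs %in% sp))
      return(sprintf("reaction '%s' references undeclared species: %s",
                     rx$name, paste(setdiff(refs, sp), collapse = ", ")))
    if (!rx$units %in% c("s-1", "M-1s-1"))
      return(sprintf("reaction '%s' has undeclared rate units", rx$name))
  }
  b <- object@bias
  if (nrow(b) > 0 && (any(b$Pn < 0 | b$Pn > 1) || any(b$Ps < 0 | b$Ps > 1)))
    return("bias probabilities must lie in [0, 1]")
  TRUE
})

#' Well-mixed compartment model
#'
#' Compartments with volumes and first-order exchange, the substrate of the
#' exact Gillespie oracle/surrogate.
#'
#' @slot compartments data.frame: name, volume (um^3), site_types
#'   (comma-separated lattice site types the compartment aggregates).
#' @slot exchange data.frame: species, from, to, rate (s^-1 per molecule),
#'   and optionally `convert_to` (species name the molecule becomes on
#'   arrival; used for nuclear-pore transport).
#' @slot network a [ReactionNetwork-class].
#' @export
setClass("CompartmentModel", representation(
  compartments = "data.frame",
  exchange = "data.frame",
  network = "ReactionNetwork"
))

setValidity("CompartmentModel", function(object) {
  if (any(object@compartments$volume <= 0)) return("volumes must be > 0")
  cn <- object@compartments$name
  ex <- object@exchange
  if (nrow(ex) > 0 && !all(c(ex$from, ex$to) %in% cn))
    return("exchange references unknown compartments")
  TRUE
})

#' Simulation trajectory
#'
#' Per-compartment species counts at recorded times, with event tallies and
#' the first-appearance time of each species.
#'
#' @slot times numeric vector of recording times (s).
#' @slot counts 3-D array `[species, compartment, time]`.
#' @slot speciesNames,compartmentNames character vectors naming the axes.
#' @slot tally numeric vector of event counts per reaction channel.
#' @slot firstSeen numeric; first time each species had positive count
#'   (-1 if never).
#' @slot metadata list (engine, seed, replicate, tau, ...).
#' @export
setClass("Trajectory", representation(
  times = "numeric",
  counts = "array",
  speciesNames = "character",
  compartmentNames = "character",
  tally = "numeric",
  firstSeen = "numeric",
  metadata = "list"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3) return("counts must be [species, compartment, time]")
  if (d[1] != length(object@speciesNames)) return("species axis mismatch")
  if (d[2] != length(object@compartmentNames)) return("compartment axis mismatch")
  if (d[3] != length(object@times)) return("time axis mismatch")
  if (is.unsorted(object@times)) return("times must be monotone")
  TRUE
})

.splitNames <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}
.joinNames <- function(x) paste(x, collapse = ",")
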