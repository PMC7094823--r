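#' Volume fraction of a site type
#'
#' Fraction of the cell volume (sites inside the plasma membrane, inclusive)
#' occupied by a site type; with `of = "box"`, fraction of the whole
#' simulation box. Fractions over all intracellular types sum to one.
#'
#' @param lattice a [SiteLattice-class].
#' @param siteType one of [siteTypeNames()].
#' @param of denominator: `"cell"` (intracellular sites) or `"box"`.
#' @return numeric fraction in `[0, 1]`.
#' @export
setGeneric("volumeFraction", function(lattice, siteType, of = c("cell", "box"))
  standardGeneric("volumeFraction"))

#' @rdname volumeFraction
setMethod("volumeFraction", "SiteLattice", function(lattice, siteType,
                                                   of = c("cell", "box")) {
  of <- match.arg(of)
  if (!siteType %in% names(.SITE_TYPES))
    stop("unknown site type: ", siteType)
  tab <- tabulate(as.integer(lattice@sites) + 1L, nbins = 11L)
  n <- tab[.SITE_TYPES[[siteType]] + 1L]
  denom <- if (of == "box") length(lattice@sites)
           else sum(tab) - tab[.SITE_TYPES[["extracellular"]] + 1L]
  n / denom
})

#' Lattice spacing
#' @param x a [SiteLattice-class].
#' @return spacing in micrometres.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname spacing
setMethod("spacing", "SiteLattice", function(x) x@spacing)

#' Per-site-type site counts
#' @param x a [SiteLattice-class].
#' @return named integer vector over the 11 site types.
#' @export
setGeneric("siteTypeCounts", function(x) standardGeneric("siteTypeCounts"))
#' @rdname siteTypeCounts
setMethod("siteTypeCounts", "SiteLattice", function(x) {
  setNames(tabulate(as.integer(x@sites) + 1L, nbins = 11L), siteTypeNames())
})

#' Species table of a network or model
#' @param x a [ReactionNetwork-class] or [CompartmentModel-class].
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))
#' @rdname speciesTable
setMethod("speciesTable", "ReactionNetwork", function(x) x@species)
#' @rdname speciesTable
setMethod("speciesTable", "CompartmentModel", function(x) x@network@species)

#' Reaction table of a network or model
#' @param x a [ReactionNetwork-class] or [CompartmentModel-class].
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))
#' @rdname reactionTable
setMethod("reactionTable", "ReactionNetwork", function(x) x@reactions)
#' @rdname reactionTable
setMethod("reactionTable", "CompartmentModel", function(x) x@network@reactions)

#' Recording times of a trajectory
#' @param x a [Trajectory-class].
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname timePoints
setMethod("timePoints", "Trajectory", function(x) x@times)

#' Counts of one species over time
#'
#' @param x a [Trajectory-class].
#' @param species species name.
#' @param compartments compartment names to sum over (default: all).
#' @return numeric vector over recorded times.
#' @export
setGeneric("speciesCounts", function(x, species, compartments = NULL)
  standardGeneric("speciesCounts"))
#' @rdname speciesCounts
setMethod("speciesCounts", "Trajectory", function(x, species,
                                                 compartments = NULL) {
  si <- match(species, x@speciesNames)
  if (any(is.na(si))) stop("unknown species: ",
                           paste(species[is.na(si)], collapse = ", "))
  if (is.null(compartments)) compartments <- x@compartmentNames
  ci <- match(compartments, x@compartmentNames)
  if (any(is.na(ci))) stop("unknown compartment")
  apply(x@counts[si, ci, , drop = FALSE], 3, sum)
})

#' Endpoint (final-time) counts
#' @param x a [Trajectory-class].
#' @param species species name(s); default all.
#' @param compartments compartments to sum over; default all.
#' @export
setGeneric("endpointCounts", function(x, species = NULL, compartments = NULL)
  standardGeneric("endpointCounts"))
#' @rdname endpointCounts
setMethod("endpointCounts", "Trajectory", function(x, species = NULL,
                                                   compartments = NULL) {
  if (is.null(species)) species <- x@speciesNames
  vapply(species, function(s) {
    v <- speciesCounts(x, s, compartments)
    v[length(v)]
  }, numeric(1))
})

setMethod("show", "SiteLattice", function(object) {
  d <- dim(object@sites)
  cat(sprintf("SiteLattice: %d x %d x %d sites, spacing %.3f um (edge %.3f um)\n",
              d[1], d[2], d[3], object@spacing, object@edge))
  tab <- siteTypeCounts(object)
  present <- tab[tab > 0]
  cat(sprintf("  %d site types present; %d gene sites\n",
              length(present), nrow(object@genePositions)))
  v <- object@spacing^3
  for (nm in names(present))
    cat(sprintf("  %-17s %10d sites  %10.1f um^3\n", nm, present[[nm]],
                present[[nm]] * v))
  invisible(NULL)
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork '%s': %d species, %d reactions\n",
              object@variant, nrow(object@species), nrow(object@reactions)))
  nb <- object@bias[object@bias$Pn != 1 | object@bias$Ps != 1, , drop = FALSE]
  if (nrow(nb) > 0)
    cat(sprintf("  speckle bias on %d species (Pn/Ps up to %.2f)\n",
                nrow(nb), max(nb$Pn / nb$Ps)))
  invisible(NULL)
})

setMethod("show", "CompartmentModel", function(object) {
  cat(sprintf("CompartmentModel: %s; %d exchange channels\n",
              paste(sprintf("%s (%.1f um^3)", object@compartments$name,
                            object@compartments$volume), collapse = ", "),
              nrow(object@exchange)))
  invisible(NULL)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory [%s]: %d species x %d compartments x %d times (0..%g s)\n",
              if (is.null(object@metadata$engine)) "?" else object@metadata$engine,
              dim(object@counts)[1], dim(object@counts)[2],
              dim(object@counts)[3], max(object@times)))
  invisible(NULL)
})
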