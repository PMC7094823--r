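## Constructive-solid-geometry lattice builder.
##
## Primitives are stenciled onto the lattice in depth order (painter's
## algorithm): a site belongs to a shape iff its *center* lies inside, and
## later paints win. Coordinates: site (i,j,k) has center ((i-0.5)*lambda, ...).

#' Geometry configuration
#'
#' All dimensions in micrometres. Defaults describe the mid-size (3000 um^3)
#' spherical HeLa cell: radius 8.9 um, nucleus 4.2 um with nuclear pore
#' complexes at 7 per um^2 (radius 0.08), 20 nuclear speckles (radius 0.35),
#' 4 Cajal bodies (radius 0.5), ~2000 mitochondria (0.9 x 0.5 um
#' spherocylinders, ~11% of cell volume), ER grown to 4.5% of cell volume,
#' and a 5-sheet Golgi. Membranes are 0.128 um thick.
#'
#' @param edge box edge length; `spacing` the lattice spacing (64 nm default).
#' @param cellRadius,nuclearRadius sphere radii.
#' @param membraneThickness shell thickness for both membranes; raised to
#'   `spacing` automatically on coarse lattices (a thinner shell would leak).
#' @param npcDensity pores per um^2 of nuclear envelope; `npcRadius` pore
#'   channel radius.
#' @param nSpeckles,speckleRadius,speckleTotalFraction speckle count and
#'   either a fixed radius or a total volume fraction of the nucleus (the
#'   radius then follows from `(3 f V_nuc / (4 pi n))^(1/3)`).
#' @param nCajal,cajalRadius Cajal bodies.
#' @param nMito,mitoLength,mitoDiameter,mitoMode mitochondria;
#'   mode "discrete" (non-overlapping spherocylinders) or "network"
#'   (crossing rods of length `networkRodLength`, total volume matched to
#'   discrete mode).
#' @param erFraction target ER fraction of cell volume.
#' @param golgiSheets,golgiThickness Golgi cone-shell stack.
#' @param nGenes,geneDistance,geneShellWidth active genes placed
#'   `geneDistance` to `geneDistance + geneShellWidth` um from the nearest
#'   speckle surface, round-robin over speckles.
#' @param cytoplasmicOrganelles include ER/mitochondria/Golgi?
#' @param nucleusOnly build only the nucleus (plus a thin cytoplasm rim) in
#'   a tight box; used for nucleus-scale splicing runs.
#' @param seed integer build seed.
#' @return a `geometryConfig` list.
#' @export
geometryConfig <- function(edge = 18.432, spacing = 0.064,
                           cellRadius = 8.9, nuclearRadius = 4.2,
                           membraneThickness = 0.128,
                           npcDensity = 7, npcRadius = 0.08,
                           nSpeckles = 20, speckleRadius = 0.35,
                           speckleTotalFraction = NULL,
                           nCajal = 4, cajalRadius = 0.5,
                           nMito = 2000, mitoLength = 0.9, mitoDiameter = 0.5,
                           mitoMode = c("discrete", "network"),
                           networkRodLength = 2.95,
                           erFraction = 0.045,
                           golgiSheets = 5, golgiThickness = 0.128,
                           nGenes = 20, geneDistance = 0,
                           geneShellWidth = 0.02,
                           cytoplasmicOrganelles = TRUE,
                           nucleusOnly = FALSE,
                           seed = 1L) {
  mitoMode <- match.arg(mitoMode)
  if (spacing <= 0) stop("spacing must be positive")
  if (cellRadius <= 0 || nuclearRadius <= 0) stop("radii must be positive")
  if (nuclearRadius + membraneThickness >= cellRadius)
    stop("nucleus does not fit inside the cell")
  if (erFraction < 0 || erFraction >= 1) stop("erFraction must be in [0, 1)")
  membraneThickness <- max(membraneThickness, spacing)
  if (nucleusOnly)
    edge <- ceiling(2 * (nuclearRadius + membraneThickness + 0.5) / spacing) *
      spacing
  cfg <- as.list(environment())
  class(cfg) <- "geometryConfig"
  cfg
}

.emptyLattice <- function(edge, spacing, fill = "extracellular") {
  n <- round(edge / spacing)
  new("SiteLattice",
      sites = array(.SITE_TYPES[[fill]], dim = c(n, n, n)),
      spacing = spacing, edge = n * spacing,
      placedObjects = data.frame(),
      genePositions = matrix(integer(0), 0, 3),
      geneInfo = data.frame(),
      config = list(), seed = NA_integer_)
}

.axisCenters <- function(lattice) {
  (seq_len(dim(lattice@sites)[1]) - 0.5) * lattice@spacing
}

## ---- shape primitives -------------------------------------------------

#' Geometric primitives for stenciling
#'
#' Constructors for the shapes understood by [stencilPrimitive()]:
#' sphere, spherocylinder (capsule between two endpoints), spherical shell,
#' and cone-intersect-shell (the Golgi element).
#'
#' @param center,a,b,apex numeric length-3 positions (um).
#' @param r,rIn,rOut radii (um).
#' @param axis unit direction of the cone axis; `halfAngle` in radians.
#' @return a shape object.
#' @export
shpSphere <- function(center, r) {
  if (!is.finite(r) || r < 0) stop("invalid shape: sphere radius must be >= 0")
  structure(list(center = center, r = r), class = c("shpSphere", "shape"))
}

#' @rdname shpSphere
#' @export
shpSpherocylinder <- function(a, b, r) {
  if (!is.finite(r) || r <= 0) stop("invalid shape: capsule radius must be > 0")
  structure(list(a = a, b = b, r = r),
            class = c("shpSpherocylinder", "shape"))
}

#' @rdname shpSphere
#' @export
shpShell <- function(center, rIn, rOut) {
  if (!(rOut > rIn) || rIn < 0) stop("invalid shape: need 0 <= rIn < rOut")
  structure(list(center = center, rIn = rIn, rOut = rOut),
            class = c("shpShell", "shape"))
}

#' @rdname shpSphere
#' @export
shpConeShell <- function(apex, axis, halfAngle, rIn, rOut) {
  if (halfAngle <= 0 || halfAngle >= pi / 2) stop("invalid cone half-angle")
  if (!(rOut > rIn) || rIn < 0) stop("invalid shape: need 0 <= rIn < rOut")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(apex = apex, axis = axis, halfAngle = halfAngle,
                 rIn = rIn, rOut = rOut),
            class = c("shpConeShell", "shape"))
}

.shapeBBox <- function(shape) {
  switch(class(shape)[1],
    shpSphere = cbind(shape$center - shape$r, shape$center + shape$r),
    shpSpherocylinder = cbind(pmin(shape$a, shape$b) - shape$r,
                              pmax(shape$a, shape$b) + shape$r),
    shpShell = cbind(shape$center - shape$rOut, shape$center + shape$rOut),
    shpConeShell = cbind(shape$apex - shape$rOut, shape$apex + shape$rOut))
}

## logical inside-test on coordinate vectors x, y, z (same length)
.shapeInside <- function(shape, x, y, z) {
  switch(class(shape)[1],
    shpSphere = {
      (x - shape$center[1])^2 + (y - shape$center[2])^2 +
        (z - shape$center[3])^2 <= shape$r^2
    },
    shpShell = {
      d2 <- (x - shape$center[1])^2 + (y - shape$center[2])^2 +
        (z - shape$center[3])^2
      d2 >= shape$rIn^2 & d2 < shape$rOut^2
    },
    shpSpherocylinder = {
      ab <- shape$b - shape$a
      L2 <- sum(ab^2)
      px <- x - shape$a[1]; py <- y - shape$a[2]; pz <- z - shape$a[3]
      t <- if (L2 > 0) pmin(1, pmax(0, (px * ab[1] + py * ab[2] + pz * ab[3]) / L2)) else 0
      (px - t * ab[1])^2 + (py - t * ab[2])^2 + (pz - t * ab[3])^2 <= shape$r^2
    },
    shpConeShell = {
      px <- x - shape$apex[1]; py <- y - shape$apex[2]; pz <- z - shape$apex[3]
      d <- sqrt(px^2 + py^2 + pz^2)
      proj <- px * shape$axis[1] + py * shape$axis[2] + pz * shape$axis[3]
      inCone <- proj > 0 & proj >= d * cos(shape$halfAngle)
      inCone & d >= shape$rIn & d < shape$rOut
    })
}

#' Stencil a primitive onto the lattice
#'
#' Every site whose center lies inside the shape is overwritten with
#' `siteType` (painter's algorithm: later calls win); other sites are
#' unchanged. Shapes may extend beyond the box (clipped). With `onlyOver`,
#' only sites currently of those types are overwritten (used to confine
#' organelles to the cytoplasm).
#'
#' @param lattice a [SiteLattice-class].
#' @param shape a shape from [shpSphere()] and friends.
#' @param siteType target site type name.
#' @param onlyOver optional character vector of site types that may be
#'   overwritten.
#' @return the updated lattice. The number of painted sites is available as
#'   `attr(, "painted")`.
#' @export
stencilPrimitive <- function(lattice, shape, siteType, onlyOver = NULL) {
  if (!inherits(shape, "shape")) stop("invalid shape object")
  code <- .SITE_TYPES[[siteType]]
  if (is.null(code)) stop("unknown site type: ", siteType)
  ax <- .axisCenters(lattice)
  n <- length(ax)
  bb <- .shapeBBox(shape)
  lo <- pmax(1L, pmin(n, ceiling(bb[, 1] / lattice@spacing + 0.5 - 1e-9)))
  hi <- pmax(0L, pmin(n, floor(bb[, 2] / lattice@spacing + 0.5 + 1e-9)))
  if (any(hi < lo)) {
    attr(lattice, "painted") <- 0L
    return(lattice)
  }
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- expand.grid(x = ax[ix], y = ax[iy], z = ax[iz], KEEP.OUT.ATTRS = FALSE)
  inside <- .shapeInside(shape, g$x, g$y, g$z)
  sub <- lattice@sites[ix, iy, iz, drop = FALSE]
  dim(inside) <- dim(sub)
  if (!is.null(onlyOver)) {
    okCodes <- .SITE_TYPES[onlyOver]
    inside <- inside & (sub %in% okCodes)
  }
  sub[inside] <- code
  lattice@sites[ix, iy, iz] <- sub
  np <- sum(inside)
  lattice@placedObjects <- rbind(
    lattice@placedObjects,
    .objectRow(shape, siteType, np))
  attr(lattice, "painted") <- np
  lattice
}

.objectRow <- function(shape, siteType, painted) {
  ctr <- switch(class(shape)[1],
    shpSphere = shape$center,
    shpShell = shape$center,
    shpSpherocylinder = (shape$a + shape$b) / 2,
    shpConeShell = shape$apex)
  dims <- switch(class(shape)[1],
    shpSphere = c(shape$r, NA, NA),
    shpShell = c(shape$rIn, shape$rOut, NA),
    shpSpherocylinder = c(sqrt(sum((shape$b - shape$a)^2)), shape$r, NA),
    shpConeShell = c(shape$rIn, shape$rOut, shape$halfAngle))
  data.frame(kind = class(shape)[1], site_type = siteType,
             cx = ctr[1], cy = ctr[2], cz = ctr[3],
             d1 = dims[1], d2 = dims[2], d3 = dims[3],
             painted = painted)
}

## ---- membranes, pores -------------------------------------------------

#' Build plasma and nuclear membranes
#'
#' Paints the cell sphere (cytoplasm), a plasma-membrane shell
#' `[cellRadius - thickness, cellRadius)`, a nuclear-membrane shell
#' `[nuclearRadius, nuclearRadius + thickness)` and the nucleoplasm sphere.
#' A shell at least one lattice spacing thick is topologically closed under
#' 6-adjacency, so no cytoplasm site touches extracellular space and no
#' nucleoplasm site touches cytoplasm except through pore sites.
#'
#' @param lattice a [SiteLattice-class] (extracellular-filled box).
#' @param cellRadius,nuclearRadius,thickness micrometres.
#' @return the updated lattice.
#' @export
buildMembranes <- function(lattice, cellRadius, nuclearRadius, thickness) {
  if (thickness < lattice@spacing - 1e-9)
    stop("membrane thickness below the lattice spacing would leak")
  ctr <- rep(lattice@edge / 2, 3)
  lattice <- stencilPrimitive(lattice, shpSphere(ctr, cellRadius), "cytoplasm")
  lattice <- stencilPrimitive(
    lattice, shpShell(ctr, cellRadius - thickness, cellRadius),
    "plasma_membrane")
  lattice <- stencilPrimitive(
    lattice, shpShell(ctr, nuclearRadius, nuclearRadius + thickness),
    "nuclear_membrane")
  lattice <- stencilPrimitive(lattice, shpSphere(ctr, nuclearRadius),
                              "nucleoplasm")
  lattice
}

.fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Place nuclear pore complexes
#'
#' `round(density * 4 pi r_n^2)` pores at Fibonacci-sphere positions on the
#' nuclear envelope. Each pore converts the membrane sites within
#' `npcRadius` of its radial axis into npc sites, forming a channel that
#' connects nucleoplasm and cytoplasm at any lattice spacing. Overlapping
#' channels are merged (with a warning).
#'
#' @param lattice lattice with the nuclear membrane built.
#' @param density pores per um^2; `npcRadius` channel radius (um).
#' @param layout "fibonacci" (default) or "random".
#' @param seed used only for random layout.
#' @return list(lattice, count) with `count` the number of pores placed.
#' @export
placeNPCs <- function(lattice, density, npcRadius = 0.08,
                      layout = c("fibonacci", "random"), seed = 1L) {
  layout <- match.arg(layout)
  if (density < 0) stop("npc density must be >= 0")
  cfg <- lattice@config
  rn <- cfg$nuclearRadius
  count <- round(density * 4 * pi * rn^2)
  if (count == 0) return(list(lattice = lattice, count = 0L))
  dirs <- if (layout == "fibonacci") .fibonacciSphere(count) else
    .withSeed(seed, {
      v <- matrix(rnorm(3 * count), ncol = 3)
      v / sqrt(rowSums(v^2))
    })
  ctr <- lattice@edge / 2
  memCode <- .SITE_TYPES[["nuclear_membrane"]]
  idxLin <- which(lattice@sites == memCode)
  d <- dim(lattice@sites)
  coord <- arrayInd(idxLin, d)
  pos <- (coord - 0.5) * lattice@spacing
  pos <- sweep(pos, 2, rep(ctr, 3))
  r <- sqrt(rowSums(pos^2))
  ## channel must span the voxelized membrane: below ~0.75 lambda the
  ## radial voxel column would miss site centers and the pore would dead-end
  rEff <- max(npcRadius, 0.75 * lattice@spacing)
  claimed <- integer(0)
  nclaims <- 0L
  block <- max(1L, as.integer(5e6 / max(length(idxLin), 1L)))
  for (b in seq(1, count, by = block)) {
    bi <- b:min(b + block - 1L, count)
    dots <- pos %*% t(dirs[bi, , drop = FALSE])   # nMem x nBlock
    perp2 <- r^2 - pmax(dots, 0)^2
    hit <- which(dots > 0 & perp2 <= rEff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      claimed <- c(claimed, idxLin[hit[, 1]])
      nclaims <- nclaims + nrow(hit)
    }
  }
  claimedU <- unique(claimed)
  if (length(claimed) > length(claimedU))
    warning("overlapping NPC channels merged")
  sites <- lattice@sites
  sites[claimedU] <- .SITE_TYPES[["npc"]]
  lattice@sites <- sites
  list(lattice = lattice, count = as.integer(count))
}

## ---- stochastic organelles -------------------------------------------

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.neighbors6 <- function(idx, d) {
  ## linear-index 6-neighborhood with boundary guards; returns matrix
  nx <- d[1]; nxy <- d[1] * d[2]
  co <- arrayInd(idx, d)
  out <- cbind(
    ifelse(co[, 1] < d[1], idx + 1L, NA_integer_),
    ifelse(co[, 1] > 1L, idx - 1L, NA_integer_),
    ifelse(co[, 2] < d[2], idx + nx, NA_integer_),
    ifelse(co[, 2] > 1L, idx - nx, NA_integer_),
    ifelse(co[, 3] < d[3], idx + nxy, NA_integer_),
    ifelse(co[, 3] > 1L, idx - nxy, NA_integer_))
  out
}

#' Grow the endoplasmic reticulum
#'
#' Stochastic cellular-automaton growth: nuclei seeded on cytoplasm sites
#' next to the nuclear envelope dilate probabilistically into cytoplasm
#' sites only, with acceptance probability decaying with distance from the
#' nucleus, until the ER occupies `targetFraction` of the cell volume
#' (within +-0.002; the final accepted batch is truncated to land on the
#' target count). Deterministic given `seed`.
#'
#' @param lattice built lattice with cytoplasm present.
#' @param targetFraction target ER fraction of intracellular volume.
#' @param seed integer.
#' @param nSeeds number of seed nuclei.
#' @param decayLength e-folding length (um) of the radial acceptance decay.
#' @return the updated lattice.
#' @export
growER <- function(lattice, targetFraction, seed = 1L, nSeeds = 100L,
                   decayLength = NULL) {
  if (targetFraction < 0) stop("targetFraction must be >= 0")
  if (targetFraction == 0) return(lattice)
  tab <- siteTypeCounts(lattice)
  nCell <- sum(tab) - tab[["extracellular"]]
  target <- round(targetFraction * nCell)
  cytoCode <- .SITE_TYPES[["cytoplasm"]]
  erCode <- .SITE_TYPES[["er"]]
  nCyto <- tab[["cytoplasm"]]
  if (target > nCyto)
    stop(sprintf(
      "ER target unreachable: %.4f of cell volume requested but only %.4f available as cytoplasm",
      targetFraction, nCyto / nCell))
  d <- dim(lattice@sites)
  cfg <- lattice@config
  rn <- cfg$nuclearRadius %||% 0
  rc <- cfg$cellRadius %||% (lattice@edge / 2)
  if (is.null(decayLength)) decayLength <- max((rc - rn) / 2, 1)
  ctr <- lattice@edge / 2
  sites <- lattice@sites
  .withSeed(seed, {
    cytoIdx <- which(sites == cytoCode)
    co <- arrayInd(cytoIdx, d)
    rr <- sqrt(rowSums(((co - 0.5) * lattice@spacing - ctr)^2))
    nearEnv <- cytoIdx[rr <= rn + (cfg$membraneThickness %||% 0.128) +
                         2 * lattice@spacing]
    if (length(nearEnv) == 0) nearEnv <- cytoIdx[rank(rr) <= 500]
    seeds <- sample(nearEnv, min(nSeeds, length(nearEnv), target))
    sites[seeds] <- erCode
    nEr <- length(seeds)
    frontier <- seeds
    widened <- FALSE
    while (nEr < target) {
      nb <- .neighbors6(frontier, d)
      cand <- unique(nb[!is.na(nb)])
      cand <- cand[sites[cand] == cytoCode]
      if (length(cand) == 0) {
        if (widened)
          stop(sprintf(
            "ER growth stalled at fraction %.4f (target %.4f unreachable)",
            nEr / nCell, targetFraction))
        frontier <- which(sites == erCode)
        widened <- TRUE
        next
      }
      widened <- FALSE
      co <- arrayInd(cand, d)
      rr <- sqrt(rowSums(((co - 0.5) * lattice@spacing - ctr)^2))
      p <- 0.5 * exp(-pmax(rr - rn, 0) / decayLength)
      acc <- cand[runif(length(cand)) < p]
      if (length(acc) == 0) next
      if (nEr + length(acc) > target)
        acc <- sample(acc, target - nEr)
      sites[acc] <- erCode
      nEr <- nEr + length(acc)
      frontier <- acc
    }
  })
  lattice@sites <- sites
  lattice
}

#' Place mitochondria
#'
#' Discrete mode: `n` non-overlapping spherocylinders (total length
#' `length`, diameter `diameter`) at uniform random positions and
#' orientations in the cytoplasm. Network mode: rods of length
#' `rodLength` that may cross, added until the total mitochondrial volume
#' matches the discrete-mode total within 2%.
#'
#' @param lattice built lattice.
#' @param n number of discrete mitochondria (also sets the network-mode
#'   volume target).
#' @param totalLength,diameter discrete spherocylinder dimensions (um).
#' @param mode "discrete" or "network"; `rodLength` for network mode.
#' @param seed integer.
#' @return the updated lattice.
#' @export
placeMitochondria <- function(lattice, n, totalLength = 0.9, diameter = 0.5,
                              mode = c("discrete", "network"),
                              rodLength = 2.95, seed = 1L) {
  mode <- match.arg(mode)
  if (n == 0) return(lattice)
  cytoCode <- .SITE_TYPES[["cytoplasm"]]
  mitoCode <- .SITE_TYPES[["mitochondria"]]
  r <- diameter / 2
  volOne <- pi * r^2 * (totalLength - 2 * r) + 4 / 3 * pi * r^3
  d <- dim(lattice@sites)
  ax <- .axisCenters(lattice)
  sites <- lattice@sites
  spacing <- lattice@spacing
  segLen <- if (mode == "discrete") totalLength - 2 * r else rodLength - 2 * r
  coveredSites <- function(a, b) {
    sh <- shpSpherocylinder(a, b, r)
    bb <- .shapeBBox(sh)
    lo <- pmax(1L, ceiling(bb[, 1] / spacing + 0.5 - 1e-9))
    hi <- pmin(d, floor(bb[, 2] / spacing + 0.5 + 1e-9))
    if (any(hi < lo)) return(integer(0))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- expand.grid(x = ax[ix], y = ax[iy], z = ax[iz],
                     KEEP.OUT.ATTRS = FALSE)
    inside <- .shapeInside(sh, g$x, g$y, g$z)
    gi <- expand.grid(ix, iy, iz)[inside, , drop = FALSE]
    gi[, 1] + (gi[, 2] - 1L) * d[1] + (gi[, 3] - 1L) * d[1] * d[2]
  }
  .withSeed(seed, {
    cytoIdx <- which(sites == cytoCode)
    if (mode == "discrete") {
      placed <- 0L
      tries <- 0L
      maxTries <- 60L * n
      while (placed < n) {
        tries <- tries + 1L
        if (tries > maxTries)
          stop(sprintf("could not place %d mitochondria without overlap (placed %d)",
                       n, placed))
        ci <- sample(cytoIdx, 1L)
        cc <- as.numeric(arrayInd(ci, d) - 0.5) * spacing
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        a <- cc - u * segLen / 2
        b <- cc + u * segLen / 2
        cov <- coveredSites(a, b)
        if (length(cov) == 0 || any(sites[cov] != cytoCode)) next
        sites[cov] <- mitoCode
        placed <- placed + 1L
      }
    } else {
      # rods may cross each other but must stay within cytoplasm/mito space
      targetSites <- round(n * volOne / spacing^3)
      nMitoSites <- 0L
      tries <- 0L
      while (nMitoSites < targetSites * 0.98) {
        tries <- tries + 1L
        if (tries > 60L * n) stop("network mitochondria placement stalled")
        ci <- sample(cytoIdx, 1L)
        cc <- as.numeric(arrayInd(ci, d) - 0.5) * spacing
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        a <- cc - u * segLen / 2
        b <- cc + u * segLen / 2
        cov <- coveredSites(a, b)
        if (length(cov) == 0 ||
            !all(sites[cov] %in% c(cytoCode, mitoCode))) next
        newSites <- cov[sites[cov] == cytoCode]
        sites[newSites] <- mitoCode
        nMitoSites <- nMitoSites + length(newSites)
      }
    }
  })
  lattice@sites <- sites
  lattice
}

#' Place nuclear speckles
#'
#' `n` spheres placed uniformly at random in the nucleoplasm, not
#' overlapping each other, Cajal bodies, or the envelope. If
#' `totalFraction` is given, the per-speckle radius is
#' `(3 f V_nucleus / (4 pi n))^(1/3)`.
#'
#' @param lattice built lattice with nucleoplasm.
#' @param n number of speckles.
#' @param radius fixed radius (um), or NULL to use `totalFraction`.
#' @param totalFraction total speckle volume as a fraction of the nuclear
#'   volume.
#' @param seed integer.
#' @return the updated lattice; realized radius in `attr(, "radius")`.
#' @export
placeSpeckles <- function(lattice, n, radius = 0.35, totalFraction = NULL,
                          seed = 1L) {
  if (n == 0) return(lattice)
  rn <- lattice@config$nuclearRadius
  if (!is.null(totalFraction)) {
    Vn <- 4 / 3 * pi * rn^3
    radius <- (3 * totalFraction * Vn / (4 * pi * n))^(1 / 3)
  }
  lattice <- .placeNuclearBodies(lattice, n, radius, "speckle", seed)
  attr(lattice, "radius") <- radius
  lattice
}

#' Place Cajal bodies
#' @inheritParams placeSpeckles
#' @export
placeCajal <- function(lattice, n = 4, radius = 0.5, seed = 1L) {
  if (n == 0) return(lattice)
  .placeNuclearBodies(lattice, n, radius, "cajal", seed)
}

.placeNuclearBodies <- function(lattice, n, radius, siteType, seed) {
  rn <- lattice@config$nuclearRadius
  spacing <- lattice@spacing
  ctr <- rep(lattice@edge / 2, 3)
  maxR <- rn - radius - spacing
  if (maxR <= 0) stop("bodies of radius ", radius, " do not fit in the nucleus")
  existing <- lattice@placedObjects
  existing <- existing[existing$site_type %in% c("speckle", "cajal"), ,
                       drop = FALSE]
  centers <- if (nrow(existing)) as.matrix(existing[, c("cx", "cy", "cz")])
             else matrix(numeric(0), 0, 3)
  radii <- if (nrow(existing)) pmax(existing$d1, 0) else numeric(0)
  newCenters <- .withSeed(seed + match(siteType, names(.SITE_TYPES)), {
    placed <- 0L
    tries <- 0L
    acc <- matrix(numeric(0), 0, 3)
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 2000L * n)
        stop("infeasible packing of ", siteType, " bodies (placed ", placed, ")")
      p <- runif(3, -1, 1) * maxR
      if (sum(p^2) > maxR^2) next
      p <- ctr + p
      ok <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt(rowSums(sweep(centers, 2, p)^2))
        ok <- all(dd >= radii + radius + spacing)
      }
      if (!ok) next
      centers <- rbind(centers, p)
      radii <- c(radii, radius)
      acc <- rbind(acc, p)
      placed <- placed + 1L
    }
    acc
  })
  for (i in seq_len(nrow(newCenters)))
    lattice <- stencilPrimitive(lattice, shpSphere(newCenters[i, ], radius),
                                siteType, onlyOver = "nucleoplasm")
  lattice
}

#' Place active genes near speckle surfaces
#'
#' Gene sites are nucleoplasm sites at distance `[d, d + shellWidth]` from
#' the nearest speckle surface (the band is widened by one lattice spacing
#' if the exact band contains no site centers), assigned round-robin over
#' speckles.
#'
#' @param lattice lattice with speckles placed.
#' @param nGenes number of genes.
#' @param d target distance from the speckle surface (um).
#' @param shellWidth band width (um).
#' @param seed integer.
#' @return the updated lattice with `genePositions`/`geneInfo` filled.
#' @export
placeGenes <- function(lattice, nGenes, d = 0, shellWidth = 0.02, seed = 1L) {
  if (nGenes == 0) return(lattice)
  if (d < 0) stop("gene distance must be >= 0")
  obj <- lattice@placedObjects
  spk <- obj[obj$site_type == "speckle", , drop = FALSE]
  if (nrow(spk) == 0) stop("no speckles placed; cannot position genes")
  centers <- as.matrix(spk[, c("cx", "cy", "cz")])
  srad <- spk$d1
  nucIdx <- which(lattice@sites == .SITE_TYPES[["nucleoplasm"]])
  dd <- dim(lattice@sites)
  pos <- (arrayInd(nucIdx, dd) - 0.5) * lattice@spacing
  ## distance of each nucleoplasm site to each speckle surface
  distSurf <- matrix(0, length(nucIdx), nrow(spk))
  for (k in seq_len(nrow(spk)))
    distSurf[, k] <- sqrt(rowSums(sweep(pos, 2, centers[k, ])^2)) - srad[k]
  nearest <- max.col(-distSurf)
  nearestDist <- distSurf[cbind(seq_along(nucIdx), nearest)]
  gp <- matrix(0L, nGenes, 3)
  gi <- data.frame(speckle = integer(nGenes), distance = numeric(nGenes))
  .withSeed(seed + 97L, {
    for (g in seq_len(nGenes)) {
      k <- (g - 1L) %% nrow(spk) + 1L
      band <- c(d, d + shellWidth)
      cand <- which(nearest == k & nearestDist >= band[1] &
                      nearestDist <= band[2])
      if (length(cand) == 0) {
        band <- band + c(-0.5, 0.5) * lattice@spacing
        band[1] <- max(band[1], 0)
        cand <- which(nearest == k & nearestDist >= band[1] &
                        nearestDist <= band[2])
      }
      if (length(cand) == 0)
        stop(sprintf(
          "empty gene shell: no nucleoplasm site %.3f-%.3f um from speckle %d",
          d, d + shellWidth, k))
      pick <- cand[sample.int(length(cand), 1L)]
      gp[g, ] <- arrayInd(nucIdx[pick], dd)
      gi$speckle[g] <- k
      gi$distance[g] <- nearestDist[pick]
    }
  })
  lattice@genePositions <- gp
  lattice@geneInfo <- gi
  lattice
}

## ---- whole-cell composition ------------------------------------------

#' Build the voxelized cell
#'
#' Composes all placement operations in depth order: extracellular box,
#' cell sphere, plasma and nuclear membranes with nucleoplasm, Golgi,
#' mitochondria, ER, Cajal bodies, speckles, nuclear pore channels, genes.
#' Deterministic given `config$seed`.
#'
#' @param config a [geometryConfig()].
#' @return a [SiteLattice-class]; the NPC count is recorded in
#'   `lattice@config$npcCount`, the realized speckle radius in
#'   `lattice@config$speckleRadiusRealized`.
#' @export
buildCell <- function(config) {
  stopifnot(inherits(config, "geometryConfig"))
  lat <- .emptyLattice(config$edge, config$spacing,
                       fill = if (config$nucleusOnly) "cytoplasm"
                              else "extracellular")
  lat@config <- unclass(config)
  lat@seed <- as.integer(config$seed)
  ctr <- rep(lat@edge / 2, 3)
  th <- config$membraneThickness
  rn <- config$nuclearRadius
  if (config$nucleusOnly) {
    lat <- stencilPrimitive(lat, shpShell(ctr, rn, rn + th), "nuclear_membrane")
    lat <- stencilPrimitive(lat, shpSphere(ctr, rn), "nucleoplasm")
  } else {
    lat <- buildMembranes(lat, config$cellRadius, rn, th)
    if (config$cytoplasmicOrganelles) {
      if (config$golgiSheets > 0) {
        axis <- c(1, 0, 0)
        for (s in seq_len(config$golgiSheets)) {
          r0 <- rn + th + (s - 1) * 2 * config$golgiThickness
          lat <- stencilPrimitive(
            lat,
            shpConeShell(ctr, axis, pi / 6, r0, r0 + config$golgiThickness),
            "golgi", onlyOver = "cytoplasm")
        }
      }
      if (config$nMito > 0)
        lat <- placeMitochondria(lat, config$nMito, config$mitoLength,
                                 config$mitoDiameter, config$mitoMode,
                                 config$networkRodLength,
                                 seed = config$seed + 11L)
      if (config$erFraction > 0)
        lat <- growER(lat, config$erFraction, seed = config$seed + 23L)
    }
  }
  if (config$nCajal > 0)
    lat <- placeCajal(lat, config$nCajal, config$cajalRadius,
                      seed = config$seed + 31L)
  if (config$nSpeckles > 0) {
    lat <- placeSpeckles(lat, config$nSpeckles, config$speckleRadius,
                         config$speckleTotalFraction,
                         seed = config$seed + 41L)
    lat@config$speckleRadiusRealized <- attr(lat, "radius")
  }
  np <- placeNPCs(lat, config$npcDensity, config$npcRadius,
                  seed = config$seed + 51L)
  lat <- np$lattice
  lat@config$npcCount <- np$count
  if (config$nGenes > 0 && config$nSpeckles > 0)
    lat <- placeGenes(lat, config$nGenes, config$geneDistance,
                      config$geneShellWidth, seed = config$seed + 61L)
  validObject(lat)
  lat
}

#' Construction report
#'
#' Per-site-type site counts, volumes and cell-volume fractions.
#'
#' @param lattice a [SiteLattice-class].
#' @return data.frame (site_type, site_count, volume_um3, fraction); the
#'   fraction is relative to the intracellular volume (NA for
#'   extracellular).
#' @export
constructionReport <- function(lattice) {
  tab <- siteTypeCounts(lattice)
  v <- lattice@spacing^3
  nCell <- sum(tab) - tab[["extracellular"]]
  data.frame(
    site_type = names(tab),
    site_count = as.integer(tab),
    volume_um3 = as.numeric(tab) * v,
    fraction = ifelse(names(tab) == "extracellular", NA_real_,
                      as.numeric(tab) / nCell))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
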