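## Lattice container, trajectory format, configuration and run manifests.

.LATTICE_FORMAT <- "SpliceCell-lattice/1"

#' Write / read a lattice container
#'
#' Lossless round trip of the site array, spacing, site-type table, placed
#' objects, gene positions and build seed through R's native serialization
#' with a format-version field; `readLattice` validates the version and
#' rejects unknown site-type codes naming the offending code.
#'
#' @param lattice a [SiteLattice-class].
#' @param path file path (conventionally `.lat.rds`).
#' @return `readLattice` returns the [SiteLattice-class].
#' @export
writeLattice <- function(lattice, path) {
  obj <- list(format = .LATTICE_FORMAT,
              siteTypes = .SITE_TYPES,
              sites = lattice@sites,
              spacing = lattice@spacing,
              edge = lattice@edge,
              placedObjects = lattice@placedObjects,
              genePositions = lattice@genePositions,
              geneInfo = lattice@geneInfo,
              config = lattice@config,
              seed = lattice@seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeLattice
#' @export
readLattice <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt lattice container: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, .LATTICE_FORMAT))
    stop("lattice container version mismatch in ", path,
         " (expected ", .LATTICE_FORMAT, ")")
  bad <- setdiff(unique(as.integer(obj$sites)), unname(.SITE_TYPES))
  if (length(bad))
    stop("unknown site-type code ", bad[1], " in ", path)
  methods::new("SiteLattice", sites = obj$sites, spacing = obj$spacing,
               edge = obj$edge, placedObjects = obj$placedObjects,
               genePositions = obj$genePositions, geneInfo = obj$geneInfo,
               config = obj$config, seed = obj$seed)
}

#' Write the construction report
#'
#' Tab-separated site_type / site_count / volume_um3 / fraction table.
#'
#' @param lattice a [SiteLattice-class].
#' @param path file path.
#' @export
writeReport <- function(lattice, path) {
  write.table(constructionReport(lattice), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a trajectory
#'
#' Tab-separated long format (time, compartment, species, count,
#' replicate) with a `#`-prefixed metadata header (engine, seed, tau,
#' lambda, variant). Zero-count records are omitted; `readTrajectory`
#' restores them.
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @return `readTrajectory` returns the [Trajectory-class] (tally and
#'   first-seen times are not round-tripped).
#' @export
writeTrajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- traj@metadata
  for (k in names(md))
    writeLines(sprintf("# %s: %s", k, paste(format(md[[k]]), collapse = " ")),
               con)
  writeLines(sprintf("# species: %s", paste(traj@speciesNames, collapse = " ")),
             con)
  writeLines(sprintf("# compartments: %s",
                     paste(traj@compartmentNames, collapse = " ")), con)
  writeLines(sprintf("# times: %s", paste(format(traj@times), collapse = " ")),
             con)
  writeLines("time\tcompartment\tspecies\tcount\treplicate", con)
  rep <- md$replicate %||% 1L
  d <- dim(traj@counts)
  for (ti in seq_len(d[3])) {
    m <- traj@counts[, , ti, drop = FALSE]
    nz <- which(m != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    df <- data.frame(time = traj@times[ti],
                     compartment = traj@compartmentNames[nz[, 2]],
                     species = traj@speciesNames[nz[, 1]],
                     count = m[nz], replicate = rep)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", h)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- strsplit(v, " +")[[1]]
  }
  spn <- meta$species
  cpn <- meta$compartments
  times <- as.numeric(meta$times)
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  counts <- array(0, dim = c(length(spn), length(cpn), length(times)))
  if (nrow(df)) {
    si <- match(df$species, spn)
    ci <- match(df$compartment, cpn)
    ti <- match(df$time, times)
    counts[cbind(si, ci, ti)] <- df$count
  }
  md <- list(engine = meta$engine %||% "unknown")
  for (k in c("seed", "replicate", "tau", "lambda"))
    if (!is.null(meta[[k]])) md[[k]] <- as.numeric(meta[[k]])
  if (!is.null(meta$variant)) md$variant <- meta$variant
  methods::new("Trajectory", times = times, counts = counts,
               speciesNames = spn, compartmentNames = cpn,
               tally = numeric(0), firstSeen = numeric(0), metadata = md)
}

#' Read a geometry configuration from YAML
#'
#' Field names match the arguments of [geometryConfig()]; omitted fields
#' take their defaults.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags win
#'   over the file).
#' @return a `geometryConfig`.
#' @export
readGeometryConfig <- function(path, overrides = list()) {
  doc <- if (is.null(path)) list() else yaml::read_yaml(path)
  doc <- utils::modifyList(doc, overrides)
  known <- names(formals(geometryConfig))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown geometry configuration fields: ",
         paste(unknown, collapse = ", "))
  do.call(geometryConfig, doc)
}

#' Write a run manifest
#'
#' JSON provenance record: configuration echo, package version, seeds,
#' input/output file digests and wall time; any output file can be
#' regenerated from its manifest alone.
#'
#' @param path manifest path.
#' @param config configuration echo (list).
#' @param seeds named seeds used.
#' @param inputs,outputs file paths to digest.
#' @param wallTime seconds.
#' @export
writeManifest <- function(path, config = list(), seeds = list(),
                          inputs = character(0), outputs = character(0),
                          wallTime = NA_real_) {
  digest <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (!length(fs)) return(setNames(list(), character(0)))
    as.list(tools::md5sum(fs))
  }
  man <- list(package = "SpliceCell",
              version = as.character(packageVersion("SpliceCell")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = config, seeds = seeds,
              inputs = digest(inputs), outputs = digest(outputs),
              wall_time_s = wallTime)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
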