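## Shared I/O: multi-page float TIFF field stacks with JSON sidecars for
## units and scaling, CSV event catalogs and tables, YAML configuration,
## and run manifests.  All writers are atomic (write to a temporary file in
## the target directory, then rename).

.atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp",
                                                           basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Write and read field stacks as 32-bit float TIFF
#'
#' Frames of a scalar (or multi-channel) field are stored as a multi-page
#' 32-bit TIFF.  Because the TIFF writer persists float data in
#' \eqn{[0, 1]}, values are affinely normalized on write; the double
#' offset/scale and the unit metadata go to a JSON sidecar
#' (`<path>.json`), and reading inverts the mapping.  The round trip is
#' accurate to 32-bit float precision and bit-stable from the second
#' round trip on.
#'
#' @param field numeric array: `[nx, ny]`, `[nx, ny, nFrames]` or
#'   `[nx, ny, nChannel, nFrames]`.
#' @param path output `.tif` path.
#' @param unit unit label stored in the sidecar.
#' @param pixelSize pixel size stored in the sidecar.
#' @return `writeFieldStack`: the path, invisibly.  `readFieldStack`: the
#'   array with attributes `unit` and `pixelSize`.
#' @export
writeFieldStack <- function(field, path, unit = "", pixelSize = 1) {
  stopifnot(is.numeric(field), length(dim(field)) >= 2)
  d <- dim(field)
  lo <- min(field); hi <- max(field)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (field - lo) / scale
  pages <- if (length(d) == 2L) list(norm) else
    lapply(seq_len(prod(d[-(1:2)])), function(k) {
      m <- norm
      dim(m) <- c(d[1], d[2], prod(d[-(1:2)]))
      m[, , k]
    })
  meta <- list(offset = lo, scale = scale, dim = d, unit = unit,
               pixelSize = pixelSize)
  .atomically(path, function(tmp)
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32L, reduce = FALSE))
  .atomically(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname writeFieldStack
#' @export
readFieldStack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("parse error: missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  dim(arr) <- meta$dim
  out <- arr * meta$scale + meta$offset
  attr(out, "unit") <- meta$unit
  attr(out, "pixelSize") <- meta$pixelSize
  out
}

#' Write and read extrusion-event catalogs as CSV
#'
#' Columns: `step` (or `frame`), `x`, `y`, optional `id`, `type`.
#' Reading validates coordinates (nonnegative, finite) and required
#' columns, and reports the offending column on failure.
#'
#' @param events catalog data.frame.
#' @param path CSV path.
#' @return `writeEvents`: the path invisibly; `readEvents`: the validated
#'   data.frame.
#' @export
writeEvents <- function(events, path) {
  .atomically(path, function(tmp)
    write.csv(events, tmp, row.names = FALSE))
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  fcol <- intersect(c("step", "frame"), names(ev))
  if (!length(fcol))
    stop("validation error in ", path, ": missing column 'step' or 'frame'")
  for (cc in c("x", "y")) {
    if (!cc %in% names(ev))
      stop("validation error in ", path, ": missing column '", cc, "'")
    if (any(!is.finite(ev[[cc]])) || any(ev[[cc]] < 0))
      stop("validation error in ", path, ": column '", cc,
           "' has negative or non-finite coordinates")
  }
  if (!"type" %in% names(ev))
    stop("validation error in ", path, ": missing column 'type'")
  ev
}

#' Write a table atomically as CSV
#' @param rows data.frame to write.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeTable <- function(rows, path) {
  .atomically(path, function(tmp) write.csv(rows, tmp, row.names = FALSE))
  invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' Mirrors the [simConfig()] arguments: top-level keys for grid and
#' numerical constants, and a `typeParams` section with `A` and `B`
#' subsections holding [cellTypeParams()] arguments.  Validation errors
#' name the offending key.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
loadSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("nx", "ny", "nz", "nCell", "R0")
  for (k in req)
    if (is.null(y[[k]]))
      stop("config error in ", path, ": missing required key '", k, "'")
  tp <- list(A = cellTypeParams(), B = cellTypeParams())
  if (!is.null(y$typeParams)) {
    for (ty in names(y$typeParams)) {
      if (!ty %in% c("A", "B"))
        stop("config error in ", path,
             ": typeParams section must contain only 'A' and 'B', found '",
             ty, "'")
      tp[[ty]] <- do.call(cellTypeParams, y$typeParams[[ty]])
    }
  }
  args <- y[setdiff(names(y), "typeParams")]
  args$typeParams <- tp
  do.call(simConfig, args)
}

#' Run manifest for reproducibility
#'
#' Records the command, a hash of the configuration, the seed, the package
#' version and a timestamp.  Re-running with the same config and seed
#' reproduces stochastic outputs bit-exactly.
#'
#' @param command character command name.
#' @param config a [SimConfig-class] or any serializable configuration.
#' @param files optional named character vector of files to digest.
#' @return a list; write it with [writeRunManifest()].
#' @export
runManifest <- function(command, config, files = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  seed <- if (is(config, "SimConfig")) config@seed else NA_integer_
  list(command = command, configHash = hash, seed = seed,
       package = as.character(packageVersion("mechcompete")),
       files = digests, timestamp = format(Sys.time(), tz = "UTC"))
}

#' @rdname runManifest
#' @param manifest a manifest list.
#' @param path JSON output path.
#' @export
writeRunManifest <- function(manifest, path) {
  .atomically(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}
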