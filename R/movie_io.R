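#' Write a mapping movie to TIFF + JSON
#'
#' Stores each channel as a multi-page 16-bit TIFF (one file per channel,
#' `<basename>_ca.tif` / `<basename>_vm.tif`), with the affine scaling used
#' for quantization, all acquisition metadata and (optionally) the
#' ground-truth record in a JSON sidecar `<basename>.json`. Fluorescence
#' counts from the generator are quantized to 16 bits, matching the bit
#' depth of the EMCCD cameras such recordings come from; writing a movie
#' read back from disk reproduces the files bit-exactly.
#'
#' @param movie a `mapping_movie`.
#' @param dir output directory (created if needed).
#' @param basename file basename.
#' @param truth optional ground-truth record (as from
#'   [synthesize_movie()]) to embed in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_movie <- function(movie, dir, basename = "movie", truth = NULL) {
  stopifnot(inherits(movie, "mapping_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- list(ca = movie$calcium, vm = movie$voltage)
  meta <- list(frame_rate_hz = movie$frame_rate,
               pacing_times_ms = movie$pacing_times, bcl_ms = movie$bcl,
               condition = movie$condition, fov_mm = movie$fov,
               bz_mask = movie$bz_mask, channels = list())
  for (ch in names(channels)) {
    stack <- channels[[ch]]
    if (is.null(stack)) next
    rng <- range(stack)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    # quantize explicitly (writeTIFF truncates): pass mid-quantum values so
    # the stored integers are exactly round(norm * 65535), making
    # write -> read -> write idempotent
    q <- round((stack - rng[1]) / scale * 65535)
    norm <- pmin((q + 0.5) / 65535, 1)
    pages <- lapply(seq_len(dim(norm)[3]), function(k) norm[, , k])
    path <- file.path(dir, sprintf("%s_%s.tif", basename, ch))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    meta$channels[[ch]] <- list(file = basename(path), offset = rng[1],
                                scale = scale)
  }
  if (!is.null(truth)) {
    truth$template <- unclass(truth$template)
    meta$truth <- truth
  }
  sidecar <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a mapping movie written by [write_movie()]
#'
#' @param sidecar path to the JSON sidecar (or its basename without
#'   extension).
#' @return A list with `movie` (a `mapping_movie`) and `truth` (the embedded
#'   ground truth, or `NULL`).
#' @export
read_movie <- function(sidecar) {
  if (!grepl("\\.json$", sidecar)) sidecar <- paste0(sidecar, ".json")
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  stacks <- list(ca = NULL, vm = NULL)
  for (ch in names(meta$channels)) {
    info <- meta$channels[[ch]]
    pages <- tiff::readTIFF(file.path(dir, info$file), all = TRUE)
    stack <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) stack[, , k] <- pages[[k]]
    stacks[[ch]] <- stack * info$scale + info$offset
  }
  movie <- structure(list(
    calcium = stacks$ca, voltage = stacks$vm,
    frame_rate = meta$frame_rate_hz, pacing_times = meta$pacing_times_ms,
    bcl = meta$bcl_ms, condition = meta$condition,
    bz_mask = matrix(as.logical(meta$bz_mask), nrow(meta$bz_mask)),
    fov = meta$fov_mm), class = "mapping_movie")
  truth <- meta$truth
  if (!is.null(truth)) {
    for (f in c("signed", "nam", "catd90_ms")) {
      if (!is.null(truth[[f]])) truth[[f]] <- as.matrix(truth[[f]])
    }
  }
  list(movie = movie, truth = truth)
}
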