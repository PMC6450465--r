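# Run manifests: every command writes its configuration, seed and package
# version next to its outputs so any result is reproducible from the
# manifest alone.
.write_manifest <- function(out_dir, command, params) {
  manifest <- list(
    package = "alternansim",
    version = as.character(utils::packageVersion("alternansim")),
    command = command, timestamp = format(Sys.time(), tz = "UTC"),
    parameters = params)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Synthesize a mapping dataset on disk
#'
#' Generates the full synthetic protocol (every basic cycle length of the
#' ladder, `n_repeats` repeats per condition) and writes each movie as
#' TIFF + JSON with its ground truth, plus a run manifest.
#'
#' @param out_dir output directory.
#' @param config a [synth_protocol_config()].
#' @param field baseline [alternans_field()]; defaults to a field with
#'   stronger border-zone alternans on the default BZ mask.
#' @param template a [transient_template()].
#' @param conditions condition labels to generate.
#' @param n_repeats repeats per condition and bcl.
#' @param ... passed to [synthesize_protocol()].
#' @return data.frame indexing the written movies (condition, bcl, repeat,
#'   sidecar path), invisibly.
#' @export
cmd_synthesize <- function(out_dir, config = synth_protocol_config(),
                           field = NULL, template = transient_template(),
                           conditions = c("control", "NE", "NE+Meto"),
                           n_repeats = 3, ...) {
  if (is.null(field)) {
    mask <- default_bz_mask(config$grid)
    field <- make_uniform_field(config$grid, signed_magnitude = 0.1,
                                bz_mask = mask, bz_magnitude = 0.3)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- synthesize_protocol(config, field, template,
                              conditions = conditions,
                              n_repeats = n_repeats, ...)
  index <- list()
  for (cond in names(prot)) {
    for (bcl in names(prot[[cond]])) {
      for (r in seq_along(prot[[cond]][[bcl]])) {
        base <- sprintf("%s_bcl%s_rep%d", gsub("[^A-Za-z0-9]", "", cond),
                        bcl, r)
        el <- prot[[cond]][[bcl]][[r]]
        sidecar <- write_movie(el$movie, out_dir, base, truth = el$truth)
        index[[length(index) + 1]] <- data.frame(
          condition = cond, bcl_ms = as.numeric(bcl), rep = r,
          sidecar = basename(sidecar))
      }
    }
  }
  index <- do.call(rbind, index)
  utils::write.csv(index, file.path(out_dir, "index.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "synthesize",
                  list(config = unclass(config),
                       conditions = conditions, n_repeats = n_repeats,
                       field_summary = list(
                         grid = dim(field$signed),
                         magnitude_range = range(field$signed),
                         n_bz = sum(field$bz_mask))))
  invisible(index)
}

#' Analyze a mapping dataset
#'
#' Runs the alternans pipeline over every movie of a synthesized dataset
#' (per-pixel alternans map, transient durations, recording summaries),
#' averages the repeats of each condition and cycle length, and writes the
#' per-pixel CSVs, a JSON of recording summaries, the alternans-vs-bcl table
#' and the border-zone ratio table.
#'
#' @param in_dir dataset directory produced by [cmd_synthesize()].
#' @param out_dir output directory (defaults to `in_dir`).
#' @param ... passed to [alternans_map()].
#' @return List with `summaries` (per condition x bcl, repeats averaged) and
#'   `tables` (alternans vs bcl; BZ/NZ ratio vs bcl), invisibly.
#' @export
cmd_analyze <- function(in_dir, out_dir = in_dir, ...) {
  index_path <- file.path(in_dir, "index.csv")
  if (!file.exists(index_path)) stop("no index.csv in ", in_dir)
  index <- utils::read.csv(index_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frame_rates <- numeric(0)
  per_rec <- list()
  for (i in seq_len(nrow(index))) {
    rd <- read_movie(file.path(in_dir, index$sidecar[i]))
    frame_rates <- c(frame_rates, rd$movie$frame_rate)
    if (length(unique(frame_rates)) > 1) {
      stop("mixed frame rates across recordings: ", index$sidecar[i])
    }
    map <- alternans_map(rd$movie, ...)
    catd <- catd_map(rd$movie)
    px <- pixel_table(map, catd, rd$movie$bz_mask)
    csv <- sub("\\.json$", "_pixels.csv", index$sidecar[i])
    utils::write.csv(px, file.path(out_dir, csv), row.names = FALSE)
    per_rec[[i]] <- summarize_recording(map, catd, rd$movie$bz_mask)
  }
  # average repeats per condition x bcl
  key <- paste(index$condition, index$bcl_ms)
  summaries <- lapply(split(seq_len(nrow(index)), key), function(ix) {
    average_repeats(per_rec[ix], expected = length(ix))
  })
  tab <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(condition = s$condition, bcl_ms = s$bcl,
               mean_nam = s$mean_nam_total, mean_nam_bz = s$mean_nam_bz,
               mean_nam_nz = s$mean_nam_nz, bz_nz_ratio = s$bz_nz_ratio,
               catd90_bz = s$catd90_bz, catd90_nz = s$catd90_nz)
  }))
  tab <- tab[order(tab$condition, -tab$bcl_ms), ]
  utils::write.csv(tab, file.path(out_dir, "summary_by_bcl.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(summaries, unclass),
                       file.path(out_dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, "analyze", list(in_dir = in_dir,
                                           n_movies = nrow(index)))
  invisible(list(summaries = summaries, tables = tab))
}

#' Run the fiber protocols and write their tables
#'
#' Entry point over the simulation stack: runs either the five-fiber
#' premature-complex comparison (`protocol = "table2"`) or the
#' conduction-block window scan at a given beta-adrenergic level
#' (`protocol = "block"`), and writes the scan CSV, a JSON result and a run
#' manifest.
#'
#' @param out_dir output directory.
#' @param protocol `"table2"` or `"block"`.
#' @param bar_level beta-adrenergic level for the block protocol.
#' @param n_cells,n_prepace fiber size and pre-pacing depth.
#' @param ci_range,step coupling-interval scan bounds and step, ms.
#' @param fibers fiber ids for the table protocol.
#' @param ... passed to [fiber_config()].
#' @return The result object (data.frame or `vulnerability_result`),
#'   invisibly.
#' @export
cmd_simulate <- function(out_dir, protocol = c("table2", "block"),
                         bar_level = 0, n_cells = 240, n_prepace = 500,
                         ci_range = c(150, 250), step = 1,
                         fibers = c("A", "B", "C", "D", "E"), ...) {
  protocol <- match.arg(protocol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (protocol == "table2") {
    res <- table2_harness(fibers = fibers, n_cells = n_cells,
                          n_prepace = n_prepace, ci_range = ci_range,
                          step = step, ...)
    utils::write.csv(res, file.path(out_dir, "pvc_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res, file.path(out_dir, "pvc_table.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    cfg <- fiber_config(n_cells = n_cells, n_prepace = n_prepace,
                        bar_level = bar_level, ...)
    pp <- run_prepace(cfg)
    res <- suppressWarnings(
      scan_block_window(pp, ci_range = ci_range, step = step))
    utils::write.csv(res$scan, file.path(out_dir, "block_scan.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(block_window = res$block_window,
           min_full_ci = res$min_full_ci, ordered = res$ordered,
           scan_truncated = res$scan_truncated),
      file.path(out_dir, "block_result.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  .write_manifest(out_dir, paste0("simulate-", protocol),
                  list(protocol = protocol, bar_level = bar_level,
                       n_cells = n_cells, n_prepace = n_prepace,
                       ci_range = ci_range, step = step,
                       fibers = if (protocol == "table2") fibers else NULL))
  invisible(res)
}
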