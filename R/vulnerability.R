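#' Classify the outcome of an S2 stimulus
#'
#' Three outcomes are distinguished along a coupling-interval scan, decided
#' by the two fiber-end sentinel cells: `FULL_PROPAGATION` (both sentinels
#' activate after the S2), `BZ_BLOCK` (exactly one sentinel activates: the
#' wave propagates away from the stimulated segment on one side but fails to
#' traverse the tissue - in the conduction-block protocol, the border zone -
#' on the other), and `NO_PROPAGATION` (neither sentinel activates; this
#' includes marginal local ignitions that die within a few cells of the
#' stimulated segment without ever forming a propagating wave). Sentinels
#' sit `sentinel_offset` cells in from each fiber end.
#'
#' @param recording a `fiber_recording` from [apply_s2()].
#' @param sentinel_offset distance of the sentinel cells from the fiber ends.
#' @return An object of class `s2_outcome`: list with `category`, `ci`,
#'   and an `evidence` list (per-cell activation times, sentinels and which
#'   cells activated).
#' @export
classify_outcome <- function(recording, sentinel_offset = 5) {
  stopifnot(inherits(recording, "fiber_recording"), !is.null(recording$s2))
  n <- recording$config$n_cells
  act <- s2_activation_times(recording)
  seg <- recording$s2$segment
  sentinels <- c(sentinel_offset, n - sentinel_offset + 1)
  if (any(sentinels %in% seg)) {
    stop("sentinels overlap the stimulated segment")
  }
  outside <- setdiff(seq_len(n), seg)
  activated <- is.finite(act)
  n_sent <- sum(activated[sentinels])
  category <- if (n_sent == 2) {
    "FULL_PROPAGATION"
  } else if (n_sent == 1) {
    "BZ_BLOCK"
  } else {
    "NO_PROPAGATION"
  }
  structure(list(category = category, ci = recording$s2$ci,
                 evidence = list(activation_times = act,
                                 sentinels = sentinels,
                                 sentinel_activated = activated[sentinels],
                                 n_activated_outside = sum(activated[outside]))),
            class = "s2_outcome")
}

#' @export
print.s2_outcome <- function(x, ...) {
  cat(sprintf("<s2_outcome> ci=%g ms: %s (%d cells activated outside segment)\n",
              x$ci, x$category, x$evidence$n_activated_outside))
  invisible(x)
}

# Default S2 segments. Conduction block: proximal NZ directly adjacent to
# the BZ, so the S2 wave must traverse the BZ to reach the distal end. PVC:
# centered in the BZ (fiber center for a homogeneous fiber). The default
# width spans roughly one electrotonic space constant of the cable: a much
# narrower source cannot ignite partially recovered tissue at any coupling
# interval.
.block_segment <- function(config, width = 10, gap = 0) {
  if (is.null(config$bz_range)) stop("conduction-block protocol needs a BZ")
  seg <- (config$bz_range[1] - gap - width):(config$bz_range[1] - gap - 1)
  if (min(seg) < 1) stop("fiber too short for the conduction-block segment")
  seg
}

.pvc_segment <- function(config, width = 10) {
  ctr <- if (!is.null(config$bz_range)) {
    round(mean(config$bz_range))
  } else round(config$n_cells / 2)
  lo <- ctr - floor(width / 2)
  lo:(lo + width - 1)
}

# Shared CI scan.
.scan_cis <- function(prepace, s2_segment, cis, after, tail_ms) {
  cats <- character(length(cis))
  for (k in seq_along(cis)) {
    rec <- apply_s2(prepace, s2_segment, cis[k], after = after,
                    tail_ms = tail_ms)
    cats[k] <- classify_outcome(rec)$category
  }
  data.frame(ci_ms = cis, category = cats)
}

#' Scan the vulnerable window for conduction block
#'
#' Delivers S2 stimuli to a segment of non-infarcted tissue adjacent to the
#' border zone over a contiguous grid of coupling intervals, after the beat
#' with the long APD during alternans, and classifies every outcome. The
#' block window is the CI range producing `BZ_BLOCK`.
#'
#' @param prepace a `fiber_recording` from [run_prepace()].
#' @param ci_range two-element vector of scan bounds, ms.
#' @param step scan step, ms (1 ms default).
#' @param s2_segment stimulated cells; default 10 cells of proximal NZ
#'   near the BZ.
#' @param after which pre-paced beat the S2 follows (`"long"` by default:
#'   block is probed after the long-APD alternans beat).
#' @param tail_ms post-S2 integration time, ms.
#' @return An object of class `vulnerability_result`: the scan table, the
#'   `block_window` (`c(lo, hi)` or `NULL`), `min_full_ci`, and a
#'   `scan_truncated` flag set when the scan top never reaches full
#'   propagation.
#' @export
scan_block_window <- function(prepace, ci_range = c(150, 250), step = 1,
                              s2_segment = NULL, after = "long",
                              tail_ms = 500) {
  stopifnot(inherits(prepace, "fiber_recording"))
  config <- prepace$config
  if (is.null(s2_segment)) s2_segment <- .block_segment(config)
  cis <- seq(ci_range[1], ci_range[2], by = step)
  scan <- .scan_cis(prepace, s2_segment, cis, after, tail_ms)
  blocked <- scan$ci_ms[scan$category == "BZ_BLOCK"]
  full <- scan$ci_ms[scan$category == "FULL_PROPAGATION"]
  res <- structure(list(
    scan = scan, protocol = "conduction_block",
    s2_segment = s2_segment, after = after,
    block_window = if (length(blocked)) range(blocked) else NULL,
    min_full_ci = if (length(full)) min(full) else Inf,
    scan_truncated = !length(full) ||
      scan$category[nrow(scan)] != "FULL_PROPAGATION",
    ordered = .scan_ordered(scan$category)
  ), class = "vulnerability_result")
  if (res$scan_truncated) {
    warning("scan range ends before full propagation; widen ci_range")
  }
  res
}

# TRUE when the categories along increasing ci follow
# NO_PROPAGATION* -> BZ_BLOCK* -> FULL_PROPAGATION* without interleaving.
.scan_ordered <- function(categories) {
  lev <- c(NO_PROPAGATION = 1, BZ_BLOCK = 2, FULL_PROPAGATION = 3)
  !is.unsorted(lev[categories])
}

#' Minimum coupling interval with a propagating premature complex
#'
#' Mimics a premature ventricular complex: the S2 is delivered inside the
#' border zone (fiber interior for a homogeneous fiber) after the beat with
#' the short APD during alternans, and the coupling interval is scanned
#' linearly on a 1 ms grid. The result is the smallest CI whose activation
#' propagates in both directions past the fiber-end sentinels
#' (`FULL_PROPAGATION`); monotonicity of the outcome sequence is verified,
#' not assumed.
#'
#' @inheritParams scan_block_window
#' @param s2_segment stimulated cells; default 10 cells centered in the BZ.
#' @param after which pre-paced beat the S2 follows (`"short"` by default).
#' @return A `vulnerability_result` whose `min_full_ci` is the minimum
#'   propagating CI (`Inf` sentinel when no CI in range propagates).
#' @export
min_propagating_ci <- function(prepace, ci_range = c(150, 250), step = 1,
                               s2_segment = NULL, after = "short",
                               tail_ms = 500) {
  stopifnot(inherits(prepace, "fiber_recording"))
  config <- prepace$config
  if (is.null(s2_segment)) s2_segment <- .pvc_segment(config)
  if (config$composition == "NZ only") after <- "last"
  cis <- seq(ci_range[1], ci_range[2], by = step)
  scan <- .scan_cis(prepace, s2_segment, cis, after, tail_ms)
  full <- scan$ci_ms[scan$category == "FULL_PROPAGATION"]
  structure(list(scan = scan, protocol = "pvc", s2_segment = s2_segment,
                 after = after,
                 block_window = NULL,
                 min_full_ci = if (length(full)) min(full) else Inf,
                 scan_truncated = !length(full),
                 ordered = .scan_ordered(scan$category)),
            class = "vulnerability_result")
}

#' @export
print.vulnerability_result <- function(x, ...) {
  cat(sprintf("<vulnerability_result> protocol=%s, scan %g-%g ms\n",
              x$protocol, min(x$scan$ci_ms), max(x$scan$ci_ms)))
  if (!is.null(x$block_window)) {
    cat(sprintf("  conduction-block window: %g-%g ms\n",
                x$block_window[1], x$block_window[2]))
  } else if (x$protocol == "conduction_block") {
    cat("  conduction-block window: empty\n")
  }
  cat(sprintf("  minimum fully propagating ci: %g ms\n", x$min_full_ci))
  if (!x$ordered) cat("  WARNING: outcome sequence not monotone along ci\n")
  invisible(x)
}

# Table of the five standard fiber configurations compared in the premature
# complex protocol: paced at 300 or 400 ms, with and without a border zone,
# and with full beta-adrenergic stimulation.
.std_fibers <- list(
  A = list(bcl = 300, composition = "NZ-BZ-NZ", bar = 0),
  B = list(bcl = 300, composition = "NZ only", bar = 0),
  C = list(bcl = 400, composition = "NZ-BZ-NZ", bar = 0),
  D = list(bcl = 400, composition = "NZ only", bar = 0),
  E = list(bcl = 300, composition = "NZ-BZ-NZ", bar = 1)
)

#' Premature-complex vulnerability across the standard fiber set
#'
#' Runs the full pipeline (pre-pacing then the PVC coupling-interval scan)
#' for the five standard fibers: A (bcl 300 ms, NZ-BZ-NZ, no stimulation),
#' B (300, NZ only, 0), C (400, NZ-BZ-NZ, 0), D (400, NZ only, 0) and
#' E (300, NZ-BZ-NZ, full beta-adrenergic stimulation), and tabulates the
#' shortest coupling interval with a propagating S2 for each.
#'
#' @param fibers character vector of fiber ids to run (subset of A-E).
#' @param n_cells,n_prepace fiber size and pre-pacing depth (passed to
#'   [fiber_config()]).
#' @param ci_range,step CI scan bounds and step, ms.
#' @param ... further arguments passed to [fiber_config()].
#' @return A data.frame with columns `fiber_id`, `bcl_ms`, `composition`,
#'   `bar_level`, `min_ci_ms` (`NA` for a fiber whose pre-pace or scan
#'   failed, with the message in `note`).
#' @export
table2_harness <- function(fibers = names(.std_fibers), n_cells = 240,
                           n_prepace = 500, ci_range = c(150, 250),
                           step = 1, ...) {
  bad <- setdiff(fibers, names(.std_fibers))
  if (length(bad)) {
    stop(sprintf("unknown fiber id(s) %s; valid ids: %s",
                 paste(bad, collapse = ", "),
                 paste(names(.std_fibers), collapse = ", ")))
  }
  rows <- lapply(fibers, function(id) {
    f <- .std_fibers[[id]]
    row <- data.frame(fiber_id = id, bcl_ms = f$bcl,
                      composition = f$composition, bar_level = f$bar,
                      min_ci_ms = NA_real_, note = "")
    res <- tryCatch({
      cfg <- fiber_config(n_cells = n_cells, composition = f$composition,
                          bcl = f$bcl, n_prepace = n_prepace,
                          bar_level = f$bar, ...)
      pp <- run_prepace(cfg)
      min_propagating_ci(pp, ci_range = ci_range, step = step)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$note <- conditionMessage(res)
    } else {
      row$min_ci_ms <- if (is.finite(res$min_full_ci)) res$min_full_ci else NA
      if (!is.finite(res$min_full_ci)) row$note <- "no propagating ci in range"
    }
    row
  })
  do.call(rbind, rows)
}
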