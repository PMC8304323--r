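#' Region-of-interest labels
#'
#' The six cortical regions covered by the montage: left and right
#' dorsolateral prefrontal cortex (LDLPFC, RDLPFC), medial prefrontal cortex
#' (MPFC), left and right premotor cortex (LPM, RPM), and the supplementary
#' motor area (SMA).
#'
#' @return Character vector of the 6 ROI labels, in canonical order.
#' @export
roi_labels <- function() {
  c("LDLPFC", "RDLPFC", "MPFC", "LPM", "RPM", "SMA")
}

#' Construct a probe layout
#'
#' A probe layout describes the 21 measurement channels formed by an
#' 8-source / 8-detector montage and assigns each channel to one region of
#' interest. The channel -> ROI assignment is configuration, not code: the
#' packaged default can be replaced by any CSV with columns
#' `channel,source,detector,roi` (see [read_layout()]).
#'
#' @param channels Data frame with integer columns `channel`, `source`,
#'   `detector` and a character column `roi`.
#' @return A `probe_layout` object (a validated data frame).
#' @seealso [default_layout()], [validate_layout()], [channel_pairs()]
#' @export
probe_layout <- function(channels) {
  req <- c("channel", "source", "detector", "roi")
  if (!all(req %in% names(channels))) {
    stop_invalid("layout", paste("missing column(s):",
                                 paste(setdiff(req, names(channels)), collapse = ", ")))
  }
  layout <- as.data.frame(channels)[, req]
  layout$channel <- as.integer(layout$channel)
  layout$source <- as.integer(layout$source)
  layout$detector <- as.integer(layout$detector)
  layout$roi <- as.character(layout$roi)
  layout <- layout[order(layout$channel), , drop = FALSE]
  rownames(layout) <- NULL
  class(layout) <- c("probe_layout", "data.frame")
  validate_layout(layout)
}

#' The packaged default 21-channel layout
#'
#' Reads the layout shipped in `inst/extdata/probe_layout.csv`: 21 channels
#' over 8 sources and 8 detectors, assigned to the six ROIs with
#' LDLPFC/RDLPFC/LPM/RPM 4 channels each, MPFC 3 and SMA 2.
#'
#' @return A `probe_layout`.
#' @export
default_layout <- function() {
  path <- system.file("extdata", "probe_layout.csv", package = "nirslearn",
                      mustWork = TRUE)
  read_layout(path)
}

#' Read a probe layout from CSV
#'
#' @param path CSV file with header `channel,source,detector,roi`.
#' @return A validated `probe_layout`.
#' @export
read_layout <- function(path) {
  probe_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a probe layout
#'
#' Checks the layout invariants: exactly 21 channels numbered 1..21, source
#' and detector ids within 1..8, every channel assigned to exactly one of the
#' six ROI labels, and every ROI populated. The first violated invariant is
#' reported.
#'
#' @param layout A `probe_layout` (or coercible data frame).
#' @return The layout, unchanged, if valid.
#' @export
validate_layout <- function(layout) {
  if (nrow(layout) != 21L) {
    stop_invalid("layout", sprintf("expected exactly 21 channels, got %d", nrow(layout)))
  }
  if (!identical(sort(layout$channel), 1:21)) {
    stop_invalid("layout", "channel ids must be exactly 1..21")
  }
  if (any(layout$source < 1L | layout$source > 8L)) {
    stop_invalid("layout", "source ids must lie in 1..8")
  }
  if (any(layout$detector < 1L | layout$detector > 8L)) {
    stop_invalid("layout", "detector ids must lie in 1..8")
  }
  bad <- setdiff(unique(layout$roi), roi_labels())
  if (length(bad)) {
    stop_invalid("layout", paste("unknown ROI label(s):", paste(bad, collapse = ", ")))
  }
  missing_roi <- setdiff(roi_labels(), unique(layout$roi))
  if (length(missing_roi)) {
    stop_invalid("layout", paste("ROI(s) with no channel:",
                                 paste(missing_roi, collapse = ", ")))
  }
  layout
}

#' ROI of each channel
#'
#' @param layout A `probe_layout`.
#' @return Named character vector mapping channel id to ROI label.
#' @export
roi_of <- function(layout) {
  stats::setNames(layout$roi, layout$channel)
}

#' All unordered channel pairs
#'
#' Enumerates the C(n, 2) unordered channel pairs in deterministic
#' lexicographic order (i < j), the order in which the HbO connectivity
#' features are laid out. For the 21-channel layout this yields 210 pairs.
#'
#' @param layout A `probe_layout`, or an integer vector of channel ids.
#' @return Two-column integer matrix with columns `a`, `b` (a < b).
#' @export
channel_pairs <- function(layout) {
  ids <- if (inherits(layout, "probe_layout")) layout$channel else as.integer(layout)
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2L) stop_invalid("layout", "need at least 2 channels to form pairs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  cbind(a = ids[idx[, 1L]], b = ids[idx[, 2L]])
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d channels, %d ROIs\n",
              nrow(x), length(unique(x$roi))))
  counts <- table(factor(x$roi, levels = roi_labels()))
  cat("  ", paste(sprintf("%s:%d", names(counts), counts), collapse = "  "), "\n")
  invisible(x)
}
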