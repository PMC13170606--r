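#' fNIRS optode montage
#'
#' Describes the set of source-detector channels of a prefrontal fNIRS
#' montage. The default is an 8-source x 8-detector headband layout with 20
#' plausible source-detector pairs separated by 30-35 mm, including the four
#' channels reported to show training-related changes (S3-D2, S3-D5, S5-D4,
#' S5-D5). Region labels are opaque annotations.
#'
#' @param channels data frame with columns `source`, `detector`,
#'   `separation_mm` and optionally `region`.
#' @return Object of class `fnirs_montage`.
#' @export
fnirs_montage <- function(channels) {
  stopifnot(all(c("source", "detector", "separation_mm") %in% names(channels)))
  if (!"region" %in% names(channels)) channels$region <- NA_character_
  channels$label <- sprintf("S%d-D%d", channels$source, channels$detector)
  if (anyDuplicated(channels$label))
    stop("channel labels must be unique")
  if (any(channels$separation_mm < 25 | channels$separation_mm > 45))
    stop("source-detector separations outside a plausible 25-45 mm range")
  structure(list(channels = channels,
                 n_sources = max(channels$source),
                 n_detectors = max(channels$detector)),
            class = "fnirs_montage")
}

#' @rdname fnirs_montage
#' @param labels optional subset of channel labels to keep.
#' @export
default_montage <- function(labels = NULL) {
  ch <- data.frame(
    source   = c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 5, 5, 5, 6, 6, 7, 7, 8, 8, 4),
    detector = c(1, 2, 1, 2, 3, 2, 5, 3, 3, 4, 4, 5, 6, 5, 6, 6, 7, 7, 8, 8),
    separation_mm = c(30, 32, 31, 33, 30, 32, 34, 31, 30, 33,
                      32, 35, 31, 30, 34, 32, 31, 33, 30, 35),
    region = c(rep("rdlPFC", 5), "l-dlPFC", "l-dlPFC", "rdlPFC", "rdlPFC",
               "dmPFC", "dmPFC", "l-dlPFC", "dmPFC", rep("frontal", 7))
  )
  m <- fnirs_montage(ch)
  if (!is.null(labels)) {
    keep <- m$channels$label %in% labels
    if (!all(labels %in% m$channels$label))
      stop("unknown channel label(s): ",
           paste(setdiff(labels, m$channels$label), collapse = ", "))
    m$channels <- m$channels[keep, , drop = FALSE]
  }
  m
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf("fNIRS montage: %d channels (%d sources, %d detectors), %g-%g mm\n",
              nrow(x$channels), x$n_sources, x$n_detectors,
              min(x$channels$separation_mm), max(x$channels$separation_mm)))
  invisible(x)
}
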