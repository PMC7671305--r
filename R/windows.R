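#' Sliding-window grid along read coordinates
#'
#' Defaults reproduce the 1 kbp windows with 0.5 kbp overlap over read
#' positions 1-7500 used for 5'-noise profiling: 14 windows starting at
#' 1, 501, ..., 6501, restricted to reads of at least 7500 bp.
#'
#' @param window_length window size (bp)
#' @param step distance between window starts (bp); `step < window_length`
#'   gives overlapping windows
#' @param region_end last read position considered (bp)
#' @param min_read_length reads shorter than this are excluded
#' @return an object of class `window_grid`
#' @export
window_grid <- function(window_length = 1000L, step = 500L,
                        region_end = 7500L, min_read_length = 7500L) {
  window_length <- as.integer(window_length); step <- as.integer(step)
  region_end <- as.integer(region_end)
  if (!(step > 0L && step <= window_length && window_length <= region_end))
    stop_usage("window grid requires 0 < step <= window_length <= region_end")
  starts <- seq.int(1L, region_end - window_length + 1L, by = step)
  structure(list(window_length = window_length, step = step,
                 region_end = region_end,
                 min_read_length = as.integer(min_read_length),
                 starts = starts, ends = starts + window_length - 1L),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %d bp, step %d, positions 1-%d, reads >= %d bp\n",
              length(x$starts), x$window_length, x$step, x$region_end,
              x$min_read_length))
  invisible(x)
}

# Assign every column a read position: match/sub/ins use their own
# read_pos; a deletion column takes the read_pos of the next non-deletion
# column in ORIGINAL read orientation (previous one for terminal
# deletions). Orientation-aware so the assignment is strand-invariant.
assign_read_pos <- function(script) {
  p <- script$columns$read_pos
  if (!anyNA(p)) return(p)
  if (identical(script$strand, "reverse")) p <- rev(p)
  # fill NA runs from the following value, falling back to the preceding one
  n <- length(p)
  idx <- which(!is.na(p))
  nxt <- rep(NA_integer_, n)
  nxt[idx] <- idx
  nxt <- rev(cummin(rev(replace(nxt, is.na(nxt), n + 1L))))
  nxt[nxt > n] <- NA_integer_
  filled <- p
  take <- is.na(p) & !is.na(nxt)
  filled[take] <- p[nxt[take]]
  if (anyNA(filled)) {            # terminal deletions: use previous value
    prv <- cummax(ifelse(is.na(p), 0L, seq_len(n)))
    miss <- which(is.na(filled))
    filled[miss] <- p[prv[miss]]
  }
  if (identical(script$strand, "reverse")) filled <- rev(filled)
  filled
}

#' Per-read windowed error rates
#'
#' For one read's edit script, computes the percentage of columns of each
#' error type within every window of `grid`, in original-read coordinates.
#' The window denominator is ALL columns assigned to the window (including
#' deletion columns attached to their neighboring read base).
#'
#' @param script an `edit_script`
#' @param grid a [window_grid()]
#' @return a numeric matrix (windows x 3, columns `sub`, `ins`, `del`), or
#'   `NULL` if the read is shorter than `grid$min_read_length`
#' @export
per_read_window_rates <- function(script, grid) {
  if (script$read_length < grid$min_read_length) return(NULL)
  pos <- assign_read_pos(script)
  op <- script$columns$op
  keep <- !is.na(pos) & pos <= grid$region_end
  pos <- pos[keep]; op <- op[keep]
  nw <- length(grid$starts)
  out <- matrix(NA_real_, nw, 3, dimnames = list(NULL, c("sub", "ins", "del")))
  for (w in seq_len(nw)) {
    sel <- pos >= grid$starts[w] & pos <= grid$ends[w]
    denom <- sum(sel)
    if (denom == 0L) { out[w, ] <- 0; next }
    ow <- op[sel]
    out[w, ] <- 100 * c(sum(ow == "sub"), sum(ow == "ins"),
                        sum(ow == "del")) / denom
  }
  out
}

#' Windowed error-rate distribution of a read set
#'
#' Per window and error type, the mean and sample standard deviation
#' (n - 1 denominator) of per-read window rates over all qualifying reads
#' (read length >= `grid$min_read_length`). This is a per-read-then-average
#' summary: the error bars describe read-to-read spread per window.
#'
#' @param scripts list of `edit_script` objects
#' @param grid a [window_grid()]
#' @return a `data.frame` of class `window_distribution` with columns
#'   `error_type`, `window_start`, `window_end`, `n_reads`, `mean_pct`,
#'   `stddev_pct`; attribute `n_skipped` counts too-short reads
#' @export
window_distribution <- function(scripts, grid = window_grid()) {
  mats <- lapply(scripts, per_read_window_rates, grid = grid)
  skipped <- sum(vapply(mats, is.null, TRUE))
  mats <- mats[!vapply(mats, is.null, TRUE)]
  n <- length(mats)
  if (n == 0L) stop_usage("no read reaches min_read_length = %d",
                          grid$min_read_length)
  if (n < 2L)
    warning("fewer than 2 qualifying reads: stddev reported as NA",
            call. = FALSE)
  nw <- length(grid$starts)
  rows <- vector("list", 3L)
  for (t in c("sub", "ins", "del")) {
    vals <- vapply(mats, function(m) m[, t], numeric(nw))
    vals <- matrix(vals, nrow = nw)
    rows[[t]] <- data.frame(
      error_type = t, window_start = grid$starts, window_end = grid$ends,
      n_reads = n,
      mean_pct = rowMeans(vals),
      stddev_pct = if (n >= 2L) apply(vals, 1, sd) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  class(out) <- c("window_distribution", "data.frame")
  out
}

#' Write a window distribution as TSV
#'
#' @param wd a [window_distribution()] result
#' @param path output path
#' @param dataset dataset label written in the first column
#' @export
write_window_tsv <- function(wd, path, dataset = "dataset") {
  tab <- cbind(dataset = dataset, as.data.frame(wd))
  tab$mean_pct <- round(tab$mean_pct, 4)
  tab$stddev_pct <- round(tab$stddev_pct, 4)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
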