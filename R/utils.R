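#' @keywords internal
"_PACKAGE"

#' @importFrom stats rlnorm rgeom runif sd setNames
#' @importFrom utils write.table read.delim head
NULL

BASES <- c("A", "C", "G", "T")

# Classed conditions so the CLI can map error families to exit codes.
stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("lrp_format_error", "lrp_error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("lrp_usage_error", "lrp_error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("lrp_validation_error", "lrp_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run expr with a seeded RNG, restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Complement of a character vector of single bases (N and NA pass through).
comp_bases <- function(x) {
  c("T", "G", "C", "A", "N")[match(x, c("A", "C", "G", "T", "N"))]
}

# Reverse complement of whole sequence strings.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Split a sequence string into a character vector of bases.
explode <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# data.frame without the constructor's checking overhead (hot paths only;
# columns must be equal-length atomic vectors)
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
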