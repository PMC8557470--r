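#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats cor pnorm p.adjust quantile rbeta rbinom runif rnorm
#'   rexp median mad setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## format numeric columns at 6 significant digits for TSV output,
## leaving integers and non-numeric columns untouched
.fmt_num_cols <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.double(x)) df[[nm]] <- signif(x, 6L)
  }
  df
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Benjamini-Hochberg wrapper kept in one place so every module adjusts
## identically (NA-preserving).
.bh <- function(p) stats::p.adjust(p, method = "BH")

## 0-based half-open window index for 1-based positions
.window_index <- function(pos, window_bp) (pos - 1L) %/% as.integer(window_bp)

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
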