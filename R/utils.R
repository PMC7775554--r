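#' @keywords internal
"_PACKAGE"

#' @importFrom methods new validObject is
#' @importFrom stats lm coef rnorm rlnorm rexp rgeom runif pt aggregate
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    .stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# strand tokens used throughout: "+", "-", "unknown"
.normStrand <- function(s) {
  s <- as.character(s)
  s[is.na(s) | s == "." | s == "*" | s == ""] <- "unknown"
  bad <- !s %in% c("+", "-", "unknown")
  if (any(bad))
    .stopf("invalid strand value(s): %s", paste(unique(s[bad]), collapse = ", "))
  s
}
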