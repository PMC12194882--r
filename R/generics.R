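#' Turn package result objects into tidy tibbles
#'
#' \code{tidy()} returns per-element rows (tracks, pores), and
#' \code{glance()} a one-row summary, following the broom convention.
#' If broom is attached its generics dispatch to these methods too.
#'
#' @param x a result object.
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
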