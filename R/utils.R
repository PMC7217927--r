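# Internal helpers: classed conditions and numerics shared across the package.

vcn_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "vcn_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

vcn_warn <- function(message, class) {
  warning(structure(
    class = c(class, "vcn_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Variance-stabilizing transforms
#'
#' Monotone transforms applied to VCN measurements before Gaussian noise
#' modelling. `sqrt` is the default: for count-like quantities it makes the
#' replicate spread approximately independent of the copy number, and it maps
#' 0 to 0 so the half-normal likelihood for the zero-copy hypothesis sits
#' naturally at the origin.
#'
#' @param x numeric vector, non-negative.
#' @param transform one of `"sqrt"`, `"log1p"`, `"identity"`.
#' @return transformed numeric vector.
#' @export
vcn_transform <- function(x, transform = c("sqrt", "log1p", "identity")) {
  transform <- match.arg(transform)
  switch(transform,
    sqrt = sqrt(x),
    log1p = log1p(x),
    identity = x
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
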