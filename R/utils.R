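`%||%` <- function(x, y) if (is.null(x)) y else x

#' Heaviside step function with H(0) = 1
#'
#' Threshold gate used throughout the model (metabolic switch, angiogenesis
#' density gate, stiffness crowding term). Ties are resolved toward the
#' "resource sufficient" branch, i.e. `H(0) = 1`.
#'
#' @param x Numeric vector, matrix or array.
#' @return Numeric object of the same shape with values in \{0, 1\}.
#' @export
#' @examples
#' heaviside(c(-1, 0, 2))
heaviside <- function(x) {
  out <- as.numeric(x >= 0)
  dim(out) <- dim(x)
  out
}

# Michaelis-Menten saturation x / (x + k), with the 0/0 case defined as 0.
mm_sat <- function(x, k) {
  r <- x / (x + k)
  r[x <= 0] <- 0
  dim(r) <- dim(x)
  r
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_nonneg <- function(x, name) {
  stop_if(any(!is.finite(x)), sprintf("'%s' must be finite", name))
  stop_if(any(x < 0), sprintf("'%s' must be non-negative", name))
  invisible(x)
}

same_dim <- function(a, b) identical(dim(a), dim(b))

zero_like <- function(m) matrix(0, nrow = nrow(m), ncol = ncol(m))
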