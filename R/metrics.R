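#' Relative l2-norm error
#'
#' The reconstruction-quality metric
#' \deqn{\mathrm{RLNE} = \|\hat{x} - x\|_2 / \|x\|_2,}
#' computed on complex entries (the solvers operate on complex images, so
#' phase errors count). Zero iff the images are identical; 1 for the zero
#' image.
#'
#' @param x_hat reconstructed complex image.
#' @param x_ref fully sampled reference image of the same shape.
#' @return nonnegative scalar.
#' @export
rlne <- function(x_hat, x_ref) {
  if (!all(dim(x_hat) == dim(x_ref))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  ref_norm <- sqrt(sum(Mod(x_ref)^2))
  if (ref_norm == 0) stop("reference image has zero norm", call. = FALSE)
  sqrt(sum(Mod(x_hat - x_ref)^2)) / ref_norm
}
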