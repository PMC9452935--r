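#' Receptive field of a dilated convolution
#'
#' Side length of the receptive field of a single \eqn{k \times k}
#' convolution with dilation rate \eqn{d}, computed as
#' \deqn{v = (k + 1)(d - 1) + k.}
#' This is the rule the network's design analysis uses: it gives
#' \eqn{v = k} at \eqn{d = 1} and \eqn{v = 7} for a 3x3 kernel at
#' \eqn{d = 2}. Note that it differs from the conventional effective
#' kernel size \eqn{k + (k - 1)(d - 1)} (which gives 5 for the same
#' case); the conventional rule is available as
#' [receptiveFieldConventional()] for comparison.
#'
#' @param k odd positive kernel size.
#' @param d positive integer dilation rate.
#' @return the receptive-field side \eqn{v}, a positive integer.
#' @examples
#' receptiveField(3, 1) # 3: dilation 1 is an ordinary convolution
#' receptiveField(3, 2) # 7
#' @export
receptiveField <- function(k, d) {
  .checkKD(k, d)
  (k + 1) * (d - 1) + k
}

#' Conventional effective kernel size of a dilated convolution
#'
#' The standard effective-kernel-size rule \eqn{k + (k - 1)(d - 1)}:
#' the span of a \eqn{k \times k} kernel whose taps are spaced \eqn{d}
#' pixels apart. Exposed alongside [receptiveField()] so the two
#' conventions can be compared directly.
#'
#' @inheritParams receptiveField
#' @return the effective kernel side, a positive integer.
#' @examples
#' receptiveFieldConventional(3, 2) # 5
#' @export
receptiveFieldConventional <- function(k, d) {
  .checkKD(k, d)
  k + (k - 1) * (d - 1)
}

.checkKD <- function(k, d) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k %% 2 != 1)
    stop("k must be a positive odd kernel size", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || d < 1)
    stop("d must be a positive dilation rate", call. = FALSE)
  invisible(TRUE)
}
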