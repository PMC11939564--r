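#' Cross-coupled feature fusion
#'
#' Builds the stage-2 input vectors from a stage-1 feature bundle. The
#' systolic matrix appends the *diastolic* preliminary estimate to the
#' systolic features, and vice versa — the cross pairing exploits the strong
#' physiological coupling between systolic and diastolic pressure. The
#' appended estimate is scaled by 1/200 so its magnitude matches the
#' unit-norm features.
#'
#' @param bundle list with `F_S`, `F_D` (`n x B` feature matrices) and
#'   `y_S`, `y_D` (length-B preliminary estimates in mmHg), as returned by
#'   [resnet_forward()].
#' @param fusion logical; `FALSE` gives the no-fusion ablation in which
#'   `X_S = F_S` and `X_D = F_D` (length n instead of n + 1).
#' @return list with matrices `X_S`, `X_D` of dim `(n + fusion) x B`.
#' @export
fuse <- function(bundle, fusion = TRUE) {
  stopifnot(!is.null(bundle$F_S), !is.null(bundle$F_D))
  if (!fusion) {
    return(list(X_S = bundle$F_S, X_D = bundle$F_D))
  }
  if (is.null(bundle$y_S) || is.null(bundle$y_D)) {
    stop("preliminary predictions missing; cannot fuse")
  }
  list(X_S = rbind(bundle$F_S, matrix(bundle$y_D * BP_SCALE, 1)),
       X_D = rbind(bundle$F_D, matrix(bundle$y_S * BP_SCALE, 1)))
}
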