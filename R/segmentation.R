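#' Abnormality response map
#'
#' The response of pixel `j` is the Euclidean norm of the `j`-th column of the
#' abnormality matrix `E*`: `T(x_j) = sqrt(sum_i e*_ij^2)`. Large responses
#' indicate pixels that the background dictionary cannot represent, i.e.
#' lesion candidates.
#'
#' @param E_star Abnormality matrix from [solve_jclrrsr()], one column per
#'   scored pixel.
#' @param pixel_index Data frame with `row`, `col` (as produced by
#'   [extract_features()]), one entry per column of `E_star`.
#' @param dim Image dimensions `c(H, W)`.
#' @return An object of class `response_map` with `scores` (an `H x W` matrix,
#'   `NA` at unscored pixels), `values` (the per-column responses) and
#'   `pixel_index`.
#' @export
response_map <- function(E_star, pixel_index, dim) {
  E_star <- as.matrix(E_star)
  if (nrow(pixel_index) != ncol(E_star))
    stop("response_map: pixel_index rows must match E_star columns",
         call. = FALSE)
  values <- sqrt(colSums(E_star^2))
  scores <- matrix(NA_real_, dim[1], dim[2])
  scores[cbind(pixel_index$row, pixel_index$col)] <- values
  structure(list(scores = scores, values = values,
                 pixel_index = pixel_index, dim = dim),
            class = "response_map")
}

# Otsu threshold of a score vector on a 256-bin histogram.
#' @noRd
otsu_threshold_ <- function(v, levels = 256L) {
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = range(v),
                levels = levels)
}

#' Threshold a response map into a lesion mask
#'
#' Pixels whose response strictly exceeds the threshold are lesion; ties are
#' background. The default threshold is Otsu's method on a 256-bin histogram
#' of the scored (in-brain) responses; `"quantile"` uses the `param`-quantile
#' of the responses and `"fixed"` uses `param` directly.
#'
#' @param rmap A [response_map()].
#' @param method `"otsu"`, `"quantile"` or `"fixed"`.
#' @param param Quantile in `[0, 1]` or fixed threshold, depending on
#'   `method`.
#' @return An object of class `lesion_map`: logical `mask`, `threshold`,
#'   `method`.
#' @export
threshold_response <- function(rmap, method = c("otsu", "quantile", "fixed"),
                               param = NULL) {
  stopifnot(inherits(rmap, "response_map"))
  method <- match.arg(method)
  v <- rmap$values
  if (length(v) == 0L) stop("threshold_response: empty response map",
                            call. = FALSE)
  t <- switch(method,
    otsu = {
      if (diff(range(v)) == 0) {
        warning("threshold_response: all responses equal; empty mask")
        max(v)
      } else {
        otsu_threshold_(v)
      }
    },
    quantile = {
      if (is.null(param) || param < 0 || param > 1)
        stop("threshold_response: quantile 'param' must be in [0, 1]",
             call. = FALSE)
      as.numeric(stats::quantile(v, param))
    },
    fixed = {
      if (is.null(param))
        stop("threshold_response: 'param' required for fixed threshold",
             call. = FALSE)
      as.numeric(param)
    })
  mask <- !is.na(rmap$scores) & rmap$scores > t
  structure(list(mask = mask, threshold = t, method = method),
            class = "lesion_map")
}

#' Restrict a lesion mask to the brain and drop small components
#'
#' Intersects the mask with the brain mask (detections outside brain tissue
#' are discarded) and optionally (i) erodes the brain mask by `shrink` pixels
#' first, removing detections whose patch neighborhood straddles the brain
#' boundary and therefore mixes tissue with background signal, and (ii)
#' removes connected components smaller than `min_size` pixels.
#'
#' @param lmap A [threshold_response()] result (or a logical matrix).
#' @param brain_mask Logical matrix on the same grid.
#' @param min_size Minimum connected-component size to retain; `0` (default)
#'   disables the filter.
#' @param shrink Brain-mask erosion radius in pixels (square structuring
#'   element); `0` (default) uses the mask as given. Set to the patch radius
#'   `(omega - 1) / 2` to drop boundary-contaminated detections.
#' @return A `lesion_map` with the cleaned mask.
#' @export
postprocess_mask <- function(lmap, brain_mask, min_size = 0L, shrink = 0L) {
  mask <- if (inherits(lmap, "lesion_map")) lmap$mask else lmap
  mask <- as.matrix(mask)
  brain_mask <- as.matrix(brain_mask)
  if (!identical(dim(mask), dim(brain_mask)))
    stop("postprocess_mask: grid mismatch", call. = FALSE)
  if (shrink > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(shrink) + 1L, "box")
    brain_mask <- as.matrix(EBImage::erode(EBImage::Image(brain_mask * 1),
                                           brush)) > 0
  }
  mask <- mask & brain_mask
  if (min_size > 0L && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_size])
    mask <- matrix(as.array(lab) %in% keep, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask,
                 threshold = if (inherits(lmap, "lesion_map"))
                   lmap$threshold else NA_real_,
                 method = if (inherits(lmap, "lesion_map"))
                   lmap$method else "external"),
            class = "lesion_map")
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |P intersect T| / (|P| + |T|)`. Two empty masks are in perfect
#' agreement by convention, giving 1.
#'
#' @param pred,truth Logical matrices (or `lesion_map` objects) on the same
#'   grid.
#' @return A number in `[0, 1]`.
#' @export
dice_score <- function(pred, truth) {
  p <- if (inherits(pred, "lesion_map")) pred$mask else as.matrix(pred)
  t <- if (inherits(truth, "lesion_map")) truth$mask else as.matrix(truth)
  if (!identical(dim(p), dim(t)))
    stop("dice_score: grid mismatch", call. = FALSE)
  p <- p != 0; t <- t != 0
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}
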