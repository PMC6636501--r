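#' Bundle aligned multisequence images into a stack
#'
#' @param volumes A list of `k` numeric matrices (2-D slices), all of the same
#'   dimensions, one per MR sequence.
#' @param sequence_names Character vector of length `k` (e.g. `c("T1", "T2",
#'   "FLAIR")`). Defaults to `S1..Sk`.
#' @param brain_mask Logical matrix of the same dimensions; defaults to all
#'   `TRUE`.
#' @return An object of class `sequence_stack`.
#' @export
sequence_stack <- function(volumes, sequence_names = NULL, brain_mask = NULL) {
  if (!is.list(volumes) || length(volumes) < 1L)
    stop("sequence_stack: 'volumes' must be a nonempty list of matrices",
         call. = FALSE)
  volumes <- lapply(volumes, as.matrix)
  dims <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), dims), logical(1))))
    stop("sequence_stack: all sequences must share the same dimensions",
         call. = FALSE)
  k <- length(volumes)
  if (is.null(sequence_names)) sequence_names <- paste0("S", seq_len(k))
  if (length(sequence_names) != k)
    stop("sequence_stack: need one name per sequence", call. = FALSE)
  if (is.null(brain_mask)) brain_mask <- matrix(TRUE, dims[1], dims[2])
  brain_mask <- matrix(as.logical(brain_mask), dims[1], dims[2])
  if (!identical(dim(brain_mask), dims))
    stop("sequence_stack: mask dimensions must match the images",
         call. = FALSE)
  names(volumes) <- sequence_names
  structure(list(volumes = volumes, sequence_names = sequence_names,
                 brain_mask = brain_mask, dim = dims),
            class = "sequence_stack")
}

#' Rescale image intensities to the range 0-255
#'
#' Linear min-max rescaling applied per sequence:
#' `255 * (I - min I) / (max I - min I)`. A constant image cannot be rescaled
#' and is returned as all zeros with a warning.
#'
#' @param image A numeric matrix or array with finite entries.
#' @return The rescaled image, same shape, values in `[0, 255]`.
#' @export
normalize_intensity <- function(image) {
  if (!all(is.finite(image)))
    stop("normalize_intensity: non-finite entries", call. = FALSE)
  r <- range(image)
  if (r[1] == r[2]) {
    warning("normalize_intensity: constant image, returning zeros")
    return(image * 0)
  }
  255 * (image - r[1]) / (r[2] - r[1])
}

#' Patch extraction settings
#'
#' @param omega Odd patch side length (pixels), `>= 1`. Neighborhoods are
#'   `omega x omega` within a slice.
#' @param padding Border handling: `"mirror"` reflects about the border pixel,
#'   `"replicate"` repeats it.
#' @return A list of class `patch_config`.
#' @export
patch_config <- function(omega = 7L, padding = c("mirror", "replicate")) {
  padding <- match.arg(padding)
  omega <- as.integer(omega)
  if (is.na(omega) || omega < 1L || omega %% 2L == 0L)
    stop("patch_config: 'omega' must be odd and >= 1", call. = FALSE)
  structure(list(omega = omega, padding = padding), class = "patch_config")
}

# Out-of-range index mapping for padded neighborhoods.
#' @noRd
pad_index <- function(i, n, padding) {
  # mirror: reflect about the border (border pixel not duplicated);
  # replicate: clamp to the border.
  if (padding == "replicate") return(pmin(pmax(i, 1L), n))
  j <- i
  for (rep in 1:4) {          # omega << n, a few reflections suffice
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
  }
  if (any(j < 1L | j > n))
    stop("pad_index: patch larger than image", call. = FALSE)
  j
}

#' Extract multisequence patch features
#'
#' For each requested pixel, the `omega x omega` neighborhood in every
#' sequence is flattened in a row-major scan (patch rows, then columns) and
#' the per-sequence vectors are concatenated in `sequence_names` order,
#' giving a feature vector of length `k * omega^2`. Columns are ordered by a
#' row-major scan of the pixels.
#'
#' @param stack A [sequence_stack()]; intensities are expected on the 0-255
#'   scale (see [normalize_intensity()]).
#' @param config A [patch_config()].
#' @param pixels Optional integer matrix with columns `(row, col)` selecting
#'   the pixels to featurize; defaults to every in-mask pixel.
#' @param unit_norm Scale every feature column to unit Euclidean norm. Off by
#'   default (features stay in rescaled intensity units); when used, the same
#'   setting must be applied to the dictionary, which [segment_lesions()]
#'   enforces through the dictionary metadata.
#' @return An object of class `feature_matrix` with fields `Y`
#'   (`k * omega^2 x M`), `pixel_index` (data frame `slice`, `row`, `col`),
#'   `omega`, `k`, `sequence_names` and `unit_norm`.
#' @export
extract_features <- function(stack, config = patch_config(), pixels = NULL,
                             unit_norm = FALSE) {
  stopifnot(inherits(stack, "sequence_stack"),
            inherits(config, "patch_config"))
  H <- stack$dim[1]; W <- stack$dim[2]
  omega <- config$omega
  if (is.null(pixels)) {
    coords <- which(stack$brain_mask, arr.ind = TRUE)
    coords <- coords[order(coords[, 1], coords[, 2]), , drop = FALSE]
  } else {
    coords <- as.matrix(pixels)[, 1:2, drop = FALSE]
    storage.mode(coords) <- "integer"
    if (any(coords[, 1] < 1L | coords[, 1] > H |
            coords[, 2] < 1L | coords[, 2] > W))
      stop("extract_features: pixel outside image", call. = FALSE)
    if (!all(stack$brain_mask[coords]))
      stop("extract_features: pixel outside brain mask", call. = FALSE)
  }
  M <- nrow(coords)
  if (M == 0L) stop("extract_features: no pixels to featurize", call. = FALSE)
  if (anyDuplicated(coords))
    stop("extract_features: duplicate pixels", call. = FALSE)
  k <- length(stack$volumes)
  p <- (omega - 1L) %/% 2L
  Y <- matrix(0, k * omega^2, M)
  offs <- expand.grid(dc = -p:p, dr = -p:p)      # row-major patch scan
  offs <- offs[order(offs$dr, offs$dc), ]
  for (s in seq_len(k)) {
    img <- stack$volumes[[s]]
    for (o in seq_len(omega^2)) {
      rr <- pad_index(coords[, 1] + offs$dr[o], H, config$padding)
      cc <- pad_index(coords[, 2] + offs$dc[o], W, config$padding)
      Y[(s - 1L) * omega^2 + o, ] <- img[cbind(rr, cc)]
    }
  }
  if (unit_norm) {
    nrm <- sqrt(colSums(Y^2))
    nrm[nrm == 0] <- 1
    Y <- Y * rep(1 / nrm, each = nrow(Y))
  }
  structure(list(Y = Y,
                 pixel_index = data.frame(slice = 1L, row = coords[, 1],
                                          col = coords[, 2]),
                 omega = omega, k = k,
                 sequence_names = stack$sequence_names,
                 unit_norm = unit_norm,
                 dim = stack$dim),
            class = "feature_matrix")
}

#' Draw tissue-labelled training pixels for the background dictionary
#'
#' Samples pixel coordinates without replacement from a tissue label map,
#' split across white matter, grey matter and cerebrospinal fluid according
#' to `ratio` (default 3:1:1, reflecting the larger area of white matter);
#' integer remainders are assigned to WM. Pixels covered by `lesion_mask`
#' are never selected.
#'
#' @param label_map Character matrix with entries `"WM"`, `"GM"`, `"CSF"` for
#'   in-brain pixels and `NA` elsewhere.
#' @param total Total number of training samples `S`.
#' @param ratio Numeric length-3 vector of WM:GM:CSF proportions.
#' @param seed Integer seed making the draw reproducible.
#' @param lesion_mask Optional logical matrix of pixels to exclude.
#' @return An object of class `tissue_sample_set`: a data frame with columns
#'   `row`, `col`, `label` (WM block first, then GM, then CSF) and the seed
#'   as an attribute.
#' @export
sample_tissue_pixels <- function(label_map, total, ratio = c(3, 1, 1),
                                 seed = 1L, lesion_mask = NULL) {
  label_map <- as.matrix(label_map)
  if (length(ratio) != 3L || any(ratio <= 0))
    stop("sample_tissue_pixels: 'ratio' must be 3 positive numbers",
         call. = FALSE)
  total <- as.integer(total)
  if (total < 3L) stop("sample_tissue_pixels: 'total' too small",
                       call. = FALSE)
  if (!is.null(lesion_mask)) label_map[as.logical(lesion_mask)] <- NA
  n_gm <- as.integer(floor(total * ratio[2] / sum(ratio)))
  n_csf <- as.integer(floor(total * ratio[3] / sum(ratio)))
  n_wm <- total - n_gm - n_csf
  counts <- c(WM = n_wm, GM = n_gm, CSF = n_csf)
  out <- vector("list", 3L)
  with_seed_(seed, {
    for (i in seq_along(counts)) {
      lab <- names(counts)[i]
      cand <- which(label_map == lab, arr.ind = TRUE)
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      if (nrow(cand) < counts[i])
        stop(sprintf(
          "sample_tissue_pixels: class %s has %d labelled pixels, need %d",
          lab, nrow(cand), counts[i]), call. = FALSE)
      pick <- sample.int(nrow(cand), counts[i])
      out[[i]] <- data.frame(row = cand[pick, 1], col = cand[pick, 2],
                             label = lab)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("tissue_sample_set", "data.frame")
  res
}

#' Build the normal-tissue background dictionary
#'
#' Extracts the patch feature vector at every training-sample coordinate of a
#' lesion-free (or lesion-masked) reference stack. Atoms are ordered WM block,
#' GM block, CSF block, each in sampling order, giving a
#' `k * omega^2 x S` dictionary.
#'
#' @param stack A [sequence_stack()] of the normal reference image,
#'   intensity-rescaled to 0-255.
#' @param samples A [sample_tissue_pixels()] result.
#' @param config A [patch_config()].
#' @param unit_norm Scale atoms to unit norm (see [extract_features()]).
#' @return An object of class `background_dictionary` with fields `D`,
#'   `atom_labels`, `omega`, `k`, `sequence_names`, `unit_norm`, `seed`.
#' @export
build_dictionary <- function(stack, samples, config = patch_config(),
                             unit_norm = FALSE) {
  stopifnot(inherits(stack, "sequence_stack"),
            inherits(samples, "tissue_sample_set"))
  fm <- extract_features(stack, config,
                         pixels = cbind(samples$row, samples$col),
                         unit_norm = unit_norm)
  structure(list(D = fm$Y, atom_labels = as.character(samples$label),
                 omega = config$omega, k = fm$k,
                 sequence_names = stack$sequence_names,
                 unit_norm = unit_norm,
                 seed = attr(samples, "seed")),
            class = "background_dictionary")
}

#' @export
print.background_dictionary <- function(x, ...) {
  cat(sprintf(
    "Background dictionary: %d x %d (omega = %d, k = %d: %s)\n",
    nrow(x$D), ncol(x$D), x$omega, x$k,
    paste(x$sequence_names, collapse = ", ")))
  print(table(x$atom_labels))
  invisible(x)
}

#' Persist a background dictionary
#'
#' The atom matrix is written as little-endian IEEE doubles to `file`, with a
#' JSON sidecar `<file>.json` holding dimensions and metadata (`omega`, `k`,
#' `sequence_names`, `atom_labels`, `seed`, format version). The round trip
#' through [read_dictionary()] is bit-exact.
#'
#' @param dict A [build_dictionary()] result.
#' @param file Output path for the binary matrix.
#' @return `file`, invisibly.
#' @export
write_dictionary <- function(dict, file) {
  stopifnot(inherits(dict, "background_dictionary"))
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.vector(dict$D), con, size = 8L, endian = "little")
  meta <- list(format = "jclrrsr-dictionary", version = 1L,
               nrow = nrow(dict$D), ncol = ncol(dict$D),
               omega = dict$omega, k = dict$k,
               sequence_names = dict$sequence_names,
               atom_labels = dict$atom_labels,
               unit_norm = isTRUE(dict$unit_norm), seed = dict$seed)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Load a background dictionary written by [write_dictionary()]
#'
#' @param file Path given to [write_dictionary()].
#' @return A `background_dictionary`.
#' @export
read_dictionary <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "jclrrsr-dictionary"))
    stop("read_dictionary: not a dictionary file", call. = FALSE)
  con <- file(file, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = meta$nrow * meta$ncol, size = 8L,
                  endian = "little")
  structure(list(D = matrix(vals, meta$nrow, meta$ncol),
                 atom_labels = meta$atom_labels,
                 omega = as.integer(meta$omega), k = as.integer(meta$k),
                 sequence_names = meta$sequence_names,
                 unit_norm = isTRUE(meta$unit_norm),
                 seed = meta$seed),
            class = "background_dictionary")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
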