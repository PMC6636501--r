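#' Specify a synthetic multisequence brain phantom
#'
#' The phantom is a 2-D slice built from nested ellipses: a brain ellipse
#' whose outer ring is grey matter, a white-matter interior and a small
#' central cerebrospinal-fluid (ventricle-like) ellipse. Each sequence draws
#' its per-tissue mean intensity from `tissue_means`, lesions add a
#' per-sequence offset inside planted discs, and i.i.d. Gaussian noise is
#' added before clipping to `[0, 255]`.
#'
#' @param shape `c(H, W)` image size in pixels.
#' @param sequence_names Character vector of the `k` sequences.
#' @param tissue_means `k x 3` numeric matrix (columns `WM`, `GM`, `CSF`) of
#'   mean intensities on the 0-255 scale, one row per sequence.
#' @param noise_sigma Additive Gaussian standard deviation, length 1 or `k`.
#' @param pv_sigma Partial-volume smoothing: standard deviation (pixels) of a
#'   Gaussian blur applied to the noiseless image before noise is added,
#'   emulating the partial-volume averaging of MR acquisition at tissue
#'   interfaces. `0` (default) gives a piecewise-constant phantom.
#' @param lesions List of lesions, each `list(center = c(row, col), radius,
#'   offsets)` with `offsets` a length-`k` vector of per-sequence intensity
#'   shifts. Discs must lie inside the brain ellipse.
#' @param geometry List of semi-axes `c(a, b)` (rows, cols) for `brain`,
#'   `gm_inner` (inner edge of the grey-matter ring) and `csf`, all centered
#'   at the image center.
#' @param seed Integer seed for the noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         sequence_names = c("T1", "T2", "FLAIR"),
                         tissue_means = default_tissue_means(sequence_names),
                         noise_sigma = 5,
                         pv_sigma = 0,
                         lesions = list(),
                         geometry = list(brain = c(54, 44),
                                         gm_inner = c(46, 37),
                                         csf = c(10, 7)),
                         seed = 1L) {
  k <- length(sequence_names)
  tissue_means <- as.matrix(tissue_means)
  if (!all(dim(tissue_means) == c(k, 3)))
    stop("phantom_spec: 'tissue_means' must be k x 3 (WM, GM, CSF)",
         call. = FALSE)
  colnames(tissue_means) <- c("WM", "GM", "CSF")
  if (length(noise_sigma) == 1L) noise_sigma <- rep(noise_sigma, k)
  if (any(noise_sigma < 0))
    stop("phantom_spec: 'noise_sigma' must be >= 0", call. = FALSE)
  if (length(pv_sigma) != 1L || pv_sigma < 0)
    stop("phantom_spec: 'pv_sigma' must be a single value >= 0",
         call. = FALSE)
  for (les in lesions) {
    if (is.null(les$center) || is.null(les$radius) || is.null(les$offsets))
      stop("phantom_spec: each lesion needs center, radius, offsets",
           call. = FALSE)
    if (les$radius <= 0) stop("phantom_spec: lesion radius must be > 0",
                              call. = FALSE)
    if (length(les$offsets) != k)
      stop("phantom_spec: lesion offsets must have one entry per sequence",
           call. = FALSE)
  }
  structure(list(shape = as.integer(shape), k = k,
                 sequence_names = sequence_names,
                 tissue_means = tissue_means, noise_sigma = noise_sigma,
                 pv_sigma = pv_sigma,
                 lesions = lesions, geometry = geometry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-tissue, per-sequence mean intensities
#'
#' T1-like: white matter bright, CSF dark. T2-like: CSF bright. PD-like:
#' intermediate contrast. FLAIR-like: CSF suppressed. Unknown names get a
#' generic T1-like profile.
#'
#' @param sequence_names Character vector of sequence names.
#' @return A `length(sequence_names) x 3` matrix (WM, GM, CSF).
#' @export
default_tissue_means <- function(sequence_names) {
  profiles <- list(T1 = c(160, 110, 40), T2 = c(90, 120, 200),
                   PD = c(130, 150, 180), FLAIR = c(110, 140, 30))
  t(vapply(sequence_names, function(nm) {
    if (nm %in% names(profiles)) profiles[[nm]] else profiles$T1
  }, numeric(3)))
}

# Logical mask of an ellipse with semi-axes `ab` centered at the image
# center.
#' @noRd
ellipse_mask_ <- function(shape, ab) {
  ctr <- (shape + 1) / 2
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - ctr[1]) / ab[1])^2 + ((c_ - ctr[2]) / ab[2])^2 <= 1
}

#' Generate a phantom from its specification
#'
#' Deterministic given `spec$seed`. Every in-brain pixel carries exactly one
#' tissue label; the lesion truth mask (union of the planted discs) is kept
#' separately and overlays the tissue labels.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `stack` (a [sequence_stack()] with the
#'   brain mask), `label_map` (character matrix `"WM"/"GM"/"CSF"`, `NA`
#'   outside the brain), `lesion_mask` (logical truth mask), `clip_rate`
#'   (fraction of in-brain samples clipped at 0 or 255) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  brain <- ellipse_mask_(spec$shape, spec$geometry$brain)
  inner <- ellipse_mask_(spec$shape, spec$geometry$gm_inner)
  csf <- ellipse_mask_(spec$shape, spec$geometry$csf)
  label_map <- matrix(NA_character_, H, W)
  label_map[brain] <- "GM"
  label_map[inner & brain] <- "WM"
  label_map[csf & brain] <- "CSF"

  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  lesion_mask <- matrix(FALSE, H, W)
  for (les in spec$lesions) {
    disc <- (r - les$center[1])^2 + (c_ - les$center[2])^2 <= les$radius^2
    if (any(disc & !brain))
      stop("generate_phantom: lesion extends outside the brain",
           call. = FALSE)
    lesion_mask <- lesion_mask | disc
  }

  volumes <- vector("list", spec$k)
  clipped <- 0; total <- 0
  with_seed_(spec$seed, {
    for (s in seq_len(spec$k)) {
      img <- matrix(0, H, W)
      for (lab in c("WM", "GM", "CSF"))
        img[!is.na(label_map) & label_map == lab] <-
          spec$tissue_means[s, lab]
      for (les in spec$lesions) {
        disc <- (r - les$center[1])^2 + (c_ - les$center[2])^2 <=
          les$radius^2
        img[disc] <- img[disc] + les$offsets[s]
      }
      if (spec$pv_sigma > 0)
        img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                        sigma = spec$pv_sigma))
      noisy <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma[s]),
                            H, W)
      clipped <- clipped + sum(noisy[brain] < 0 | noisy[brain] > 255)
      total <- total + sum(brain)
      volumes[[s]] <- pmin(pmax(noisy, 0), 255)
    }
  })

  structure(list(stack = sequence_stack(volumes, spec$sequence_names,
                                        brain_mask = brain),
                 label_map = label_map, lesion_mask = lesion_mask,
                 clip_rate = clipped / total, spec = spec),
            class = "phantom")
}

#' Fixed phantom presets
#'
#' Two scenarios with fixed seeds: `tumor_like`, a 128 x 128 three-sequence
#' (T1, T2, FLAIR) slice with one large lesion occupying roughly a tenth of
#' the brain area, hyperintense on FLAIR and T2 and hypointense on T1; and
#' `ms_like`, a 128 x 128 four-sequence (T1, T2, PD, FLAIR) slice with seven
#' small lesions scattered in the white matter. Both use noise sigma 5 and
#' one pixel of partial-volume smoothing.
#'
#' @return A named list of [phantom_spec()] objects.
#' @export
phantom_presets <- function() {
  list(
    tumor_like = phantom_spec(
      shape = c(128L, 128L),
      sequence_names = c("T1", "T2", "FLAIR"),
      noise_sigma = 5,
      pv_sigma = 1,
      lesions = list(list(center = c(85, 75), radius = 16,
                          offsets = c(-30, 60, 90))),
      seed = 101L),
    ms_like = phantom_spec(
      shape = c(128L, 128L),
      sequence_names = c("T1", "T2", "PD", "FLAIR"),
      noise_sigma = 5,
      pv_sigma = 1,
      lesions = list(
        list(center = c(45, 50), radius = 4, offsets = c(-25, 55, 35, 85)),
        list(center = c(50, 83), radius = 3, offsets = c(-25, 55, 35, 85)),
        list(center = c(70, 40), radius = 4, offsets = c(-25, 55, 35, 85)),
        list(center = c(77, 85), radius = 5, offsets = c(-25, 55, 35, 85)),
        list(center = c(90, 70), radius = 3, offsets = c(-25, 55, 35, 85)),
        list(center = c(37, 67), radius = 3, offsets = c(-25, 55, 35, 85)),
        list(center = c(83, 53), radius = 4, offsets = c(-25, 55, 35, 85))),
      seed = 202L))
}

#' Lesion-free copy of a phantom specification
#'
#' Used to emulate the labelled normal reference image from which the
#' background dictionary is trained: same geometry, intensity profiles and
#' noise level, no lesions, and an independent noise seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed for the reference phantom's noise (defaults to
#'   `spec$seed + 1`).
#' @return A `phantom_spec` without lesions.
#' @export
normal_reference_spec <- function(spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec$lesions <- list()
  spec$seed <- as.integer(seed)
  spec
}
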