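#' End-to-end lesion segmentation of one multisequence slice
#'
#' Runs the full chain: patch-feature extraction over the in-brain pixels,
#' LADMAP solve of the joint low-rank and sparse representation program
#' against the background dictionary, abnormality response, thresholding and
#' brain-mask postprocessing. Intensities are expected on the 0-255 scale
#' (apply [normalize_intensity()] per sequence first if needed); the run is
#' deterministic given its inputs.
#'
#' @param stack A [sequence_stack()] of the image to segment.
#' @param dictionary A [build_dictionary()] / [read_dictionary()] result. Its
#'   `omega`, `k` and sequence names must match `stack` and `patch`.
#' @param alpha Weight of the abnormality term (`> 0`). Larger values make
#'   flagging a pixel as abnormal more expensive.
#' @param beta Weight of the element-wise sparsity on the coefficients
#'   (`>= 0`; `0` gives the plain low-rank representation model).
#' @param patch A [patch_config()]; defaults to the dictionary's `omega`.
#' @param control A [ladmap_control()]; the default pipeline preset trades a
#'   little residual accuracy for speed.
#' @param threshold_method,threshold_param Passed to [threshold_response()].
#' @param min_size Passed to [postprocess_mask()].
#' @param edge_margin Brain-mask erosion radius for postprocessing (`shrink`
#'   of [postprocess_mask()]); `NULL` (default) uses the patch radius
#'   `(omega - 1) / 2`, so only pixels whose whole neighborhood lies in brain
#'   tissue can be reported as lesion.
#' @param truth Optional logical truth mask; when given, the Dice score is
#'   included in the report.
#' @return A list of class `jclrrsr_run`: `lesion` (final `lesion_map`),
#'   `response` (`response_map`), `fit` (`jclrrsr_fit`) and `report` (config
#'   echo, iterations, final residual, threshold, Dice, timing).
#' @export
segment_lesions <- function(stack, dictionary, alpha, beta = 0.05,
                            patch = NULL,
                            control = ladmap_control(eps1 = 1e-4,
                                                     eps2 = 1e-3,
                                                     max_iter = 300L),
                            threshold_method = "otsu",
                            threshold_param = NULL,
                            min_size = 0L, edge_margin = NULL,
                            truth = NULL) {
  stopifnot(inherits(stack, "sequence_stack"),
            inherits(dictionary, "background_dictionary"))
  if (is.null(patch)) patch <- patch_config(omega = dictionary$omega)
  if (is.null(edge_margin)) edge_margin <- (patch$omega - 1L) %/% 2L
  if (patch$omega != dictionary$omega)
    stop(sprintf(
      "segment_lesions: configured omega (%d) != dictionary omega (%d)",
      patch$omega, dictionary$omega), call. = FALSE)
  if (length(stack$volumes) != dictionary$k)
    stop(sprintf(
      "segment_lesions: stack has %d sequences, dictionary expects %d",
      length(stack$volumes), dictionary$k), call. = FALSE)
  if (!identical(stack$sequence_names, dictionary$sequence_names))
    warning("segment_lesions: sequence names differ from the dictionary's")
  t0 <- proc.time()[["elapsed"]]
  fm <- extract_features(stack, patch,
                         unit_norm = isTRUE(dictionary$unit_norm))
  if (nrow(fm$Y) != nrow(dictionary$D))
    stop("segment_lesions: feature/dictionary dimension mismatch",
         call. = FALSE)
  fit <- solve_jclrrsr(jclrrsr_problem(fm$Y, dictionary$D, alpha, beta),
                       control)
  rmap <- response_map(fit$E_star, fm$pixel_index, stack$dim)
  lmap <- threshold_response(rmap, threshold_method, threshold_param)
  lmap <- postprocess_mask(lmap, stack$brain_mask, min_size = min_size,
                           shrink = edge_margin)
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- list(alpha = alpha, beta = beta, omega = patch$omega,
                 k = dictionary$k, S = ncol(dictionary$D),
                 M = ncol(fm$Y),
                 threshold_method = threshold_method,
                 threshold = lmap$threshold,
                 iterations = fit$iterations, converged = fit$converged,
                 final_residual = utils::tail(fit$residual_history, 1),
                 dice = if (!is.null(truth)) dice_score(lmap$mask, truth)
                        else NA_real_,
                 runtime_s = elapsed)
  structure(list(lesion = lmap, response = rmap, fit = fit,
                 report = report),
            class = "jclrrsr_run")
}

#' @export
print.jclrrsr_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "JCLRRSR run: %d pixels, S = %d, omega = %d, alpha = %g, beta = %g\n",
    r$M, r$S, r$omega, r$alpha, r$beta))
  cat(sprintf("  solver: %d iterations, final rel. residual %.2e\n",
              r$iterations, r$final_residual))
  cat(sprintf("  threshold (%s): %.4g; lesion pixels: %d\n",
              r$threshold_method, r$threshold, sum(x$lesion$mask)))
  if (!is.na(r$dice)) cat(sprintf("  Dice vs truth: %.4f\n", r$dice))
  invisible(x)
}

#' Segment a phantom against a dictionary trained on its normal reference
#'
#' Convenience wrapper used by the worked examples and the parameter sweeps:
#' generates the phantom, generates a lesion-free reference phantom from the
#' same specification, samples `S` tissue-labelled training pixels (3:1:1
#' WM:GM:CSF), builds the dictionary and calls [segment_lesions()].
#'
#' @param spec A [phantom_spec()] (e.g. from [phantom_presets()]).
#' @param S Number of dictionary atoms.
#' @param omega Patch side length.
#' @param alpha,beta Model weights.
#' @param ratio WM:GM:CSF sampling ratio.
#' @param control Solver control.
#' @param min_size Minimum connected-component size kept in postprocessing.
#' @param sample_seed Seed for the training-pixel draw.
#' @param ... Further arguments to [segment_lesions()].
#' @return The [segment_lesions()] result, with the phantom attached as
#'   `$phantom`.
#' @export
segment_phantom <- function(spec, S = 300L, omega = 5L, alpha = 0.1,
                            beta = 0.05, ratio = c(3, 1, 1),
                            control = ladmap_control(eps1 = 1e-4,
                                                     eps2 = 1e-3,
                                                     max_iter = 300L),
                            min_size = 10L,
                            sample_seed = spec$seed + 2L, ...) {
  ph <- generate_phantom(spec)
  ref <- generate_phantom(normal_reference_spec(spec))
  samples <- sample_tissue_pixels(ref$label_map, S, ratio,
                                  seed = sample_seed)
  dict <- build_dictionary(ref$stack, samples, patch_config(omega))
  run <- segment_lesions(ph$stack, dict, alpha = alpha, beta = beta,
                         control = control, min_size = min_size,
                         truth = ph$lesion_mask, ...)
  run$phantom <- ph
  run
}

#' Parameter sweep over dictionary size, patch size and model weights
#'
#' Runs [segment_phantom()] over the Cartesian product of the supplied grids
#' and tabulates Dice score, iteration count and runtime, mirroring the
#' standard sensitivity studies (accuracy vs. number of training samples,
#' neighborhood size, and the alpha/beta weights).
#'
#' @param spec A [phantom_spec()] with at least one lesion (the truth mask).
#' @param S_grid,omega_grid,alpha_grid,beta_grid Numeric vectors; each must
#'   be nonempty.
#' @param control Solver control shared by all runs.
#' @param sample_seed Seed for the training-pixel draws.
#' @return A data frame with one row per grid point: `S`, `omega`, `alpha`,
#'   `beta`, `dice`, `iterations`, `converged`, `runtime_s`.
#' @export
sweep_segmentation <- function(spec, S_grid = 300L, omega_grid = 5L,
                               alpha_grid = 0.1, beta_grid = 0.05,
                               control = ladmap_control(eps1 = 1e-4,
                                                        eps2 = 1e-3,
                                                        max_iter = 300L),
                               sample_seed = spec$seed + 2L) {
  if (length(S_grid) == 0L || length(omega_grid) == 0L ||
      length(alpha_grid) == 0L || length(beta_grid) == 0L)
    stop("sweep_segmentation: empty grid", call. = FALSE)
  grid <- expand.grid(S = S_grid, omega = omega_grid, alpha = alpha_grid,
                      beta = beta_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    run <- segment_phantom(spec, S = grid$S[i], omega = grid$omega[i],
                           alpha = grid$alpha[i], beta = grid$beta[i],
                           control = control, sample_seed = sample_seed)
    r <- run$report
    rows[[i]] <- data.frame(S = grid$S[i], omega = grid$omega[i],
                            alpha = grid$alpha[i], beta = grid$beta[i],
                            dice = r$dice, iterations = r$iterations,
                            converged = r$converged,
                            runtime_s = r$runtime_s)
  }
  do.call(rbind, rows)
}

#' Recommended settings for the phantom presets
#'
#' Fixed study conditions used by the worked example and the reproduction
#' script: dictionary size, patch size and model weights per preset. The
#' tumor preset uses a smaller dictionary than the multiple-sclerosis preset
#' because the single large lesion leaves plenty of normal tissue per class,
#' while small scattered lesions need denser normal-tissue coverage.
#'
#' @param name `"tumor_like"` or `"ms_like"`.
#' @return A list with `S`, `omega`, `alpha`, `beta`, `min_size`.
#' @export
preset_run_settings <- function(name = c("tumor_like", "ms_like")) {
  name <- match.arg(name)
  switch(name,
         tumor_like = list(S = 300L, omega = 5L, alpha = 0.1, beta = 0.05,
                           min_size = 20L),
         ms_like = list(S = 1000L, omega = 5L, alpha = 0.5, beta = 0.05,
                        min_size = 10L))
}
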