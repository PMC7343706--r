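#' Simulate a multi-patient phantom suite
#'
#' Generates `n_patients * images_per_patient` phantom cross-sections with
#' known tissue maps.  Geometry varies between synthetic patients (mean
#' lumen radius, sector layout, wall thickness) and between images of the
#' same patient (lumen harmonics, speckle and texture realizations); the
#' tissue optical parameters are fixed study conditions shared by all
#' images.
#'
#' @param n_patients number of synthetic patients (default 10).
#' @param images_per_patient frames per patient (default 5).
#' @param sys a [system_params()].
#' @param params tissue parameters ([default_tissue_params()]).
#' @param looks speckle looks (default 4).
#' @param seed master seed; every phantom derives its own sub-seed.
#' @return list of elements `phantom` ([generate_phantom()] result),
#'   `patient_id`, `image_id`.
#' @export
simulate_phantom_suite <- function(n_patients = 10, images_per_patient = 5,
                                   sys = system_params(n_alines = 90,
                                                       axial_spacing = 0.01),
                                   params = default_tissue_params(),
                                   looks = 4, seed = 1L) {
  out <- list()
  idx <- 0L
  for (p in seq_len(n_patients)) {
    set.seed(seed * 1000L + p)
    mean_r <- runif(1, 0.7, 1.1)
    rot <- runif(1, 0, 360)
    cuts <- sort(runif(2, 70, 290))
    while (min(diff(c(0, cuts, 360))) < 60) cuts <- sort(runif(2, 70, 290))
    thick <- runif(1, 1.15, 1.45)
    sectors <- data.frame(start_deg = c(0, cuts),
                          end_deg = c(cuts, 360),
                          label = sample(1:3),
                          thickness_mm = thick)
    for (f in seq_len(images_per_patient)) {
      idx <- idx + 1L
      sub_seed <- (seed * 1000L + p * 37L + f * 101L) %% .Machine$integer.max
      set.seed(sub_seed)
      harm <- c(0, runif(1, 0, 0.08), runif(1, 0, 0.05))
      ph <- generate_phantom(
        phantom_spec(mean_radius_mm = mean_r, harmonics = harm,
                     phase = runif(3, 0, 2 * pi),
                     tissue_sectors = sectors, looks = looks,
                     seed = sub_seed),
        params_by_label = params, sys = sys)
      # rotate sector layout by shifting phases only (sectors fixed per patient)
      out[[idx]] <- list(phantom = ph, patient_id = paste0("P", p),
                         image_id = sprintf("P%02d_I%02d", p, f))
    }
  }
  out
}

#' Feature datasets from a phantom suite
#'
#' Runs the optical inversion and texture sweep on each phantom (anchored at
#' its true lumen boundary) and samples labeled analysis-band pixels,
#' producing the input expected by [cross_validate()] and
#' [patient_holdout()].
#'
#' @param suite result of [simulate_phantom_suite()].
#' @param sample_per_image labeled pixels sampled per image (default 600);
#'   `Inf` keeps every band pixel.
#' @param window_len optical fit window, mm.
#' @param analysis_depth analysis band, mm.
#' @param window_px texture window side.
#' @param levels gray levels.
#' @param seed sampling seed.
#' @return list of elements `stack`, `labels`, `patient_id`, `image_id`.
#' @export
phantom_feature_datasets <- function(suite, sample_per_image = 600,
                                     window_len = 0.25, analysis_depth = 1.0,
                                     window_px = 11, levels = 32, seed = 1L) {
  lapply(seq_along(suite), function(i) {
    ph <- suite[[i]]$phantom
    opt <- attenuation_map(ph$image, ph$boundary, ph$sys,
                           window_len = window_len,
                           analysis_depth = analysis_depth)
    cand <- which(opt$roi & ph$labels$labels > 0L, arr.ind = TRUE)
    if (is.finite(sample_per_image) && nrow(cand) > sample_per_image) {
      set.seed(seed + i)
      cand <- cand[sample(nrow(cand), sample_per_image), , drop = FALSE]
    }
    stack <- build_feature_stack(ph$image, opt, ph$boundary,
                                 window_px = window_px, levels = levels,
                                 pixels = cbind(cand[, 1] - 1L,
                                                cand[, 2] - 1L))
    labels <- ph$labels$labels[cbind(stack$row + 1L, stack$col + 1L)]
    list(stack = stack, labels = labels,
         patient_id = suite[[i]]$patient_id,
         image_id = suite[[i]]$image_id)
  })
}
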