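#' Point-process parameters for synthetic cores
#'
#' Three regimes cover the spatial organizations the feature catalogue
#' must discriminate: complete spatial randomness (`CSR`, homogeneous
#' Poisson), a Thomas cluster process (`THOMAS`, Poisson parents with
#' isotropic Gaussian offspring), and hard-core inhibition (`HARDCORE`,
#' sequential inhibition with a minimum spacing).
#'
#' For `THOMAS` the expected overall intensity is
#' `parent_intensity * offspring_mean`; offspring falling outside the
#' window are discarded (bounded biopsy core, no toroidal wrap).
#'
#' @param process one of `"CSR"`, `"THOMAS"`, `"HARDCORE"`.
#' @param intensity expected points per square micrometer (CSR and
#'   HARDCORE).
#' @param parent_intensity parents per square micrometer (THOMAS).
#' @param offspring_mean expected offspring per parent (THOMAS).
#' @param offspring_sd isotropic Gaussian offspring dispersion in
#'   micrometers (THOMAS).
#' @param inhibition_radius minimum point spacing in micrometers
#'   (HARDCORE).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @export
process_params <- function(process = c("CSR", "THOMAS", "HARDCORE"),
                           intensity = 0.002,
                           parent_intensity = 5e-5,
                           offspring_mean = 40,
                           offspring_sd = 15,
                           inhibition_radius = 10,
                           seed = NULL) {
  process <- match.arg(process)
  for (nm in c("intensity", "parent_intensity", "offspring_mean",
               "offspring_sd", "inhibition_radius")) {
    stopifnot_scalar_num(get(nm), nm, 0)
  }
  structure(list(process = process, intensity = intensity,
                 parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 offspring_sd = offspring_sd,
                 inhibition_radius = inhibition_radius, seed = seed),
            class = "process_params")
}

#' Simulate a planar point pattern
#'
#' @param params a [process_params()] object.
#' @param window a [new_window()] object; coordinates are micrometers in
#'   `[0, width] x [0, height]`.
#' @return an n x 2 matrix of coordinates (columns `x`, `y`), possibly
#'   with zero rows.
#' @examples
#' w <- new_window(500, 500)
#' pts <- simulate_point_pattern(process_params("CSR", intensity = 1e-3, seed = 1), w)
#' @export
simulate_point_pattern <- function(params, window) {
  stopifnot(inherits(params, "process_params"), inherits(window, "window"))
  with_seed(params$seed, {
    area <- window$width * window$height
    pts <- switch(params$process,
      CSR = {
        n <- stats::rpois(1, params$intensity * area)
        cbind(x = stats::runif(n, 0, window$width),
              y = stats::runif(n, 0, window$height))
      },
      THOMAS = {
        n_par <- stats::rpois(1, params$parent_intensity * area)
        if (n_par == 0) {
          cbind(x = numeric(0), y = numeric(0))
        } else {
          px <- stats::runif(n_par, 0, window$width)
          py <- stats::runif(n_par, 0, window$height)
          n_off <- stats::rpois(n_par, params$offspring_mean)
          ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, params$offspring_sd)
          oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, params$offspring_sd)
          keep <- ox >= 0 & ox <= window$width & oy >= 0 & oy <= window$height
          cbind(x = ox[keep], y = oy[keep])
        }
      },
      HARDCORE = {
        n_target <- stats::rpois(1, params$intensity * area)
        acc_x <- numeric(0); acc_y <- numeric(0)
        attempts <- 0L; max_attempts <- 100L * max(n_target, 1L)
        r2 <- params$inhibition_radius^2
        while (length(acc_x) < n_target && attempts < max_attempts) {
          attempts <- attempts + 1L
          cx <- stats::runif(1, 0, window$width)
          cy <- stats::runif(1, 0, window$height)
          if (length(acc_x) == 0 ||
              min((acc_x - cx)^2 + (acc_y - cy)^2) >= r2) {
            acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy)
          }
        }
        cbind(x = acc_x, y = acc_y)
      })
    pts
  })
}

# Full tile grid covering a window: ceiling(width / tile) columns.
full_tile_grid <- function(window, tile_size_px) {
  tile_um <- tile_size_px * window$pixel_spacing
  nx <- ceiling(window$width / tile_um - 1e-9)
  ny <- ceiling(window$height / tile_um - 1e-9)
  grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(tile_x_px = grid$ix * tile_size_px,
             tile_y_px = grid$iy * tile_size_px)
}

#' Simulate one core's cell map
#'
#' Fabricates what the (out-of-scope) CNN front end would hand the
#' feature extractor: lymphocyte centroids in pixel coordinates plus a
#' tumor-bed tile grid covering the whole window.
#'
#' @param params a [process_params()] object.
#' @param window a [new_window()] object.
#' @param tile_size_px tile edge in pixels (default 750).
#' @param core_id core identifier.
#' @return a [cell_map()].
#' @export
simulate_core <- function(params, window, tile_size_px = 750,
                          core_id = "core01") {
  stopifnot_scalar_num(tile_size_px, "tile_size_px", 0, strict = TRUE)
  pts_um <- simulate_point_pattern(params, window)
  n <- nrow(pts_um)
  cells <- data.frame(
    cell_id = if (n) sprintf("c%05d", seq_len(n)) else character(0),
    x_px = pts_um[, 1] / window$pixel_spacing,
    y_px = pts_um[, 2] / window$pixel_spacing,
    cell_type = rep("lymphocyte", n),
    stringsAsFactors = FALSE)
  cell_map(core_id, cells, full_tile_grid(window, tile_size_px),
           tile_size_px = tile_size_px, pixel_spacing = window$pixel_spacing)
}

## ---- cohorts ------------------------------------------------------------

#' Specification of a simulated two-class cohort
#'
#' @param n_patients total patients (>= 2, both classes present).
#' @param cores_per_patient integer, or length-2 range sampled uniformly.
#' @param pcr_fraction fraction of patients with a pathological complete
#'   response (pCR) label.
#' @param base_params [process_params()] shared by both classes.
#' @param class_effect named list mapping `process_params` fields to
#'   `c(pcr = value, non = value)`; e.g.
#'   `list(process = c(pcr = "THOMAS", non = "CSR"))`. Empty list means
#'   no spatial class signal.
#' @param clinical_effect named list of per-covariate class-conditional
#'   settings overriding the pooled defaults of
#'   [default_clinical_model()]; empty means no clinical class signal.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_patients, cores_per_patient = 1L,
                        pcr_fraction = 0.26,
                        base_params = process_params(),
                        class_effect = list(),
                        clinical_effect = list(),
                        seed = NULL) {
  stopifnot_scalar_num(n_patients, "n_patients", 2)
  if (pcr_fraction < 0 || pcr_fraction > 1) {
    stop("`pcr_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n_pcr <- round(n_patients * pcr_fraction)
  if (n_pcr < 1 || n_pcr > n_patients - 1) {
    stop("`pcr_fraction` leaves one class empty", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 cores_per_patient = as.integer(cores_per_patient),
                 pcr_fraction = pcr_fraction, base_params = base_params,
                 class_effect = class_effect,
                 clinical_effect = clinical_effect, seed = seed),
            class = "cohort_spec")
}

#' Default clinical covariate model
#'
#' Class-conditional sampling distributions for the clinical covariates
#' of a neoadjuvant breast-cancer cohort: age, menopausal status,
#' laterality, chemotherapy backbone, anti-HER2 therapy, ER/PR/HER2
#' status, radiological tumor size, clinical T and N stage, nodal
#' status, inflammatory status, Nottingham grade, histology and BRCA
#' status. Defaults are pooled (identical in both classes), so a cohort
#' without `clinical_effect` carries no clinical signal.
#'
#' Continuous covariates are `list(type="continuous", mean=c(pcr, non),
#' sd=...)`; categorical are `list(type="categorical", levels=...,
#' prob_pcr=..., prob_non=...)`.
#'
#' @return named list of covariate specs.
#' @export
default_clinical_model <- function() {
  cat_cov <- function(levels, prob) {
    list(type = "categorical", levels = levels,
         prob_pcr = prob, prob_non = prob)
  }
  list(
    age = list(type = "continuous", mean = c(51, 51), sd = 11),
    menopausal_status = cat_cov(c("pre", "post", "peri"), c(0.44, 0.47, 0.09)),
    laterality = cat_cov(c("left", "right"), c(0.48, 0.52)),
    regimen = cat_cov(c("FEC-D", "AC-T"), c(0.41, 0.59)),
    anti_her2 = cat_cov(c("yes", "no"), c(0.39, 0.61)),
    er_status = cat_cov(c("pos", "neg"), c(0.64, 0.36)),
    pr_status = cat_cov(c("pos", "neg"), c(0.53, 0.47)),
    her2_status = cat_cov(c("pos", "neg"), c(0.39, 0.61)),
    tumor_size_mm = list(type = "continuous", mean = c(45, 45), sd = 26),
    clinical_t_stage = cat_cov(c("1", "2", "3", "4"), c(0.10, 0.59, 0.29, 0.02)),
    clinical_n_stage = cat_cov(c("0", "1", "2", "3"), c(0.31, 0.57, 0.08, 0.04)),
    node_status = cat_cov(c("positive", "negative"), c(0.69, 0.31)),
    inflammatory = cat_cov(c("yes", "no"), c(0.08, 0.92)),
    nottingham_grade = cat_cov(c("1", "2", "3"), c(0.05, 0.44, 0.51)),
    histology = cat_cov(c("IDC", "ILC", "IMC"), c(0.93, 0.05, 0.02)),
    brca_status = cat_cov(c("positive", "negative"), c(0.06, 0.94))
  )
}

sample_clinical <- function(model, is_pcr) {
  out <- list()
  for (nm in names(model)) {
    cv <- model[[nm]]
    if (cv$type == "continuous") {
      m <- if (is_pcr) cv$mean[1] else cv$mean[2]
      out[[nm]] <- max(stats::rnorm(1, m, cv$sd), 0)
    } else {
      p <- if (is_pcr) cv$prob_pcr else cv$prob_non
      out[[nm]] <- sample(cv$levels, 1, prob = p)
    }
  }
  out
}

params_for_class <- function(spec, is_pcr) {
  p <- spec$base_params
  for (nm in names(spec$class_effect)) {
    eff <- spec$class_effect[[nm]]
    val <- if (is_pcr) eff[["pcr"]] else eff[["non"]]
    if (nm == "process") p$process <- as.character(val)
    else p[[nm]] <- as.numeric(val)
  }
  p
}

#' Simulate a labeled two-class cohort
#'
#' Exactly `round(n_patients * pcr_fraction)` patients receive the pCR
#' label. Each patient's cores are drawn under its class's point-process
#' parameters; clinical covariates are drawn from the class-conditional
#' model.
#'
#' @param spec a [cohort_spec()].
#' @param window a [new_window()].
#' @param tile_size_px tile edge in pixels.
#' @return list of patient records, each a list with `patient_id`,
#'   `label` (`"pCR"`/`"non-pCR"`), `clinical` (named list) and `cores`
#'   (list of [cell_map()]).
#' @export
simulate_cohort <- function(spec, window, tile_size_px = 750) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(window, "window"))
  n <- spec$n_patients
  n_pcr <- round(n * spec$pcr_fraction)
  model <- utils::modifyList(default_clinical_model(), spec$clinical_effect)
  with_seed(spec$seed, {
    labels <- sample(c(rep(TRUE, n_pcr), rep(FALSE, n - n_pcr)))
    lapply(seq_len(n), function(i) {
      is_pcr <- labels[i]
      n_cores <- if (length(spec$cores_per_patient) == 2L) {
        sample(spec$cores_per_patient[1]:spec$cores_per_patient[2], 1)
      } else spec$cores_per_patient
      pp <- params_for_class(spec, is_pcr)
      pp$seed <- NULL # inherit the cohort RNG stream
      cores <- lapply(seq_len(n_cores), function(k) {
        simulate_core(pp, window, tile_size_px,
                      core_id = sprintf("p%03d_c%02d", i, k))
      })
      list(patient_id = sprintf("p%03d", i),
           label = if (is_pcr) "pCR" else "non-pCR",
           clinical = sample_clinical(model, is_pcr),
           cores = cores)
    })
  })
}

#' Flatten a cohort's clinical covariates to a data.frame
#'
#' @param cohort result of [simulate_cohort()].
#' @return data.frame with `patient_id`, covariate columns and
#'   `pcr_label` (1 = pCR).
#' @export
cohort_clinical_table <- function(cohort) {
  rows <- lapply(cohort, function(p) {
    c(list(patient_id = p$patient_id), p$clinical,
      list(pcr_label = as.integer(p$label == "pCR")))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

## ---- synthetic H&E tiles -----------------------------------------------

#' Render a synthetic H&E-like tile
#'
#' Dark elliptical hematoxylin-toned blobs at the given nucleus
#' positions on a pale eosin background. Used as a controlled input for
#' the image front end: the true nucleus mask is attached as attribute
#' `nucleus_mask` so foreground detection can be scored against it.
#'
#' @param window a [new_window()]; the image is
#'   `height/pixel_spacing` x `width/pixel_spacing` pixels.
#' @param nuclei n x 2 matrix of nucleus centers in micrometers.
#' @param stain_shift length-3 additive RGB perturbation emulating stain
#'   variation (applied after rendering, clipped to `[0, 1]`).
#' @param nucleus_radius_um mean nucleus radius in micrometers
#'   (lymphocytes are ~3 um).
#' @param seed integer seed for nucleus shape and texture noise.
#' @return an `h x w x 3` array in `[0, 1]` with attribute
#'   `nucleus_mask` (logical `h x w`).
#' @export
simulate_he_tile <- function(window, nuclei, stain_shift = c(0, 0, 0),
                             nucleus_radius_um = 3, seed = NULL) {
  w_px <- round(window$width / window$pixel_spacing)
  h_px <- round(window$height / window$pixel_spacing)
  nuclei <- if (is.null(nuclei) || length(nuclei) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    matrix(as.numeric(nuclei), ncol = 2)
  }
  if (nrow(nuclei) > 0 &&
      (any(nuclei[, 1] < 0 | nuclei[, 1] > window$width) ||
       any(nuclei[, 2] < 0 | nuclei[, 2] > window$height))) {
    stop("nuclei must lie inside the window", call. = FALSE)
  }
  with_seed(seed, {
    mask <- matrix(FALSE, h_px, w_px)
    xs <- matrix(rep(seq_len(w_px) - 0.5, each = h_px), h_px, w_px)
    ys <- matrix(rep(seq_len(h_px) - 0.5, times = w_px), h_px, w_px)
    r_px <- nucleus_radius_um / window$pixel_spacing
    for (i in seq_len(nrow(nuclei))) {
      cx <- nuclei[i, 1] / window$pixel_spacing
      cy <- nuclei[i, 2] / window$pixel_spacing
      a <- r_px * stats::runif(1, 0.8, 1.2)
      b <- r_px * stats::runif(1, 0.8, 1.2)
      th <- stats::runif(1, 0, pi)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
    }
    bg <- c(0.91, 0.88, 0.93)  # pale eosin background
    fg <- c(0.36, 0.24, 0.55)  # hematoxylin nucleus
    img <- array(0, dim = c(h_px, w_px, 3))
    noise <- matrix(stats::rnorm(h_px * w_px, 0, 0.015), h_px, w_px)
    for (ch in 1:3) {
      plane <- matrix(bg[ch], h_px, w_px)
      plane[mask] <- fg[ch]
      img[, , ch] <- pmin(pmax(plane + noise + stain_shift[ch], 0), 1)
    }
    attr(img, "nucleus_mask") <- mask
    img
  })
}

#' Write an RGB array as PNG
#'
#' @param img `h x w x 3` array in `[0,1]`.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Read a PNG into an RGB array
#' @param path file path.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
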