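#' Configuration for the 3D phantom cohort generator
#'
#' Defines the study conditions the synthetic cohorts emulate: an
#' ellipsoidal "brain" parcellated into 12 supratentorial and 4
#' infratentorial regions, and two subject classes with contrasting lesion
#' patterns. The AE-like class produces multiple smaller, often bilateral
#' lesions weighted toward a medial-temporal-like sector pair in each
#' hemisphere, with short-range intensity texture; the AS-like class
#' produces a single larger unilateral lesion weighted toward a frontal-like
#' sector, with longer-range, right-skewed texture. Lesion counts are
#' 1 + Poisson: rate 1.5 for AE-like (multifocal), 0.07 for AS-like
#' (about 7% multiple, matching a predominantly single-lesion tumour
#' cohort). Texture contrast between classes is carried by the noise
#' correlation length and histogram skew, so that radiomics carries signal
#' beyond lesion size and placement.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_spacing mm per axis; all > 0.
#' @param n_regions_supra,n_regions_infra region counts; must sum to 16.
#' @param classes per-class parameter lists; see Details. Each class needs
#'   `count_lambda` (lesion count is 1 + Poisson(lambda)), `radius_meanlog`,
#'   `radius_sdlog` (lesion radius, mm, log-normal), `placement` (length-16
#'   weights over regions, summing to 1), `intensity_offset` (lesion mean
#'   above background), `noise_sd`, `corr_length_mm` (texture correlation
#'   length), `skew` (texture histogram skew).
#' @param background mean, noise sd and correlation length of the
#'   non-lesion tissue.
#' @param scanner_bias optional named additive intensity shifts per scanner
#'   id (default none: scanner is metadata only).
#' @param seed integer master seed.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid_shape = c(72, 72, 60),
                           voxel_spacing = c(2, 2, 2),
                           n_regions_supra = 12,
                           n_regions_infra = 4,
                           classes = NULL,
                           background = list(mean = 100, noise_sd = 8,
                                             corr_length_mm = 2),
                           scanner_bias = NULL,
                           seed = 1L) {
  if (n_regions_supra + n_regions_infra != 16)
    abort("n_regions_supra + n_regions_infra must equal 16")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (any(voxel_spacing <= 0)) abort("voxel spacings must be positive")
  if (is.null(classes)) {
    ae_w <- rep(0.02, 16)
    ae_w[c(3, 4, 9, 10)] <- 0.18          # medial-temporal-like, both sides
    ae_w[13:16] <- 0.03                   # occasional infratentorial lesions
    as_w <- rep(0, 16)
    as_w[1] <- 0.40                        # frontal-like, left
    as_w[7] <- 0.40                        # frontal-like, right
    as_w[setdiff(1:12, c(1, 7))] <- 0.02
    classes <- list(
      AE = list(count_lambda = 1.5, radius_meanlog = log(7), radius_sdlog = 0.30,
                placement = ae_w / sum(ae_w), intensity_offset = 25,
                noise_sd = 10, corr_length_mm = 2, skew = 0),
      AS = list(count_lambda = 0.07, radius_meanlog = log(14), radius_sdlog = 0.20,
                placement = as_w / sum(as_w), intensity_offset = 30,
                noise_sd = 10, corr_length_mm = 6, skew = 0.8)
    )
  }
  for (cl in names(classes)) {
    w <- classes[[cl]]$placement
    if (length(w) != 16 || any(w < 0) || sum(w) <= 0)
      abort(paste0("class ", cl, ": placement weights must be 16 non-negative values"))
    if (abs(sum(w) - 1) > 1e-8)
      abort(paste0("class ", cl, ": placement weights must sum to 1"))
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
         n_regions_supra = as.integer(n_regions_supra),
         n_regions_infra = as.integer(n_regions_infra),
         classes = classes, background = background,
         scanner_bias = scanner_bias, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Deterministic 16-region atlas for the phantom brain
#'
#' Parcellates an ellipsoidal foreground into `n_regions_supra` angular
#' sectors above a ventral cut (supratentorial labels `1..12` by default)
#' and `n_regions_infra` sectors below it (infratentorial labels `13..16`).
#' Purely geometric, hence bit-identical for a given configuration.
#'
#' @param config a [phantom_config()].
#' @return Integer 3D array; 0 = background, labels `1..16` partition the
#'   foreground. Errors (naming the first empty region) if the grid cannot
#'   host all regions.
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dm <- config$grid_shape
  ctr <- (dm + 1) / 2
  semi <- 0.45 * dm
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  fg <- r2 <= 1
  theta <- atan2(g$y - ctr[2], g$x - ctr[1]) + pi   # [0, 2*pi)
  zcut <- ctr[3] - 0.5 * semi[3]
  infra <- fg & g$z < zcut
  supra <- fg & !infra
  lab <- integer(nrow(g))
  ns <- config$n_regions_supra
  ni <- config$n_regions_infra
  lab[supra] <- pmin(ns, floor(theta[supra] / (2 * pi) * ns) + 1)
  lab[infra] <- ns + pmin(ni, floor(theta[infra] / (2 * pi) * ni) + 1)
  atlas <- array(as.integer(lab), dm)
  counts <- tabulate(atlas[atlas > 0], nbins = 16L)
  if (any(counts == 0)) {
    abort(paste0("grid too small to host 16 non-empty regions: region ",
                 which(counts == 0)[1], " is empty"))
  }
  atlas
}

# Correlated unit-variance Gaussian field on an arbitrary-dimension grid.
correlated_noise <- function(dm, corr_vox) {
  z <- array(rnorm(prod(dm)), dm)
  if (any(corr_vox > 0)) {
    z <- gaussian_smooth3(z, corr_vox)
    s <- sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

# One blobby lesion mask centred at voxel `ctr_vox` with nominal radius
# radius_mm: a radial field plus correlated bumps, thresholded at 0, clipped
# to the atlas foreground, reduced to the component containing the centre.
grow_lesion <- function(ctr_vox, radius_mm, fg, spacing) {
  dm <- dim(fg)
  ext <- ceiling(2 * radius_mm / spacing)
  lo <- pmax(1L, ctr_vox - ext)
  hi <- pmin(dm, ctr_vox + ext)
  ix <- lapply(1:3, function(a) lo[a]:hi[a])
  sub_fg <- fg[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  sdm <- dim(sub_fg)
  gg <- expand.grid(x = ix[[1]], y = ix[[2]], z = ix[[3]])
  d <- sqrt(((gg$x - ctr_vox[1]) * spacing[1])^2 +
            ((gg$y - ctr_vox[2]) * spacing[2])^2 +
            ((gg$z - ctr_vox[3]) * spacing[3])^2)
  bump <- correlated_noise(sdm, pmax(0.5, radius_mm / 2 / spacing))
  fld <- array(radius_mm - d, sdm) + 0.35 * radius_mm * bump
  m <- fld > 0 & sub_fg
  if (any(m)) {
    lab <- label_components_array(m, connectivity = 26L)
    cpos <- ctr_vox - lo + 1L
    cl <- lab[cpos[1], cpos[2], cpos[3]]
    m <- if (cl > 0) lab == cl else lab == which.max(tabulate(lab[lab > 0]))
  }
  if (sum(m) * prod(spacing) < 8) {
    # fall back to a plain ball big enough to satisfy the 8 mm^3 floor
    rb <- max(radius_mm, 1.5 * max(spacing))
    m <- array(d <= rb, sdm) & sub_fg
  }
  out <- array(FALSE, dm)
  out[ix[[1]], ix[[2]], ix[[3]]] <- m
  out
}

#' Simulate one phantom subject
#'
#' Draws lesion count, sizes and regional placements from the class's
#' configured distributions, grows blobby lesion masks inside the atlas
#' foreground, and synthesizes intensities: a smooth background plus, inside
#' lesions, a class-specific offset and correlated (optionally skewed)
#' texture. Identical `(config, class_label, seed)` give bit-identical
#' output.
#'
#' @param config a [phantom_config()].
#' @param class_label one of `names(config$classes)` (default "AE"/"AS").
#' @param seed integer seed for this subject.
#' @param subject_id,scanner_id metadata stamped on the result.
#' @param atlas optionally, a precomputed [make_atlas()] result.
#' @return A `phantom_subject`: list with `image`, `mask`, `atlas`, `class`,
#'   `scanner_id`, `subject_id`, `spacing`, `seed`.
#' @export
simulate_subject <- function(config, class_label, seed,
                             subject_id = NA_character_, scanner_id = "A",
                             atlas = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  cls <- config$classes[[class_label]]
  if (is.null(cls)) abort(paste0("unknown class label: ", class_label))
  if (is.null(atlas)) atlas <- make_atlas(config)
  sp <- config$voxel_spacing
  fg <- atlas > 0L
  with_seed(seed, {
    dm <- config$grid_shape
    bg <- config$background
    image <- bg$mean + bg$noise_sd *
      correlated_noise(dm, bg$corr_length_mm / sp)
    n_les <- 1L + rpois(1L, cls$count_lambda)
    mask <- array(FALSE, dm)
    for (l in seq_len(n_les)) {
      reg <- sample.int(16L, 1L, prob = cls$placement)
      vox <- which(atlas == reg)
      ctr_vox <- as.integer(arrayInd(vox[sample.int(length(vox), 1L)], dm))
      radius <- stats::rlnorm(1L, cls$radius_meanlog, cls$radius_sdlog)
      mask <- mask | grow_lesion(ctr_vox, radius, fg, sp)
    }
    tex <- correlated_noise(dm, cls$corr_length_mm / sp)
    tex <- tex + cls$skew * (tex^2 - 1) / 2
    image[mask] <- image[mask] + cls$intensity_offset + cls$noise_sd * tex[mask]
    if (!is.null(config$scanner_bias) && scanner_id %in% names(config$scanner_bias))
      image <- image + config$scanner_bias[[scanner_id]]
    structure(
      list(image = image, mask = mask, atlas = atlas, class = class_label,
           scanner_id = scanner_id, subject_id = subject_id,
           spacing = sp, seed = seed),
      class = "phantom_subject"
    )
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("<phantom_subject> ", x$subject_id, " (", x$class, ", scanner ",
      x$scanner_id, "): ", sum(x$mask), " lesion voxels\n", sep = "")
  invisible(x)
}

#' Simulate a labelled phantom cohort
#'
#' Generates `n_AE` AE-like and `n_AS` AS-like subjects with scanner ids
#' drawn from `scanner_mix`, using per-subject seeds derived
#' deterministically from the cohort seed, and returns the subjects together
#' with a truth table. Optionally writes NIfTI image/mask/atlas triplets,
#' the truth table CSV and the configuration JSON to `dir`.
#'
#' @param config a [phantom_config()].
#' @param n_AE,n_AS subject counts (>= 0).
#' @param scanner_mix named probabilities of each scanner id.
#' @param seed cohort seed; defaults to `config$seed`.
#' @param id_prefix prefix for generated subject ids.
#' @param dir if non-NULL, a directory to write the cohort to.
#' @return A list with `subjects` (list of [simulate_subject()] results) and
#'   `truth` (tibble: subject_id, class, scanner_id, seed).
#' @export
simulate_cohort <- function(config, n_AE, n_AS,
                            scanner_mix = c(A = 0.4, B = 0.4, C = 0.2),
                            seed = NULL, id_prefix = "S", dir = NULL) {
  stopifnot(inherits(config, "phantom_config"), n_AE >= 0, n_AS >= 0)
  seed <- seed %||% config$seed
  n <- n_AE + n_AS
  if (n == 0) {
    return(list(subjects = list(),
                truth = tibble::tibble(subject_id = character(),
                                       class = character(),
                                       scanner_id = character(),
                                       seed = integer())))
  }
  classes <- c(rep("AE", n_AE), rep("AS", n_AS))
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  scanners <- with_seed(derive_seed(seed, "scanners"),
                        sample(names(scanner_mix), n, replace = TRUE,
                               prob = scanner_mix))
  seeds <- vapply(ids, function(i) derive_seed(seed, "subject", i), integer(1))
  atlas <- make_atlas(config)
  subjects <- purrr::pmap(
    list(ids, classes, seeds, scanners),
    function(id, cl, sd_, sc)
      simulate_subject(config, cl, sd_, subject_id = id, scanner_id = sc,
                       atlas = atlas)
  )
  truth <- tibble::tibble(subject_id = ids, class = classes,
                          scanner_id = scanners, seed = unname(seeds))
  if (!is.null(dir)) write_phantom_cohort(subjects, truth, config, dir)
  list(subjects = subjects, truth = truth)
}

#' Write a phantom cohort to disk as NIfTI + CSV + JSON
#'
#' @param subjects,truth as returned by [simulate_cohort()].
#' @param config the [phantom_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_cohort <- function(subjects, truth, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in subjects) {
    base <- file.path(dir, s$subject_id)
    for (what in c("image", "mask", "atlas")) {
      arr <- s[[what]]
      if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
      img <- RNifti::asNifti(arr, reference = NULL)
      RNifti::pixdim(img) <- s$spacing
      RNifti::writeNifti(img, paste0(base, "_", what, ".nii.gz"))
    }
  }
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a phantom cohort written by [write_phantom_cohort()]
#'
#' @param dir cohort directory.
#' @return A list with `subjects` and `truth`, as from [simulate_cohort()].
#' @export
read_phantom_cohort <- function(dir) {
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  subjects <- purrr::pmap(truth, function(subject_id, class, scanner_id, ...) {
    base <- file.path(dir, subject_id)
    img <- RNifti::readNifti(paste0(base, "_image.nii.gz"))
    msk <- RNifti::readNifti(paste0(base, "_mask.nii.gz"))
    atl <- RNifti::readNifti(paste0(base, "_atlas.nii.gz"))
    sp <- RNifti::pixdim(img)
    list(image = array(as.numeric(img), dim(img)),
         mask = array(as.integer(msk) > 0, dim(msk)),
         atlas = array(as.integer(atl), dim(atl)),
         class = class, scanner_id = scanner_id, subject_id = subject_id,
         spacing = as.numeric(sp)[1:3])
  })
  list(subjects = subjects, truth = truth)
}
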