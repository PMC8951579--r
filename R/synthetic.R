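#' @include cohort.R sisn.R
NULL

#' Synthetic cohort generator configuration
#'
#' Bundles every knob of the synthetic cohort generator. The defaults
#' emulate the study conditions the pipeline was designed for: 458 nodules,
#' all diameters below the 30 mm inclusion bound, 5 mm slice thickness and
#' 0.618 mm pixel pitch, 60-slice stacks. Labels are drawn from uniform
#' per-task priors (margin priors conditioned on texture, tilted so that
#' suspicious margins are likelier for solid nodules); radiomics features
#' follow a class-conditional Gaussian block-prototype model with
#' separation `effect_size` (in noise-SD units); sizes follow a log-normal
#' truncated to (0, 30) mm.
#'
#' @param n Number of nodules (default 458).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param location_priors,texture_priors Probability vectors over the 6
#'   location / 3 texture classes (must sum to 1).
#' @param margin_priors_given_texture 3 x 4 row-stochastic matrix, rows in
#'   texture order, columns in margin order.
#' @param effect_size Prototype separation delta, in units of `noise_sd`.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian feature noise.
#' @param size_log_mean,size_log_sd Parameters of the log-normal size law
#'   (log-mm scale) before truncation to (0, 30) mm.
#' @param total_slices Number of axial slices per stack (default 60).
#' @param slice_thickness_mm Axial spacing, mm (default 5).
#' @param pixel_pitch_mm In-plane pixel spacing, mm (default 0.618).
#' @return A validated list of class `"GeneratorConfig"`.
#' @examples
#' cfg <- generatorConfig(n = 10, seed = 1)
#' cfg$effect_size
#' @export
generatorConfig <- function(n = 458L, seed = 0L,
                            location_priors = rep(1 / 6, 6),
                            texture_priors = rep(1 / 3, 3),
                            margin_priors_given_texture = rbind(
                              Solid = c(0.15, 0.15, 0.35, 0.35),
                              Subsolid = c(0.25, 0.25, 0.25, 0.25),
                              PureGGO = c(0.35, 0.35, 0.15, 0.15)),
                            effect_size = 3, noise_sd = 1,
                            size_log_mean = log(8), size_log_sd = 0.6,
                            total_slices = 60L, slice_thickness_mm = 5,
                            pixel_pitch_mm = 0.618) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              location_priors = location_priors,
              texture_priors = texture_priors,
              margin_priors_given_texture = margin_priors_given_texture,
              effect_size = effect_size, noise_sd = noise_sd,
              size_log_mean = size_log_mean, size_log_sd = size_log_sd,
              total_slices = as.integer(total_slices),
              slice_thickness_mm = slice_thickness_mm,
              pixel_pitch_mm = pixel_pitch_mm)
  .validateGeneratorConfig(cfg)
  class(cfg) <- "GeneratorConfig"
  cfg
}

.checkPriors <- function(p, len, what) {
  if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(sprintf("config error: %s must be %d nonnegative values summing to 1",
                 what, len), call. = FALSE)
}

.validateGeneratorConfig <- function(cfg) {
  if (cfg$n < 0L) stop("config error: n must be nonnegative", call. = FALSE)
  .checkPriors(cfg$location_priors, 6L, "location_priors")
  .checkPriors(cfg$texture_priors, 3L, "texture_priors")
  m <- cfg$margin_priors_given_texture
  if (!is.matrix(m) || !all(dim(m) == c(3L, 4L)))
    stop("config error: margin_priors_given_texture must be 3 x 4",
         call. = FALSE)
  for (i in 1:3) .checkPriors(m[i, ], 4L,
                              sprintf("margin_priors_given_texture row %d", i))
  if (cfg$effect_size < 0 || cfg$noise_sd <= 0)
    stop("config error: effect_size >= 0 and noise_sd > 0 required",
         call. = FALSE)
  if (cfg$total_slices < 1L || cfg$slice_thickness_mm <= 0 ||
      cfg$pixel_pitch_mm <= 0)
    stop("config error: stack geometry must be positive", call. = FALSE)
  invisible(TRUE)
}

## Disjoint radiomics dimension blocks per task, fixed by registry order:
## texture -> Intensity + GLCM, margin -> Shape + GLDM,
## location -> GLRLM + GLSZM + NGTDM. Each task block is split into
## near-equal contiguous sub-blocks, one per class.
.taskBlocks <- function(registry) {
  g <- registryGroups(registry)
  rad <- radiomicsNames(registry)
  idx <- function(groups) match(unlist(g[groups], use.names = FALSE), rad)
  split_even <- function(ix, k) {
    split(ix, rep(seq_len(k), times = diff(floor(seq(0, length(ix), length.out = k + 1)))))
  }
  list(
    texture = split_even(idx(c("Intensity", "GLCM")), 3L),
    margin = split_even(idx(c("Shape", "GLDM")), 4L),
    location = split_even(idx(c("GLRLM", "GLSZM", "NGTDM")), 6L)
  )
}

#' Class-conditional radiomics prototype
#'
#' The deterministic mean vector of the 107 radiomics dimensions for a
#' given label triple. Each task owns a disjoint block of dimensions
#' (texture: intensity + GLCM; margin: shape + GLDM; location: GLRLM +
#' GLSZM + NGTDM, fixed by registry order); within a task's block, the
#' contiguous sub-block indexed by the label's class is shifted by
#' `+effect_size`. With `effect_size = 0` every triple collapses to the
#' zero prototype.
#'
#' @param labels List or named character vector with elements `location`,
#'   `texture`, `margin` (canonical or case-insensitive spellings).
#' @param registry A [FeatureRegistry-class].
#' @param config A [generatorConfig()].
#' @return Named numeric vector over the radiomics names.
#' @export
classConditionalMean <- function(labels, registry = buildDefaultRegistry(),
                                 config = generatorConfig()) {
  loc <- match(as.character(.parseLabelVector(labels[["location"]],
    locationLevels(), "location")), locationLevels())
  tex <- match(as.character(.parseLabelVector(labels[["texture"]],
    textureLevels(), "texture")), textureLevels())
  mar <- match(as.character(.parseLabelVector(labels[["margin"]],
    marginLevels(), "margin")), marginLevels())
  rad <- radiomicsNames(registry)
  mu <- stats::setNames(numeric(length(rad)), rad)
  blocks <- .taskBlocks(registry)
  mu[blocks$texture[[tex]]] <- config$effect_size
  mu[blocks$margin[[mar]]] <- config$effect_size
  mu[blocks$location[[loc]]] <- config$effect_size
  mu
}

## Axial placement of a nodule: upper-lobe labels occupy the top third of
## the stack, middle-lobe/lingular the middle third, lower-lobe the bottom
## third. Returns 1-based first slice and per-slice labeled pixel areas
## (unimodal elliptical profile).
.locationBand <- function(location, total_slices) {
  band <- switch(location,
    RUL = 1L, LUL = 1L,
    RML = 2L, LingularLobe = 2L,
    RLL = 3L, LLL = 3L)
  b0 <- floor((band - 1L) * total_slices / 3) + 1L
  b1 <- floor(band * total_slices / 3)
  c(b0, b1)
}

.axialProfile <- function(size_mm, n_lab, pixel_pitch_mm) {
  rel <- (seq_len(n_lab) - 0.5) / n_lab        # slice centres in (0, 1)
  r_mm <- (size_mm / 2) * sqrt(pmax(0, 1 - (2 * rel - 1)^2))
  r_px <- pmax(1, r_mm / pixel_pitch_mm)
  pmax(1, round(pi * r_px^2))
}

.axialExtent <- function(location, size_mm, config, offset_unit) {
  n_lab <- as.integer(ceiling(size_mm / config$slice_thickness_mm))
  if (n_lab >= config$total_slices || size_mm >= config$total_slices * config$slice_thickness_mm)
    stop("value error: nodule size too large for the stack", call. = FALSE)
  band <- .locationBand(location, config$total_slices)
  slack <- max(0L, band[2L] - band[1L] + 1L - n_lab)
  start <- band[1L] + min(slack, as.integer(floor(offset_unit * (slack + 1L))))
  start <- min(start, config$total_slices - n_lab + 1L)
  areas <- numeric(config$total_slices)
  areas[start:(start + n_lab - 1L)] <-
    .axialProfile(size_mm, n_lab, config$pixel_pitch_mm)
  list(start = start, n_lab = n_lab, areas = areas)
}

#' Simulate a labeled synthetic cohort
#'
#' Draws `n` label triples from the configured priors, sizes from the
#' truncated log-normal, radiomics features as prototype + Gaussian noise
#' (`x = mu(labels) + eps`, `eps ~ N(0, noise_sd^2)` i.i.d.), and SISN
#' features from a simulated axial extent consistent with each nodule's
#' size and location band. Fully reproducible from `config$seed`.
#'
#' @param config A [generatorConfig()].
#' @param registry A [FeatureRegistry-class].
#' @return A fully labeled [NoduleCohort-class] with `n` records.
#' @examples
#' co <- simulateCohort(generatorConfig(n = 5, seed = 42))
#' semanticLabels(co)
#' @export
simulateCohort <- function(config = generatorConfig(),
                           registry = buildDefaultRegistry()) {
  .validateGeneratorConfig(config)
  n <- config$n
  set.seed(config$seed)
  loc <- sample(locationLevels(), n, replace = TRUE,
                prob = config$location_priors)
  tex <- sample(textureLevels(), n, replace = TRUE,
                prob = config$texture_priors)
  mar <- character(n)
  for (i in seq_len(n)) {
    p <- config$margin_priors_given_texture[match(tex[i], textureLevels()), ]
    mar[i] <- sample(marginLevels(), 1L, prob = p)
  }
  ## truncated log-normal sizes in (0, 30) mm, by rejection
  size <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rlnorm(length(todo), config$size_log_mean,
                          config$size_log_sd)
    ok <- draw > 0 & draw < 30
    size[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  rad <- radiomicsNames(registry)
  feat <- matrix(0, nrow = length(featureNames(registry)), ncol = n,
                 dimnames = list(featureNames(registry), NULL))
  if (n > 0L) {
    noise <- matrix(stats::rnorm(length(rad) * n, sd = config$noise_sd),
                    nrow = length(rad))
    offs <- stats::runif(n)
    for (i in seq_len(n)) {
      mu <- classConditionalMean(
        list(location = loc[i], texture = tex[i], margin = mar[i]),
        registry, config)
      feat[rad, i] <- mu + noise[, i]
      ext <- .axialExtent(loc[i], size[i], config, offs[i])
      feat[sisnNames(registry), i] <-
        .sisnFromAreas(ext$areas)[sisnNames(registry)]
    }
  }
  NoduleCohort(feat, size_mm = size, registry = registry,
               location = if (n) loc, texture = if (n) tex,
               margin = if (n) mar,
               record_id = if (n) sprintf("syn_%04d", seq_len(n)) else character(0),
               provenance = list(generator = "simulateCohort",
                                 seed = config$seed, n = n))
}

#' Simulate a phantom segmentation stack
#'
#' Builds a 3D binary mask with a contiguous run of labeled slices whose
#' axial extent is `ceiling(size_mm / slice_thickness_mm)` slices, placed
#' inside the stack band implied by the location label (upper lobes in the
#' top third, middle/lingular in the middle, lower lobes in the bottom).
#' Per-slice labeled areas follow a unimodal elliptical profile.
#'
#' @param labels List with `location`, `texture`, `margin` (only location
#'   affects placement).
#' @param size_mm Nodule diameter, mm; must be below
#'   `total_slices * slice_thickness_mm`.
#' @param config A [generatorConfig()] (stack geometry).
#' @param seed Integer seed for the in-band placement.
#' @param plane_px Side length of each slice in pixels.
#' @return A [PhantomStack-class].
#' @examples
#' ph <- simulatePhantom(list(location = "RUL", texture = "Solid",
#'                            margin = "Lobulated"), size_mm = 12,
#'                       config = generatorConfig(), seed = 7)
#' computeSISN(ph)
#' @export
simulatePhantom <- function(labels, size_mm, config = generatorConfig(),
                            seed = 0L, plane_px = 64L) {
  .validateGeneratorConfig(config)
  loc <- as.character(.parseLabelVector(labels[["location"]],
                                        locationLevels(), "location"))
  set.seed(as.integer(seed))
  ext <- .axialExtent(loc, size_mm, config, stats::runif(1L))
  mask <- array(0L, c(config$total_slices, plane_px, plane_px))
  ctr <- (plane_px + 1) / 2
  d2 <- outer((seq_len(plane_px) - ctr)^2, (seq_len(plane_px) - ctr)^2, "+")
  rel <- (seq_len(ext$n_lab) - 0.5) / ext$n_lab
  r_mm <- (size_mm / 2) * sqrt(pmax(0, 1 - (2 * rel - 1)^2))
  r_px <- pmax(1, r_mm / config$pixel_pitch_mm)
  for (k in seq_len(ext$n_lab)) {
    sl <- matrix(0L, plane_px, plane_px)
    sl[d2 <= r_px[k]^2] <- 1L
    mask[ext$start + k - 1L, , ] <- sl
  }
  new("PhantomStack", mask = mask,
      slice_thickness_mm = config$slice_thickness_mm,
      pixel_pitch_mm = config$pixel_pitch_mm)
}
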