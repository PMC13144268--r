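## Synthetic DaT-SPECT phantom: paired short (1-cycle) / long (5-cycle-sum)
## striatal acquisitions with known per-hemisphere uptake patterns.

#' Validate a striatal uptake pattern score
#'
#' The four-point visual scale for per-hemisphere striatal uptake:
#' 1 = burst striatum, 2 = egg shape, 3 = eagle wing, 4 = normal.
#'
#' @param value integer scalar in 1..4.
#' @return the validated integer score.
#' @export
striatal_pattern <- function(value) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      value != as.integer(value) || !(value %in% 1:4)) {
    stop("pattern score must be a single integer in 1..4 ",
         "(1=burst striatum, 2=egg shape, 3=eagle wing, 4=normal), got: ",
         deparse(substitute(value)), " = ", paste(value, collapse = ","))
  }
  as.integer(value)
}

#' Phantom acquisition specification
#'
#' Geometry and counting statistics of the synthetic acquisition. Defaults
#' mirror the clinical protocol being emulated: 128 x 128 pixels of 3.29 mm,
#' five ~5-min cycles whose sum is the 25-min reference image.
#'
#' @param grid_xy in-plane image size in pixels (square).
#' @param n_slices number of axial slices (>= 5).
#' @param pixel_size pixel size in mm.
#' @param background_activity relative uptake of non-striatal brain tissue.
#' @param striatal_activity relative uptake of a fully normal striatum
#'   (specific binding of caudate and putamen); typical normal
#'   striatum-to-background ratios motivate the default of 8.
#' @param psf_fwhm collimator point-spread FWHM in mm (isotropic Gaussian).
#' @param counts_per_cycle expected total counts per slice per cycle.
#' @param n_cycles number of acquisition cycles summed into the long image.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_xy = 128L, n_slices = 15L, pixel_size = 3.29,
                         background_activity = 1, striatal_activity = 8,
                         psf_fwhm = 10, counts_per_cycle = 20000,
                         n_cycles = 5L) {
  stopifnot(grid_xy >= 16, n_slices >= 5, pixel_size > 0,
            background_activity >= 0, striatal_activity >= 0,
            psf_fwhm > 0, counts_per_cycle > 0, n_cycles >= 1)
  structure(list(grid_xy = as.integer(grid_xy), n_slices = as.integer(n_slices),
                 pixel_size = pixel_size,
                 background_activity = background_activity,
                 striatal_activity = striatal_activity, psf_fwhm = psf_fwhm,
                 counts_per_cycle = counts_per_cycle,
                 n_cycles = as.integer(n_cycles)),
            class = "phantom_spec")
}

# Region geometry in reference 128-pixel coordinates (1-based, row = anterior
# to posterior, mid-sagittal plane between the two central columns). Scaled
# linearly to other grid sizes. Shapes are configuration, not science.
.striatal_regions <- list(
  caudate  = list(row = 55.0, dcol = 6.0,  semi_r = 4.5, semi_c = 3.0),
  ant_put  = list(row = 62.0, dcol = 10.0, semi_r = 4.0, semi_c = 3.0),
  post_put = list(row = 69.0, dcol = 11.5, semi_r = 5.0, semi_c = 3.0)
)
.brain_semi <- c(r = 27, c = 23)
# axial extent: 5 central slices, mask radii scaled (tapered) toward the ends
.axial_scale <- c(0.5, 0.8, 1.0, 0.8, 0.5)

.ellipse_mask <- function(g, center_r, center_c, semi_r, semi_c) {
  r <- matrix(seq_len(g), g, g)
  c_ <- matrix(seq_len(g), g, g, byrow = TRUE)
  ((r - center_r) / semi_r)^2 + ((c_ - center_c) / semi_c)^2 <= 1
}

# Per-subregion intensity for a given pattern score.
.pattern_intensity <- function(pattern, bg, act) {
  switch(pattern,
         `1` = c(caudate = bg, ant_put = bg, post_put = bg),
         `2` = c(caudate = act, ant_put = bg, post_put = bg),
         `3` = c(caudate = act, ant_put = act,
                 post_put = bg + 0.5 * (act - bg)),
         `4` = c(caudate = act, ant_put = act, post_put = act))
}

#' Build a phantom activity volume with requested uptake patterns
#'
#' Constructs a 3-D activity map: a uniform brain ellipse plus bilateral
#' comma-shaped striata (caudate, anterior putamen, posterior putamen) whose
#' sub-region intensities realise the requested pattern per hemisphere.
#' Pattern 4 keeps the full striatum at `striatal_activity`; 3 halves the
#' posterior putamen's specific uptake; 2 keeps only the caudate; 1 lowers the
#' whole striatum to background. Mild jitter (position <= 1 px, intensity
#' <= 10%) is seeded independently per hemisphere so editing one side never
#' perturbs the other.
#'
#' @param spec a [phantom_spec()].
#' @param left,right pattern scores 1..4 for the left/right hemisphere.
#' @param seed integer seed controlling jitter.
#' @param jitter logical; disable for exactly symmetric, nominal geometry.
#' @param case_id identifier stored with the case.
#' @return an object of class `phantom_case` with elements `activity`
#'   (array slices x rows x cols), `masks` (per-hemisphere sub-region voxel
#'   indices), `left_pattern`, `right_pattern`, `spec`, `case_id`.
#' @export
make_activity_volume <- function(spec, left, right, seed = 1L, jitter = TRUE,
                                 case_id = "case") {
  stopifnot(inherits(spec, "phantom_spec"))
  left <- striatal_pattern(left); right <- striatal_pattern(right)
  g <- spec$grid_xy; nz <- spec$n_slices
  u <- g / 128
  mid <- (g + 1) / 2
  activity <- array(0, dim = c(nz, g, g))
  brain2d <- .ellipse_mask(g, mid, mid, .brain_semi["r"] * u, .brain_semi["c"] * u)
  for (s in seq_len(nz)) activity[s, , ][brain2d] <- spec$background_activity

  zc <- as.integer(ceiling(nz / 2))
  zs <- (zc - 2):(zc + 2)
  stopifnot(all(zs >= 1 & zs <= nz))

  masks <- list(L = list(), R = list())
  half_cols <- list(L = seq_len(floor(g / 2)), R = (floor(g / 2) + 1):g)
  patterns <- c(L = left, R = right)
  for (hemi in c("L", "R")) {
    sgn <- if (hemi == "R") 1 else -1
    hseed <- derive_seed(seed, match(hemi, c("L", "R")))
    jit <- if (jitter) with_seed(hseed, list(dr = stats::runif(1, -1, 1),
                                             dc = stats::runif(1, -1, 1),
                                             f  = stats::runif(1, 0.9, 1.1)))
           else list(dr = 0, dc = 0, f = 1)
    act_h <- spec$background_activity +
      jit$f * (spec$striatal_activity - spec$background_activity)
    vals <- .pattern_intensity(as.character(patterns[[hemi]]),
                               spec$background_activity, act_h)
    taken2d <- matrix(FALSE, g, g)
    hemi_masks <- list(caudate = integer(0), ant_put = integer(0),
                       post_put = integer(0))
    in_half <- matrix(FALSE, g, g); in_half[, half_cols[[hemi]]] <- TRUE
    for (iz in seq_along(zs)) {
      sc <- .axial_scale[iz]
      taken2d[] <- FALSE
      for (reg in names(.striatal_regions)) {
        geo <- .striatal_regions[[reg]]
        m <- .ellipse_mask(g,
                           mid + (geo$row - 64.5) * u + jit$dr,
                           mid + sgn * geo$dcol * u + jit$dc,
                           geo$semi_r * u * sc, geo$semi_c * u * sc)
        m <- m & brain2d & in_half & !taken2d   # disjoint by priority
        taken2d <- taken2d | m
        sl <- activity[zs[iz], , ]
        sl[m] <- vals[[reg]]
        activity[zs[iz], , ] <- sl
        # voxel indices in the 3-D array
        idx2 <- which(m)
        if (length(idx2)) {
          r_ <- (idx2 - 1L) %% g + 1L
          c_ <- (idx2 - 1L) %/% g + 1L
          hemi_masks[[reg]] <- c(hemi_masks[[reg]],
            (c_ - 1L) * (nz * g) + (r_ - 1L) * nz + zs[iz])
        }
      }
    }
    masks[[hemi]] <- hemi_masks
  }
  stopifnot(all(is.finite(activity)), all(activity >= 0))
  structure(list(case_id = case_id, activity = activity, masks = masks,
                 left_pattern = left, right_pattern = right, spec = spec),
            class = "phantom_case")
}

#' Expected single-cycle image of a phantom case
#'
#' Activity blurred by the collimator PSF (isotropic Gaussian of
#' `psf_fwhm` mm, voxels assumed isotropic at `pixel_size` mm) and scaled so
#' that every non-empty slice's expected total equals `counts_per_cycle`.
#'
#' @param case a `phantom_case`.
#' @return array (slices x rows x cols) of expected counts per cycle.
#' @export
expected_cycle <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  if (!all(is.finite(case$activity))) stop("non-finite activity")
  spec <- case$spec
  sigma_px <- spec$psf_fwhm / (2 * sqrt(2 * log(2))) / spec$pixel_size
  ex <- gaussian_blur3d(case$activity, sigma_px)
  ex[ex < 0] <- 0
  for (s in seq_len(spec$n_slices)) {
    tot <- sum(ex[s, , ])
    if (tot > 0) ex[s, , ] <- ex[s, , ] * (spec$counts_per_cycle / tot)
  }
  ex
}

#' Simulate one acquisition cycle (Poisson counts)
#'
#' @param case a `phantom_case`.
#' @param seed integer seed; identical seeds give identical count grids.
#' @param expected optionally, a precomputed [expected_cycle()] image.
#' @return array (slices x rows x cols) of Poisson counts.
#' @export
simulate_cycle <- function(case, seed, expected = NULL) {
  ex <- expected %||% expected_cycle(case)
  counts <- with_seed(seed, stats::rpois(length(ex), lambda = ex))
  array(as.numeric(counts), dim = dim(ex))
}

#' Simulate a paired short/long acquisition
#'
#' The short stack is cycle 1 alone; the long stack is the pixel-wise sum of
#' `n_cycles` independent cycles (cycle 1 included); the noiseless stack is
#' the expected single-cycle image times `n_cycles`.
#'
#' @param case a `phantom_case`.
#' @param seed integer seed (cycle seeds are derived from it).
#' @return an object of class `acquisition_pair` with `short_stack`,
#'   `long_stack`, `noiseless_stack`, `case_id`.
#' @export
simulate_acquisition_pair <- function(case, seed) {
  stopifnot(inherits(case, "phantom_case"))
  ex <- expected_cycle(case)
  long <- array(0, dim = dim(ex))
  short <- NULL
  for (i in seq_len(case$spec$n_cycles)) {
    cyc <- simulate_cycle(case, derive_seed(seed, i), expected = ex)
    if (i == 1L) short <- cyc
    long <- long + cyc
  }
  structure(list(case_id = case$case_id, short_stack = short,
                 long_stack = long,
                 noiseless_stack = ex * case$spec$n_cycles),
            class = "acquisition_pair")
}

#' Generate a reproducible synthetic cohort
#'
#' Pattern scores are drawn per hemisphere from `pattern_prevalence`; each
#' case's geometry jitter and Poisson noise use child seeds derived from the
#' master seed and the case index, so enlarging the cohort never changes
#' earlier cases.
#'
#' @param n_cases number of cases (0 allowed, giving an empty cohort).
#' @param pattern_prevalence probability 4-vector over scores 1..4 (applied to
#'   both hemispheres), or a 2 x 4 matrix with rows L, R. Default follows the
#'   gold-standard score distribution of the emulated reader study
#'   (17/29/28/26 per 100 striata).
#' @param spec a [phantom_spec()].
#' @param seed master integer seed.
#' @return an object of class `dat_cohort`: lists `cases` and `pairs`, a
#'   `truth` data frame (case_id, hemisphere, score), plus `spec` and `seed`.
#' @export
generate_cohort <- function(n_cases,
                            pattern_prevalence = c(0.17, 0.29, 0.28, 0.26),
                            spec = phantom_spec(), seed = 1L) {
  stopifnot(n_cases >= 0)
  prev <- pattern_prevalence
  if (is.matrix(prev)) {
    stopifnot(nrow(prev) == 2, ncol(prev) == 4)
  } else {
    stopifnot(length(prev) == 4)
    prev <- rbind(prev, prev)
  }
  if (any(prev < 0) || any(abs(rowSums(prev) - 1) > 1e-9))
    stop("pattern_prevalence rows must be non-negative and sum to 1 (tol 1e-9)")
  cases <- vector("list", n_cases)
  pairs <- vector("list", n_cases)
  truth <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    id <- sprintf("case_%04d", i)
    pl <- with_seed(derive_seed(seed, i, 101L),
                    c(sample(1:4, 1, prob = prev[1, ]),
                      sample(1:4, 1, prob = prev[2, ])))
    cases[[i]] <- make_activity_volume(spec, left = pl[1], right = pl[2],
                                       seed = derive_seed(seed, i, 102L),
                                       case_id = id)
    pairs[[i]] <- simulate_acquisition_pair(cases[[i]],
                                            seed = derive_seed(seed, i, 103L))
    truth[[i]] <- data.frame(case_id = id, hemisphere = c("L", "R"),
                             score = pl, stringsAsFactors = FALSE)
  }
  structure(list(cases = cases, pairs = pairs,
                 truth = if (n_cases) do.call(rbind, truth)
                         else data.frame(case_id = character(0),
                                         hemisphere = character(0),
                                         score = integer(0)),
                 spec = spec, seed = as.integer(seed)),
            class = "dat_cohort")
}

#' @export
print.dat_cohort <- function(x, ...) {
  cat("DaT phantom cohort:", length(x$cases), "cases,",
      x$spec$grid_xy, "x", x$spec$grid_xy, "x", x$spec$n_slices,
      "voxels, ", x$spec$n_cycles, "cycles\n")
  if (nrow(x$truth))
    print(table(factor(x$truth$score, levels = 1:4)))
  invisible(x)
}
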