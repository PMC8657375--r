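#' Specification for a synthetic paired-modality phantom cohort
#'
#' The phantom emulates the data regime the pipeline assumes: skull-stripped,
#' co-registered, isotropic brain volumes in which a compact hyperintense
#' lesion occupies on average ~7% of the brain, accompanied by small bright
#' distractor spots outside the lesion (the confounders that make box
#' masking consequential). Two modality channels ("FLAIR"-like and
#' "T2w"-like) share geometry but differ in lesion gain and noise.
#'
#' @param grid_shape integer length-3, voxel grid; minimum (16, 16, 8).
#'   The third axis is axial.
#' @param brain_radius_frac ellipsoid semi-axes as a fraction of each grid
#'   dimension.
#' @param tumour_volume_frac_mean,tumour_volume_frac_sd mean and sd of the
#'   per-case lesion volume as a fraction of brain volume.
#' @param tumour_region `"hemisphere"` (training regime: lateral, superior)
#'   or `"midline"` (shifted regime: central, inferior, standing in for a
#'   pontine location).
#' @param contrast named list (one entry per modality) of lists with fields
#'   `lesion_gain`, `distractor_count`, `noise_sd` and optionally
#'   `distractor_gain` (default 1; independent of `lesion_gain`, since the
#'   healthy bright structures the distractors emulate do not dim when
#'   tumour contrast drops).
#' @param missing_modality_prob probability that a generated case retains
#'   only one of its modalities.
#' @param seed integer cohort seed; together with a per-case seed it makes
#'   every case bit-reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         brain_radius_frac = 0.45,
                         tumour_volume_frac_mean = 0.07,
                         tumour_volume_frac_sd = 0.02,
                         tumour_region = c("hemisphere", "midline"),
                         contrast = list(
                           FLAIR = list(lesion_gain = 1.0, distractor_count = 3,
                                        noise_sd = 0.06),
                           T2w = list(lesion_gain = 0.8, distractor_count = 3,
                                      noise_sd = 0.06)
                         ),
                         missing_modality_prob = 0,
                         seed = 1L) {
  tumour_region <- match.arg(tumour_region)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < c(16L, 16L, 8L))) {
    stop("`grid_shape` must be 3 integers, at least (16, 16, 8)")
  }
  if (!(tumour_volume_frac_mean > 0 && tumour_volume_frac_mean < 0.5)) {
    stop("`tumour_volume_frac_mean` must lie in (0, 0.5)")
  }
  if (tumour_volume_frac_sd < 0) stop("`tumour_volume_frac_sd` must be >= 0")
  if (brain_radius_frac <= 0 || brain_radius_frac > 0.5) {
    stop("`brain_radius_frac` must lie in (0, 0.5]")
  }
  if (missing_modality_prob < 0 || missing_modality_prob > 1) {
    stop("`missing_modality_prob` must lie in [0, 1]")
  }
  if (length(contrast) < 1L || is.null(names(contrast))) {
    stop("`contrast` must be a named list of per-modality settings")
  }
  for (m in names(contrast)) {
    cm <- contrast[[m]]
    if (is.null(cm$lesion_gain) || is.null(cm$distractor_count) ||
        is.null(cm$noise_sd)) {
      stop("each `contrast` entry needs lesion_gain, distractor_count, noise_sd")
    }
    if (cm$noise_sd < 0) stop("`noise_sd` must be >= 0 (modality ", m, ")")
  }
  structure(
    list(grid_shape = grid_shape, brain_radius_frac = brain_radius_frac,
         tumour_volume_frac_mean = tumour_volume_frac_mean,
         tumour_volume_frac_sd = tumour_volume_frac_sd,
         tumour_region = tumour_region, contrast = contrast,
         missing_modality_prob = missing_modality_prob,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Shift a phantom spec to the unseen-region test regime
#'
#' Produces the domain-shifted counterpart of a hemisphere spec: the lesion
#' is relocated to the central-inferior brain (the stand-in for a pontine
#' location never seen in training), lesion contrast is slightly reduced and
#' noise slightly increased. All other fields are unchanged.
#'
#' @param spec a hemisphere [phantom_spec()].
#' @param gain_factor multiplicative change to each modality's lesion gain.
#' @param noise_factor multiplicative change to each modality's noise sd.
#' @return the shifted `phantom_spec`.
#' @export
shift_domain <- function(spec, gain_factor = 0.8, noise_factor = 1.25) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$tumour_region != "hemisphere") {
    stop("spec is already domain-shifted (tumour_region = \"",
         spec$tumour_region, "\")")
  }
  spec$tumour_region <- "midline"
  for (m in names(spec$contrast)) {
    spec$contrast[[m]]$lesion_gain <- spec$contrast[[m]]$lesion_gain * gain_factor
    spec$contrast[[m]]$noise_sd <- spec$contrast[[m]]$noise_sd * noise_factor
  }
  spec
}

# Squared normalised ellipsoid distance field over the full grid.
ellipsoid_field <- function(dm, center, semi) {
  dx <- ((seq_len(dm[1]) - center[1]) / semi[1])^2
  dy <- ((seq_len(dm[2]) - center[2]) / semi[2])^2
  dz <- ((seq_len(dm[3]) - center[3]) / semi[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}

# Lesion centre for a region, in voxel coordinates (with jitter).
lesion_center <- function(spec) {
  dm <- spec$grid_shape
  bc <- (dm + 1) / 2
  semi <- spec$brain_radius_frac * dm
  if (spec$tumour_region == "hemisphere") {
    off <- c(runif(1, 0.35, 0.55) * semi[1],
             runif(1, -0.25, 0.25) * semi[2],
             runif(1, 0.15, 0.35) * semi[3])
  } else { # midline: central in-plane, inferior along z
    off <- c(runif(1, -0.08, 0.08) * semi[1],
             runif(1, -0.08, 0.08) * semi[2],
             runif(1, -0.6, -0.45) * semi[3])
  }
  bc + off
}

# Build a lesion blob (union of 3 perturbed ellipsoids) inside `brain`,
# scaled by bisection so that |blob & brain| hits `target` voxels.
lesion_blob <- function(dm, brain, center, target) {
  r0 <- (3 * target / (4 * pi))^(1 / 3) # equivalent-sphere radius
  k <- 3L
  comps <- lapply(seq_len(k), function(i) {
    list(center = center + rnorm(3, 0, 0.45 * r0),
         semi = r0 * runif(3, 0.65, 1.15))
  })
  blob_at <- function(s) {
    acc <- array(FALSE, dm)
    for (cp in comps) {
      acc <- acc | (ellipsoid_field(dm, cp$center, pmax(cp$semi * s, 0.6)) <= 1)
    }
    acc & (brain > 0)
  }
  lo <- 0.2; hi <- 4
  for (iter in 1:28) {
    mid <- (lo + hi) / 2
    if (sum(blob_at(mid)) < target) lo <- mid else hi <- mid
  }
  blob_at(hi)
}

#' Generate one synthetic phantom case
#'
#' Builds an ellipsoidal brain, a compact random lesion blob inside the
#' spec's region (hyperintense on every modality, with modality-specific
#' gain), bright spherical distractors outside the lesion, smooth intensity
#' inhomogeneity and additive noise. Fully reproducible from
#' `(spec$seed, case_seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer per-case seed.
#' @return an object of class `phantom_case` with fields `volumes` (named
#'   list of [volume()]s), `gt`, `brain_mask` (binary arrays), `tumour_frac`
#'   and `provenance`.
#' @export
generate_case <- function(spec, case_seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  with_seed(case_seed_of(spec$seed, case_seed), {
    bc <- (dm + 1) / 2
    semi <- spec$brain_radius_frac * dm
    brain <- (ellipsoid_field(dm, bc, semi) <= 1)
    n_brain <- sum(brain)

    center <- lesion_center(spec)
    cdist <- sum(((center - bc) / semi)^2)
    if (cdist > 1) {
      stop("tumour region does not fit inside the brain: check ",
           "`tumour_region`/`brain_radius_frac`/`grid_shape`")
    }
    f <- rnorm(1, spec$tumour_volume_frac_mean, spec$tumour_volume_frac_sd)
    f <- min(max(f, 0.005), 0.45)
    gt <- lesion_blob(dm, brain, center, round(f * n_brain))

    # smooth multiplicative-style inhomogeneity shared across modalities
    ph <- runif(6, 0, 2 * pi)
    gx <- seq_len(dm[1]) / dm[1]; gy <- seq_len(dm[2]) / dm[2]
    gz <- seq_len(dm[3]) / dm[3]
    inhom <- 0.06 * (outer(outer(sin(2 * pi * gx + ph[1]),
                                 cos(2 * pi * gy + ph[2]), `+`),
                           sin(2 * pi * gz + ph[3]), `+`)) / 3

    # Distractor bright spots emulate healthy structures a per-slice
    # segmenter confuses with tumour: lesion-like in-plane extent but thin
    # along z (so the axial opening can reject their box detections),
    # shared geometry across modalities (so confidence ensembling does not
    # remove them), and brightness independent of the lesion gain (healthy
    # structures do not dim when tumour contrast drops).
    r0 <- (3 * sum(gt) / (4 * pi))^(1 / 3)
    max_count <- max(vapply(spec$contrast, `[[`, numeric(1),
                            "distractor_count"))
    spots_geom <- list()
    tries <- 0L
    while (length(spots_geom) < max_count && tries < 300L) {
      tries <- tries + 1L
      p <- bc + (runif(3, -0.75, 0.75) * semi)
      pi_ <- round(p)
      if (any(pi_ < 1) || any(pi_ > dm)) next
      if (!brain[pi_[1], pi_[2], pi_[3]] || gt[pi_[1], pi_[2], pi_[3]]) next
      rxy <- runif(2, 0.35, 0.6) * r0
      rz <- runif(1, 1.4, 2.2)
      sp <- ellipsoid_field(dm, p, c(rxy, rz)) <= 1
      if (any(sp & gt)) next
      spots_geom[[length(spots_geom) + 1]] <-
        list(mask = sp & brain, amp = runif(1, 0.85, 1.15))
    }

    mods <- names(spec$contrast)
    keep <- mods
    if (length(mods) > 1 && runif(1) < spec$missing_modality_prob) {
      keep <- sample(mods, 1L)
    }

    vols <- list()
    for (m in mods) {
      cm <- spec$contrast[[m]]
      dgain <- cm$distractor_gain %||% 1.0
      img <- array(0, dm)
      img[brain] <- 1 + inhom[brain]
      img <- img + cm$lesion_gain * (gt * 1)
      n_spots <- min(cm$distractor_count, length(spots_geom))
      if (n_spots > 0) {
        for (sg in spots_geom[seq_len(n_spots)]) {
          img[sg$mask] <- pmax(img[sg$mask],
                               1 + dgain * sg$amp * runif(1, 0.9, 1.1))
        }
      }
      if (cm$noise_sd > 0) {
        img[brain] <- img[brain] + rnorm(n_brain, 0, cm$noise_sd)
      }
      if (m %in% keep) {
        vols[[m]] <- volume(img, spacing = c(1, 1, 1), modality = m,
                            brain_mask = brain * 1L)
      }
    }

    structure(
      list(volumes = vols,
           gt = array(as.integer(gt), dm),
           brain_mask = array(as.integer(brain), dm),
           tumour_frac = sum(gt) / n_brain,
           provenance = list(spec = spec, case_seed = as.integer(case_seed))),
      class = "phantom_case"
    )
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> modalities: %s  tumour/brain: %.3f  region: %s\n",
              paste(names(x$volumes), collapse = ", "), x$tumour_frac,
              x$provenance$spec$tumour_region))
  invisible(x)
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI volume per modality per case plus the ground-truth and
#' brain masks, and a manifest CSV with one row per case.
#'
#' @param spec a [phantom_spec()].
#' @param n number of cases (>= 1).
#' @param out_dir output directory (created if needed).
#' @param case_offset first case seed (cases use seeds
#'   `case_offset .. case_offset + n - 1`).
#' @return the manifest as a data.frame, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
generate_cohort <- function(spec, n, out_dir, case_offset = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- case_offset + i - 1L
    case <- generate_case(spec, cs)
    id <- sprintf("case%04d", cs)
    paths <- character(0)
    for (m in names(case$volumes)) {
      p <- file.path(out_dir, sprintf("%s_%s.nii.gz", id, m))
      write_volume(case$volumes[[m]], p)
      paths[m] <- p
    }
    gt_path <- file.path(out_dir, paste0(id, "_gt.nii.gz"))
    brain_path <- file.path(out_dir, paste0(id, "_brain.nii.gz"))
    write_volume(case$gt, gt_path)
    write_volume(case$brain_mask, brain_path)
    rows[[i]] <- data.frame(
      case_id = id, case_seed = cs,
      modalities = paste(names(case$volumes), collapse = ";"),
      volume_paths = paste(paths, collapse = ";"),
      gt_path = gt_path, brain_path = brain_path,
      tumour_frac = case$tumour_frac,
      region = spec$tumour_region,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom cohort written by [generate_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return a list of `phantom_case`-shaped lists (volumes, gt, brain_mask).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mods <- strsplit(row$modalities, ";")[[1]]
    paths <- strsplit(row$volume_paths, ";")[[1]]
    gt <- as_mask_array(read_volume(row$gt_path)$data, "gt")
    brain <- as_mask_array(read_volume(row$brain_path)$data, "brain_mask")
    vols <- list()
    for (k in seq_along(mods)) {
      v <- read_volume(paths[k], modality = mods[k])
      v$brain_mask <- brain
      vols[[mods[k]]] <- v
    }
    structure(list(volumes = vols, gt = gt, brain_mask = brain,
                   tumour_frac = row$tumour_frac,
                   provenance = list(case_id = row$case_id,
                                     case_seed = row$case_seed)),
              class = "phantom_case")
  })
}
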