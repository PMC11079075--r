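#' Synthetic dental CBCT phantom configuration
#'
#' The phantom reproduces the histogram structure the adaptive preprocessing
#' assumes: one or two narrow spikes (air and, optionally, outside-FOV
#' voxels, each sharing one exact gray value) plus one broad Gaussian
#' soft-tissue peak, with bone and teeth forming no distinct mode. Geometry
#' is parametric (ellipsoidal head, two bone arches, FDI-coded tooth
#' ellipsoids, a tubular mandibular canal, an ellipsoidal maxillary sinus),
#' not anatomically realistic; labels are the exact pre-noise geometry.
#'
#' @param dims Grid size in voxels, each >= 32 (default `c(96, 96, 80)`).
#' @param spacing Isotropic voxel spacing in mm (default 0.4).
#' @param air_value Exact gray value of air voxels (the spike; default 0).
#' @param outside_fov_value Exact gray value outside the cylindrical field
#'   of view (second spike; `NULL` disables the FOV cylinder; default -500).
#' @param soft_tissue_mean,soft_tissue_sd Mean and standard deviation of the
#'   soft-tissue gray values (defaults 300 and 40); this is the Gaussian
#'   peak the preprocessing fits.
#' @param bone_offset Bone mean above `soft_tissue_mean`, in gray units;
#'   must be at least 5 soft-tissue standard deviations (default 400).
#' @param tooth_offset Tooth mean above `soft_tissue_mean`
#'   (> `bone_offset`; default 700).
#' @param noise_sd Intensity-spread scale of mineralized tissue: bone and
#'   tooth gray values are drawn uniformly within plus/minus `6 * noise_sd`
#'   of their base value (default 30, i.e. a 360-unit band), so they smear
#'   into a low plateau instead of forming a histogram mode.
#' @param missing_fdi FDI codes of absent teeth (default none).
#' @param target_tooth_fraction Intended fraction of tooth-labeled voxels;
#'   teeth occupy roughly 1-3% of a dental CBCT volume (default 0.02).
#' @param intensity_scale,intensity_shift Affine "manufacturer profile"
#'   applied to all gray values after noise (defaults 1 and 0); see
#'   [manufacturer_profiles()].
#' @param seed Integer seed; the phantom is bit-reproducible for a fixed
#'   seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dims = c(96, 96, 80), spacing = 0.4,
                           air_value = 0, outside_fov_value = -500,
                           soft_tissue_mean = 300, soft_tissue_sd = 40,
                           bone_offset = 400, tooth_offset = 700,
                           noise_sd = 30, missing_fdi = integer(0),
                           target_tooth_fraction = 0.02,
                           intensity_scale = 1, intensity_shift = 0,
                           seed = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 32))
    cbct_abort("`dims` must be 3 integers, each >= 32.", "bad_config")
  if (!(tooth_offset > bone_offset && bone_offset > 0))
    cbct_abort("need tooth_offset > bone_offset > 0.", "bad_config")
  if (bone_offset < 5 * soft_tissue_sd)
    cbct_abort("`bone_offset` must be >= 5 soft-tissue standard deviations.",
               "bad_config")
  if (target_tooth_fraction <= 0 || target_tooth_fraction >= 0.1)
    cbct_abort("`target_tooth_fraction` must be in (0, 0.1).", "bad_config")
  if (intensity_scale <= 0)
    cbct_abort("`intensity_scale` must be positive.", "bad_config")
  if (length(missing_fdi) > 0 && !all(is_fdi(missing_fdi)))
    cbct_abort("`missing_fdi` contains invalid FDI codes.", "bad_config")
  structure(list(dims = dims, spacing = spacing, air_value = air_value,
                 outside_fov_value = outside_fov_value,
                 soft_tissue_mean = soft_tissue_mean,
                 soft_tissue_sd = soft_tissue_sd,
                 bone_offset = bone_offset, tooth_offset = tooth_offset,
                 noise_sd = noise_sd, missing_fdi = as.integer(missing_fdi),
                 target_tooth_fraction = target_tooth_fraction,
                 intensity_scale = intensity_scale,
                 intensity_shift = intensity_shift,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# All 32 permanent-tooth FDI codes
all_fdi_codes <- function() as.integer(outer(1:4 * 10, 1:8, `+`))

#' Generate a synthetic CBCT phantom with ground-truth labels
#'
#' Builds the parametric head geometry, assigns exact labels (0 background,
#' 1 maxilla, 2 mandible, 3 maxillary sinus, 4 mandibular canal, FDI codes
#' for teeth), then synthesizes gray values as class base intensity plus
#' Gaussian noise (air and outside-FOV voxels keep one exact value each, so
#' they form histogram spikes), and finally applies the affine manufacturer
#' profile. Deterministic for a fixed seed.
#'
#' @param config A [phantom_config()].
#' @return List with `volume` (a [cbct_volume()]), `labels`
#'   (a [cbct_labels()]), `tooth_fraction` (achieved fraction of
#'   tooth-labeled voxels) and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(dims = c(48, 48, 40), seed = 7))
#' ph$tooth_fraction
#' @export
generate_phantom <- function(config = phantom_config()) {
  d <- config$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n <- prod(d)

  # tooth size from the target voxel fraction; elongation 2.2 along z
  n_teeth <- length(setdiff(all_fdi_codes(), config$missing_fdi))
  v_tooth <- config$target_tooth_fraction * n / n_teeth
  r_tooth <- (v_tooth / ((4 / 3) * pi * 2.2))^(1 / 3)
  c_tooth <- 2.2 * r_tooth
  if (c_tooth > 0.12 * nz || r_tooth > 0.35 * 0.32 * min(nx, ny))
    cbct_abort(paste0(
      "teeth cannot reach the target voxel fraction within these grid ",
      "dimensions; increase `dims` or lower `target_tooth_fraction`."),
      "phantom_geometry")

  # voxel-centre coordinates, column-major
  x <- rep(seq_len(nx), times = ny * nz)
  y <- rep(rep(seq_len(ny), each = nx), times = nz)
  z <- rep(seq_len(nz), each = nx * ny)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  head <- ((x - cx) / (0.46 * nx))^2 + ((y - cy) / (0.46 * ny))^2 +
    ((z - (nz + 1) / 2) / (0.48 * nz))^2 <= 1

  # dental arches: circular arcs around a centre shifted backwards
  cy_a <- cy - 0.10 * ny
  R <- 0.32 * min(nx, ny)
  rb <- 0.09 * min(nx, ny)
  rxy <- sqrt((x - cx)^2 + (y - cy_a)^2)
  phi <- atan2(x - cx, y - cy_a)   # 0 points forward (+y)
  in_arch <- abs(rxy - R) <= rb & abs(phi) <= 85 * pi / 180
  mand_band <- z >= 0.18 * nz & z <= 0.42 * nz
  max_band <- z >= 0.58 * nz & z <= 0.82 * nz

  lab <- integer(n)
  lab[head & in_arch & max_band] <- 1L
  lab[head & in_arch & mand_band] <- 2L

  # maxillary sinuses: two ellipsoidal air cavities above the upper arch
  for (sx in c(-1, 1)) {
    sc <- c(cx + sx * 0.17 * nx, cy_a + 0.02 * ny, 0.72 * nz)
    sin_m <- ((x - sc[1]) / (0.07 * nx))^2 + ((y - sc[2]) / (0.09 * ny))^2 +
      ((z - sc[3]) / (0.07 * nz))^2 <= 1
    lab[sin_m & head] <- 3L
  }

  # mandibular canal: tube following the lower arch inside the bone
  rc <- max(1.6, 0.02 * min(nx, ny))
  zc <- 0.30 * nz
  canal <- (rxy - R)^2 + (z - zc)^2 <= rc^2 & abs(phi) <= 80 * pi / 180
  lab[canal & lab == 2L] <- 4L

  # teeth: ellipsoids along each arch, FDI coded; position 1 (central
  # incisor) at the front, position 8 (third molar) at the back
  codes <- setdiff(all_fdi_codes(), config$missing_fdi)
  for (code in codes) {
    q <- code %/% 10
    p <- code %% 10
    sgn <- if (q %in% c(1, 4)) -1 else 1   # quadrants 1/4 on the -x side
    ang <- sgn * (p * 10 - 5) * pi / 180
    tz <- if (q %in% c(1, 2)) 0.53 * nz else 0.47 * nz
    tc <- c(cx + R * sin(ang), cy_a + R * cos(ang), tz)
    tooth <- ((x - tc[1]) / r_tooth)^2 + ((y - tc[2]) / r_tooth)^2 +
      ((z - tc[3]) / c_tooth)^2 <= 1
    lab[tooth] <- code
  }

  tooth_fraction <- sum(lab >= 11L) / n

  withr::with_seed(config$seed, {
    mu_s <- config$soft_tissue_mean
    vals <- rep(config$air_value, n)
    soft <- head & lab == 0L
    vals[soft] <- mu_s + stats::rnorm(sum(soft), 0, config$soft_tissue_sd)
    # bone and teeth are spread over a broad, bounded band (half-width
    # 6 * noise_sd) so they form no distinct histogram mode: in CBCT only
    # soft tissue produces a peak, while mineralized tissue smears out
    hw <- 6 * config$noise_sd
    bone <- lab == 1L | lab == 2L
    vals[bone] <- mu_s + config$bone_offset +
      stats::runif(sum(bone), -hw, hw)
    teeth <- lab >= 11L
    vals[teeth] <- mu_s + config$tooth_offset +
      stats::runif(sum(teeth), -hw, hw)
    canal_v <- lab == 4L
    vals[canal_v] <- mu_s + stats::rnorm(sum(canal_v), 0,
                                         config$soft_tissue_sd)
    vals[lab == 3L] <- config$air_value   # sinus is an air cavity
    if (!is.null(config$outside_fov_value)) {
      fov <- (x - cx)^2 + (y - cy)^2 <= (0.49 * min(nx, ny))^2
      vals[!fov] <- config$outside_fov_value
      lab[!fov] <- 0L
    }
    vals <- config$intensity_scale * vals + config$intensity_shift
  })

  sp <- rep(config$spacing, 3)
  list(volume = cbct_volume(array(vals, d), spacing = sp),
       labels = cbct_labels(array(lab, d), spacing = sp),
       tooth_fraction = tooth_fraction,
       config = config)
}

#' Apply an affine manufacturer intensity profile
#'
#' CBCT gray values are not calibrated across devices; different
#' manufacturers produce different gray ranges and contrasts. This models
#' that variability as `v -> scale * v + shift`.
#'
#' @param volume A [cbct_volume()].
#' @param scale Positive multiplicative factor.
#' @param shift Additive offset in gray units.
#' @return A transformed [cbct_volume()].
#' @export
apply_intensity_profile <- function(volume, scale, shift = 0) {
  check_volume(volume)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    cbct_abort("`scale` must be a single positive number.", "bad_scale")
  out <- volume
  out$values <- scale * volume$values + shift
  out
}

#' Synthetic manufacturer intensity profiles
#'
#' Six affine scale/shift presets emulating the gray-range and contrast
#' spread seen across CBCT device manufacturers. The vendor names are
#' generic and the values are invented for testing; they are not
#' measurements of any real device.
#'
#' @return Tibble with columns `profile`, `scale`, `shift`.
#' @export
manufacturer_profiles <- function() {
  tibble::tibble(
    profile = paste0("vendor_", letters[1:6]),
    scale = c(1, 0.6, 0.8, 1.3, 1.8, 2.4),
    shift = c(0, -150, 200, 500, -100, 350))
}

shift_logical <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Controlled perturbation of a label volume
#'
#' Produces graded synthetic "predictions" for metric testing: per-class
#' morphological erosion or dilation by a ball of the given voxel radius, or
#' a rigid integer shift. Magnitude 0 is the identity for every kind.
#'
#' @param labels A [cbct_labels()].
#' @param kind `"erode"`, `"dilate"` or `"shift"`.
#' @param magnitude Non-negative radius (erode/dilate) or offset (shift) in
#'   voxels.
#' @param offset Optional integer length-3 shift vector overriding the
#'   default `c(magnitude, 0, 0)` (shift kind only).
#' @param seed Unused by the deterministic kinds; kept so batch drivers can
#'   pass one uniformly.
#' @return A perturbed [cbct_labels()].
#' @export
perturb_labels <- function(labels, kind = c("erode", "dilate", "shift"),
                           magnitude = 1, offset = NULL, seed = NULL) {
  if (!inherits(labels, "cbct_labels"))
    cbct_abort("`labels` must be a cbct_labels.", "bad_input")
  kind <- match.arg(kind)
  if (magnitude < 0)
    cbct_abort("`magnitude` must be >= 0.", "bad_config")
  if (magnitude == 0 && is.null(offset)) return(labels)
  lab <- labels$values
  d <- dim(lab)

  if (kind == "shift") {
    off <- as.integer(offset %||% c(magnitude, 0, 0))
    out <- array(0L, d)
    src <- dst <- vector("list", 3)
    for (ax in 1:3) {
      o <- off[ax]
      if (abs(o) >= d[ax])
        cbct_abort("shift magnitude exceeds grid size.", "bad_config")
      if (o >= 0) {
        dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
      } else {
        dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
      }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- lab[src[[1]], src[[2]], src[[3]]]
    return(cbct_labels(out, spacing = labels$spacing,
                       origin = labels$origin))
  }

  offs <- ball_offsets(magnitude)
  classes <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (kind == "erode") {
    out <- array(0L, d)
    for (k in classes) {
      m <- lab == k
      keep <- m
      for (i in seq_len(nrow(offs))) {
        if (all(offs[i, ] == 0)) next
        keep <- keep & shift_logical(m, offs[i, ])
        if (!any(keep)) break
      }
      out[keep] <- k
    }
  } else {
    out <- lab
    for (k in classes) {
      m <- lab == k
      grow <- m
      for (i in seq_len(nrow(offs))) {
        if (all(offs[i, ] == 0)) next
        grow <- grow | shift_logical(m, offs[i, ])
      }
      out[grow & lab == 0L & out == 0L] <- k
    }
  }
  cbct_labels(out, spacing = labels$spacing, origin = labels$origin)
}
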