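#' Bundle of co-registered resource maps
#'
#' Glucose (mM), oxygen (mg/L) and tissue stiffness (Pa) maps sharing one grid
#' shape, plus voxel-size metadata. These three fields define the
#' micro-environment a simulated tumor grows in.
#'
#' @param glucose,oxygen,stiffness Numeric matrices of identical shape.
#' @param voxel_mm Voxel edge length (mm); the default 2 mm gives the model's
#'   4 mm^2 voxel area.
#' @param mask Optional logical validity matrix (in-brain voxels).
#' @return An object of class `atlas_set`.
#' @export
atlas_set <- function(glucose, oxygen, stiffness, voxel_mm = 2, mask = NULL) {
  stop_if(!is.matrix(glucose) || !is.matrix(oxygen) || !is.matrix(stiffness),
          "all maps must be matrices")
  stop_if(!same_dim(glucose, oxygen) || !same_dim(glucose, stiffness),
          "all maps must share one shape")
  check_nonneg(oxygen, "oxygen")
  check_nonneg(stiffness, "stiffness")
  check_nonneg(glucose, "glucose")
  if (!is.null(mask)) stop_if(!same_dim(mask, glucose), "mask shape mismatch")
  structure(list(glucose = glucose, oxygen = oxygen, stiffness = stiffness,
                 voxel_mm = voxel_mm, mask = mask),
            class = "atlas_set")
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("Resource atlas %dx%d (%g mm voxels)\n",
              nrow(x$glucose), ncol(x$glucose), x$voxel_mm))
  cat(sprintf("  glucose  : %.3g - %.3g mM (mean %.3g)\n",
              min(x$glucose), max(x$glucose), mean(x$glucose)))
  cat(sprintf("  oxygen   : %.3g - %.3g mg/L (mean %.3g)\n",
              min(x$oxygen), max(x$oxygen), mean(x$oxygen)))
  cat(sprintf("  stiffness: %.4g - %.4g Pa (mean %.4g)\n",
              min(x$stiffness), max(x$stiffness), mean(x$stiffness)))
  invisible(x)
}

#' Convert an SUVr map to a glucose atlas
#'
#' FDG uptake (SUVr) is inversely related to free tissue glucose, so the map
#' is reflected and min-max scaled into the physiological brain glucose range:
#' the voxel with the highest SUVr maps to `lo` and the lowest to `hi`. The
#' transform is invariant under any positive affine rescaling of the input
#' (SUVr is dimensionless; the scaling assigns the unit).
#'
#' @param suvr Numeric matrix of SUVr values.
#' @param lo,hi Output range (mM); defaults 1.0 and 2.7.
#' @param mask Optional logical matrix of valid (in-brain) voxels; scaling
#'   statistics use valid voxels only and invalid voxels return `NA`.
#' @return Glucose map (mM) with range exactly `[lo, hi]` over valid voxels.
#' @export
#' @examples
#' suvr_to_glucose(matrix(c(1, 2, 3, 4), 2))
suvr_to_glucose <- function(suvr, lo = 1.0, hi = 2.7, mask = NULL) {
  stop_if(hi <= lo, "'hi' must exceed 'lo'")
  vals <- if (is.null(mask)) suvr else suvr[mask]
  rng <- range(vals)
  stop_if(diff(rng) == 0,
          "SUVr map is constant over its valid voxels: min-max scaling is degenerate")
  refl <- -suvr
  out <- lo + (refl - (-rng[2])) / (rng[2] - rng[1]) * (hi - lo)
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Convert an oxygen extraction fraction map to dissolved oxygen
#'
#' `dO2 = oef * O2cap`, where `O2cap` is the typical oxygen content of fully
#' oxygenated capillaries; the extracted oxygen is assumed retained by the
#' tissue.
#'
#' @param oef Oxygen extraction fraction map; values in `[0, 1]`.
#' @param o2cap Capillary oxygen content (mg/L); default 0.4655.
#' @return Dissolved oxygen map (mg/L).
#' @export
#' @examples
#' oef_to_do2(0.4)
oef_to_do2 <- function(oef, o2cap = 0.4655) {
  stop_if(any(oef < 0 | oef > 1, na.rm = TRUE),
          "'oef' values must lie in [0, 1]")
  oef * o2cap
}

#' Excess resource supply from regional vascular density
#'
#' Regions more vascularized than the infiltrating-zone average supply extra
#' resource proportionally to the fold difference:
#' `g0 * (va_roi / va_iz_mean - 1)`, clamped at zero from below (regions less
#' vascular than normal brain supply no extra resource).
#'
#' @param va_roi Vascular area fraction of the region(s) of interest.
#' @param va_iz_mean Mean vascular area fraction over infiltrating-zone
#'   regions (> 0), the normal-brain reference.
#' @param g0 Baseline resource generation rate of physiologic vascular supply
#'   (e.g. mM/day for glucose).
#' @return Excess generation rate, same units as `g0`.
#' @export
excess_glucose <- function(va_roi, va_iz_mean, g0) {
  stop_if(va_iz_mean <= 0, "'va_iz_mean' must be positive")
  check_nonneg(va_roi, "va_roi")
  check_nonneg(g0, "g0")
  pmax(g0 * (va_roi / va_iz_mean - 1), 0)
}

# Smooth standardized Gaussian random field: white noise low-pass filtered
# with a circular Gaussian kernel (correlation length in voxels), then
# standardized to zero mean / unit sd.
smooth_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  kern <- function(len) {
    r <- min(ceiling(3 * corr_len), max(0, (len - 1) %/% 2))
    k <- stats::dnorm(-r:r, sd = corr_len)
    k / sum(k)
  }
  if (corr_len > 0) {
    if (nr > 2) {
      kc <- kern(nr)
      z <- apply(z, 2, function(v) as.numeric(stats::filter(v, kc, circular = TRUE)))
    }
    if (nc > 2) {
      kr <- kern(nc)
      z <- t(apply(z, 1, function(v) as.numeric(stats::filter(v, kr, circular = TRUE))))
    }
  }
  if (stats::sd(z) == 0) return(matrix(0, nr, nc))
  (z - mean(z)) / stats::sd(z)
}

#' Generate synthetic resource atlases
#'
#' Smooth correlated random fields (low-pass-filtered white noise) standing in
#' for imaging-derived atlases, mapped into physiological ranges: glucose
#' clipped to `[1.0, 2.7]` mM, oxygen to `[0, 0.4655]` mg/L, stiffness to
#' `[0, stiff0]` Pa. The `low_glucose` and `high_glucose` presets emulate
#' glucose-poor and glucose-rich brain regions with spatial mean glucose 1.22
#' and 2.36 mM. Perfusion delivers glucose and oxygen together, so the
#' glucose-poor preset is modeled as a poorly perfused (hypoxic) region with
#' mean dissolved oxygen 0.04 mg/L — below the metabolic switch threshold, so
#' starvation there is glucose-limited — while the glucose-rich preset is
#' well perfused (mean 0.186 mg/L, a typical oxygen extraction fraction of
#' 0.4 times the capillary content). `uniform` gives constant maps.
#' Deterministic per seed.
#'
#' @param shape Grid dimensions `c(rows, cols)`.
#' @param seed Integer seed (required; the global RNG state is preserved).
#' @param preset One of `"low_glucose"`, `"high_glucose"`, `"uniform"`,
#'   `"custom"`.
#' @param config Named list overriding generator settings: `corr_len`
#'   (voxels), `glucose_mean`, `glucose_sd`, `oxygen_mean`, `oxygen_sd`,
#'   `stiffness_mean`, `stiffness_sd`, `stiff0`, and for the uniform preset
#'   `glucose`, `oxygen`, `stiffness`.
#' @return An [atlas_set()].
#' @export
#' @examples
#' a <- synthetic_atlases(c(32, 32), seed = 1, preset = "low_glucose")
#' mean(a$glucose)
synthetic_atlases <- function(shape = c(64, 64), seed,
                              preset = c("low_glucose", "high_glucose",
                                         "uniform", "custom"),
                              config = list()) {
  preset <- match.arg(preset)
  stop_if(missing(seed), "'seed' is required for reproducible atlases")
  defaults <- list(corr_len = 4,
                   glucose_mean = 1.85, glucose_sd = 0.15,
                   oxygen_mean = 0.186, oxygen_sd = 0.03,
                   stiffness_mean = 2000, stiffness_sd = 300,
                   stiff0 = 2930,
                   glucose = 1.85, oxygen = 0.186, stiffness = 2000)
  if (preset == "low_glucose") {
    defaults$glucose_mean <- 1.22
    defaults$glucose_sd <- 0.05
    defaults$oxygen_mean <- 0.04
    defaults$oxygen_sd <- 0.005
  } else if (preset == "high_glucose") {
    defaults$glucose_mean <- 2.36
    defaults$glucose_sd <- 0.08
  }
  extra <- setdiff(names(config), names(defaults))
  stop_if(length(extra) > 0,
          "unknown generator config keys: ", paste(extra, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  nr <- shape[1]; nc <- shape[2]
  if (preset == "uniform") {
    return(atlas_set(matrix(cfg$glucose, nr, nc),
                     matrix(cfg$oxygen, nr, nc),
                     matrix(cfg$stiffness, nr, nc)))
  }
  withr::with_seed(seed, {
    z1 <- smooth_field(nr, nc, cfg$corr_len)
    z2 <- smooth_field(nr, nc, cfg$corr_len)
    z3 <- smooth_field(nr, nc, cfg$corr_len)
  })
  glucose <- pmin(pmax(cfg$glucose_mean + cfg$glucose_sd * z1, 1.0), 2.7)
  oxygen <- pmin(pmax(cfg$oxygen_mean + cfg$oxygen_sd * z2, 0), 0.4655)
  stiffness <- pmin(pmax(cfg$stiffness_mean + cfg$stiffness_sd * z3, 0), cfg$stiff0)
  atlas_set(glucose, oxygen, stiffness)
}
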