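sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

md5_of_file <- function(path) unname(tools::md5sum(path))

#' Write a 2D map to NIfTI
#'
#' Stores the matrix as a double-precision NIfTI image with the voxel size in
#' the header, plus an optional JSON sidecar declaring the units.
#'
#' @param map Numeric matrix.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel edge length (mm).
#' @param units Optional unit string recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_mm = 2, units = NULL) {
  stop_if(!is.matrix(map), "'map' must be a matrix")
  attr(map, "pixdim") <- c(voxel_mm, voxel_mm)
  RNifti::writeNifti(RNifti::asNifti(map, datatype = "double"), path)
  if (!is.null(units)) {
    jsonlite::write_json(list(units = units), sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a 2D map (or an axial slice of a 3D volume) from NIfTI
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param expected_units Optional unit string; checked against the JSON
#'   sidecar when one is present, mismatches raise an error.
#' @param slice For 3D volumes, the axial slice index to extract; reading a
#'   3D volume without a slice (or anything that is not 2D/3D) is an error.
#' @return List with `map` (matrix), `voxel_mm` and `units` (`NA` when no
#'   sidecar exists).
#' @export
read_map <- function(path, expected_units = NULL, slice = NULL) {
  stop_if(!file.exists(path), sprintf("file '%s' not found", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3) {
    stop_if(is.null(slice), "3D volume: supply an axial 'slice' index")
    stop_if(slice < 1 || slice > dim(arr)[3], "slice index out of range")
    arr <- arr[, , slice]
  } else {
    stop_if(nd != 2, sprintf("expected a 2D map or 3D volume, got %d dimensions", nd))
  }
  arr <- structure(as.numeric(arr), dim = dim(arr))  # plain double matrix
  units <- NA_character_
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    units <- jsonlite::read_json(sc)$units %||% NA_character_
    if (!is.null(expected_units)) {
      stop_if(!identical(units, expected_units),
              sprintf("unit mismatch for '%s': sidecar says '%s', expected '%s'",
                      path, units, expected_units))
    }
  }
  pd <- RNifti::pixdim(img)
  list(map = arr, voxel_mm = pd[1], units = units)
}

# Full-precision CSV writer: %.17g repr round-trips doubles, so identical
# trajectories produce byte-identical files.
write_timeseries_csv <- function(df, path) {
  fmt_col <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(paste(names(df), collapse = ","),
             apply(cells, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_model_config(tmp, cfg$params, cfg$clones)
  cat(sprintf("duration: %d\nseed: %d\nsteps_per_day: %d\n",
              cfg$duration, cfg$seed, cfg$steps_per_day),
      file = tmp, append = TRUE)
  md5_of_file(tmp)
}

#' Write run outputs with a checksummed manifest
#'
#' Writes the trajectory's summary time series as a full-precision CSV, any
#' recorded density maps as NIfTI snapshots, and a JSON manifest carrying the
#' config hash, seed, day range and an MD5 inventory of every written file.
#'
#' @param trajectory A [run_simulation()] result.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(trajectory, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  ts_path <- file.path(out_dir, "timeseries.csv")
  write_timeseries_csv(trajectory$summary, ts_path)
  files <- c(files, "timeseries.csv")

  if (!is.null(trajectory$maps)) {
    for (d in names(trajectory$maps)) {
      nm <- sprintf("density_day%s.nii.gz", d)
      write_map(trajectory$maps[[d]], file.path(out_dir, nm),
                voxel_mm = trajectory$config$atlases$voxel_mm %||% 2,
                units = "cells/voxel")
      files <- c(files, nm, sub("\\.nii\\.gz$", ".json", nm))
    }
  }

  manifest <- list(
    config_hash = config_hash(trajectory$config),
    seed = trajectory$config$seed,
    start_day = trajectory$summary$day[1],
    end_day = trajectory$summary$day[nrow(trajectory$summary)],
    files = lapply(files, function(f) {
      list(name = f, md5 = md5_of_file(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' Recomputes the MD5 checksum of every file listed in `manifest.json`.
#'
#' @param out_dir Directory written by [write_outputs()].
#' @return `TRUE` if all checksums match; otherwise an error naming the first
#'   mismatching file.
#' @export
verify_manifest <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  stop_if(!file.exists(mpath), "no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(mpath)
  for (f in manifest$files) {
    actual <- md5_of_file(file.path(out_dir, f$name))
    stop_if(!identical(actual, f$md5),
            sprintf("checksum mismatch for '%s'", f$name))
  }
  TRUE
}
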