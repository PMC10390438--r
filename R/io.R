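# File formats: NIfTI-1 volumes via RNifti, tables as CSV, reports as JSON,
# plus a small config/manifest utility.

#' Write a volume or image as NIfTI-1
#'
#' Accepts an `activity_volume` (writes the activity map), a
#' `spect_volume`, a `planar_image` (stored as a 2-D NIfTI) or a bare
#' array. Voxel sizes are preserved in the NIfTI header; data are stored as
#' floating point.
#'
#' @param vol The object to write.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel sizes, required only for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = NULL) {
  if (inherits(vol, "activity_volume")) {
    data <- vol$activity; voxel_mm <- vol$grid$voxel_mm
  } else if (inherits(vol, "spect_volume")) {
    data <- vol$counts; voxel_mm <- vol$grid$voxel_mm
  } else if (inherits(vol, "planar_image")) {
    data <- vol$counts
    voxel_mm <- vol$pixel_mm
  } else if (is.array(vol)) {
    data <- vol
    if (is.null(voxel_mm)) stop("`voxel_mm` is required for bare arrays")
  } else stop("unsupported volume type")
  img <- RNifti::asNifti(data + 0)              # force double storage
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a NIfTI file.
#' @return List with `data` (array) and `voxel_mm`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)), error = function(e)
    stop(sprintf("malformed NIfTI file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  d <- dim(img)
  list(data = array(as.numeric(img), d),
       voxel_mm = RNifti::pixdim(img)[seq_along(d)])
}

#' Write a table as both CSV and JSON
#'
#' The two renderings hold the same values; JSON keeps full double
#' precision.
#'
#' @param df A data.frame.
#' @param stem Path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return The two paths, invisibly.
#' @export
write_table_pair <- function(df, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, js, dataframe = "columns", digits = NA)
  invisible(c(csv, js))
}

# Polynomial rolling hash of an R object's serialization (mod 2^31 - 1);
# used to fingerprint configurations in run manifests.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

# Write a run manifest (config hash, seed, package version) next to outputs.
write_manifest <- function(config, seed, out_dir, stage) {
  man <- list(stage = stage, seed = seed,
              config_hash = config_hash(config),
              package = "thyroquant",
              version = as.character(utils::packageVersion("thyroquant")))
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE)
  invisible(man)
}
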