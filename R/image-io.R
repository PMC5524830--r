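#' Write and read dynamic image series
#'
#' One animal's series is stored as a 4-D NIfTI volume (`<id>.nii`, float64,
#' so values round-trip bit-exactly), a brain-mask NIfTI (`<id>_mask.nii`),
#' an acquisition-times CSV (`<id>_times.csv` with columns `animal_id`,
#' `t_index`, `time_s`) and a JSON sidecar (`<id>_meta.json`) holding the
#' grid metadata (voxel size, origin) and rendering constants.
#'
#' @param series An `image_series`.
#' @param dir Output directory (created if needed).
#' @param id Animal identifier used as the file stem.
#' @return `write_image_series()` returns the file paths invisibly;
#'   `read_image_series()` returns an `image_series`.
#' @export
write_image_series <- function(series, dir, id) {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    nii = file.path(dir, paste0(id, ".nii")),
    mask = file.path(dir, paste0(id, "_mask.nii")),
    times = file.path(dir, paste0(id, "_times.csv")),
    meta = file.path(dir, paste0(id, "_meta.json"))
  )
  vols <- series$volumes
  attr(vols, "pixdim") <- c(rep(series$voxel_size, 3), 1)
  RNifti::writeNifti(RNifti::asNifti(vols, datatype = "double"), paths$nii)
  mask <- array(as.integer(series$brain_mask), dim = dim(series$brain_mask))
  attr(mask, "pixdim") <- rep(series$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(mask, datatype = "uint8"), paths$mask)
  readr::write_csv(
    tibble(animal_id = id, t_index = seq_along(series$times) - 1L,
           time_s = series$times),
    paths$times)
  jsonlite::write_json(
    list(voxel_size = series$voxel_size, origin = series$origin,
         noise_sd = series$noise_sd, beta = series$beta,
         baseline = series$baseline, center = series$center),
    paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(dir, id) {
  nii <- file.path(dir, paste0(id, ".nii"))
  times_csv <- file.path(dir, paste0(id, "_times.csv"))
  meta_json <- file.path(dir, paste0(id, "_meta.json"))
  mask_nii <- file.path(dir, paste0(id, "_mask.nii"))
  for (f in c(nii, times_csv, meta_json, mask_nii)) {
    if (!file.exists(f)) stop_validation("missing input file: %s", f)
  }
  tt <- readr::read_csv(times_csv, show_col_types = FALSE)
  if (!"time_s" %in% names(tt)) {
    stop_validation("file %s is missing required column `time_s`", times_csv)
  }
  meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  vols <- array(as.numeric(RNifti::readNifti(nii)), dim = dim(RNifti::readNifti(nii)))
  mask <- array(as.numeric(RNifti::readNifti(mask_nii)) > 0,
                dim = dim(RNifti::readNifti(mask_nii)))
  structure(
    list(volumes = vols, times = as.numeric(tt$time_s),
         voxel_size = as.numeric(meta$voxel_size),
         origin = as.numeric(meta$origin),
         brain_mask = mask, noise_sd = as.numeric(meta$noise_sd),
         beta = as.numeric(meta$beta), baseline = as.numeric(meta$baseline),
         center = as.numeric(meta$center)),
    class = "image_series"
  )
}

#' Write and read a cohort table
#'
#' CSV with one row per animal (`animal_id`, `group`, `mode`, `sub_seed`,
#' and the drawn parameter columns).
#'
#' @param cohort Cohort tibble from [draw_cohort()].
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_validation("missing cohort file: %s", path)
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("animal_id", "group", "mode")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop_validation("file %s is missing required column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  x
}
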