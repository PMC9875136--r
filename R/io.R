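# NIfTI / CSV / JSON input-output. Images travel as NIfTI with an explicit
# slice axis of length 1; acquisition metadata travels in JSON sidecars.

SIDECAR_VERSION <- 1L

#' Write a Z-spectral dataset to disk
#'
#' One 3D NIfTI per saturation power (`x * y * n_offsets`, float32) plus a
#' JSON sidecar listing the offsets (ppm, in data order) and powers (uT).
#'
#' @param dataset A [zspectral_dataset()] (or the `raw` stack of
#'   [generate_phantom()] passed with `offsets`/`b1_list`).
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the sidecar path.
#' @export
write_zspectra <- function(dataset, dir) {
  stop_if(!inherits(dataset, "zspectral_dataset"), "dataset must be a zspectral_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(dataset$b1_list)) {
    RNifti::writeNifti(dataset$signal[, , , j],
                       file.path(dir, sprintf("zspec_b1_%g.nii.gz", dataset$b1_list[j])),
                       datatype = "float")
  }
  sidecar <- file.path(dir, "zspec.json")
  jsonlite::write_json(list(version = SIDECAR_VERSION,
                            offsets = dataset$offsets,
                            b1_list = dataset$b1_list,
                            reference_offset = dataset$reference_offset,
                            larmor = dataset$larmor),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a Z-spectral dataset written by [write_zspectra()]
#'
#' Validates the sidecar against the image dimensions: the offset list must
#' match the stored data order (sorted ascending) and its length the third
#' image dimension.
#'
#' @param dir Directory containing `zspec.json` and the per-power NIfTIs.
#' @return A [zspectral_dataset()].
#' @export
read_zspectra <- function(dir) {
  sidecar <- file.path(dir, "zspec.json")
  stop_if(!file.exists(sidecar), sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  stop_if(is.unsorted(meta$offsets),
          "sidecar offset list does not match data order (must be sorted ascending)")
  stacks <- lapply(meta$b1_list, function(b1) {
    path <- file.path(dir, sprintf("zspec_b1_%g.nii.gz", b1))
    stop_if(!file.exists(path), sprintf("missing image: %s", path))
    img <- strip_nifti(RNifti::readNifti(path))
    stop_if(dim(img)[3] != length(meta$offsets),
            sprintf("%s: offset count %d does not match sidecar (%d)",
                    path, dim(img)[3], length(meta$offsets)))
    img
  })
  signal <- array(unlist(stacks), c(dim(stacks[[1]]), length(stacks)))
  zspectral_dataset(signal, meta$offsets, meta$b1_list,
                    meta$reference_offset, larmor = meta$larmor)
}

#' Write a quantitative map as NIfTI
#'
#' Float32, with an explicit slice axis of length 1 for a 2D map.
#'
#' @param map Matrix or map object (`kex_map`, `susceptibility_map`,
#'   `field_map`).
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  m <- map_values(map)
  if (is.matrix(m)) m <- array(m, c(dim(m), 1L))
  RNifti::writeNifti(m, path, datatype = "float")
  invisible(path)
}

#' Read a quantitative map written by [write_map()]
#'
#' @param path `.nii.gz` path.
#' @return Matrix (slice axes of length 1 dropped).
#' @export
read_map <- function(path) {
  stop_if(!file.exists(path), sprintf("missing image: %s", path))
  img <- strip_nifti(RNifti::readNifti(path))
  d <- dim(img)
  if (length(d) == 3L && d[3] == 1L) img <- img[, , 1]
  img
}

# plain numeric array without the NIfTI header attributes
strip_nifti <- function(img) {
  array(as.vector(img), dim(img))
}

#' Write multi-echo phase images
#'
#' 4D NIfTI (`x * y * 1 * n_echo`, radians) plus a JSON sidecar with the
#' echo times.
#'
#' @param phase Array `x * y * n_echo`.
#' @param te_list Echo times, s.
#' @param path Output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @return Invisibly, `path`.
#' @export
write_phase <- function(phase, te_list, path) {
  stop_if(dim(phase)[3] != length(te_list),
          "echo count does not match te_list length")
  d <- dim(phase)
  RNifti::writeNifti(array(phase, c(d[1], d[2], 1L, d[3])), path,
                     datatype = "float")
  jsonlite::write_json(list(version = SIDECAR_VERSION, te_list = te_list),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read multi-echo phase images written by [write_phase()]
#'
#' @param path `.nii.gz` path.
#' @return List: `phase` (`x * y * n_echo`), `te_list`.
#' @export
read_phase <- function(path) {
  img <- strip_nifti(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  stop_if(dim(img)[4] != length(meta$te_list),
          sprintf("echo count %d does not match sidecar te_list (%d)",
                  dim(img)[4], length(meta$te_list)))
  list(phase = array(img, dim(img)[c(1, 2, 4)]), te_list = meta$te_list)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Tabular CSV helpers
#'
#' Comma-separated, UTF-8, header row, `.` decimal.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_table()`: invisibly, `path`; `read_table_csv()`: a tibble.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  stop_if(!file.exists(path), sprintf("missing table: %s", path))
  readr::read_csv(path, show_col_types = FALSE)
}
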