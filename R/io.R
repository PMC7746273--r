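# Standard-format I/O: NIfTI volumes (via RNifti), tab-separated events and
# motion tables, CSV layer matrices and surfaces, minimal ASCII GIFTI
# surfaces, and JSON results.

#' Write a BOLD run as NIfTI-1
#'
#' Stores the 4D array with the voxel size and TR in the header and the
#' grid's voxel-to-world affine.
#' @param run a `bold_run`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`pixdim<-`(img, c(rep(run$grid$voxel_mm, 3), run$TR_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI as a `bold_run`
#' @param path NIfTI file.
#' @return a `bold_run` (without design/motion, which travel separately).
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  grid <- sampling_grid(dim(img)[1:3], voxel_mm = pd[1])
  structure(list(data = unclass(img)[, , , , drop = FALSE], TR_s = pd[4],
                 grid = grid, affine = grid_affine(grid),
                 motion = NULL, design = NULL, n_baseline_vols = 1L),
            class = "bold_run")
}

#' Write a design table as a BIDS-like events TSV
#' @param design a [simulate_design()] table.
#' @param path output path.
#' @export
write_events_tsv <- function(design, path) {
  ev <- data.frame(onset = design$onset_s,
                   duration = attr(design, "trial_dur_s") %||% 2.5,
                   trial_type = design$trial_type,
                   task = design$task,
                   cue = design$cue_colour,
                   orientation = design$cued_orientation_deg,
                   run = design$run)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV
#' @param path events file.
#' @return data.frame.
#' @export
read_events_tsv <- function(path) read.delim(path)

#' Write motion parameters as a 6-column TSV
#' @param motion T x 6 matrix.
#' @param path output path.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a layer volume matrix as CSV
#'
#' One row per voxel: i, j, k indices plus the five compartment fractions.
#' @param layers a [layer_volume_distribution()].
#' @param path output path.
#' @export
write_layer_matrix_csv <- function(layers, path) {
  df <- cbind(as.data.frame(layers$ijk), as.data.frame(layers$fractions))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a surface mesh as vertex/face CSV tables
#'
#' Writes `<stem>_vertices.csv` (x, y, z in mm) and `<stem>_faces.csv`
#' (1-based indices v1, v2, v3).
#' @param mesh a [surface_mesh()].
#' @param stem path stem.
#' @export
write_surface_csv <- function(mesh, stem) {
  v <- as.data.frame(mesh$vertices); names(v) <- c("x", "y", "z")
  f <- as.data.frame(mesh$faces); names(f) <- c("v1", "v2", "v3")
  write.csv(v, paste0(stem, "_vertices.csv"), row.names = FALSE)
  write.csv(f, paste0(stem, "_faces.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a surface mesh from vertex/face CSV tables
#' @param stem path stem used by [write_surface_csv()].
#' @return a [surface_mesh()].
#' @export
read_surface_csv <- function(stem) {
  v <- utils::read.csv(paste0(stem, "_vertices.csv"))
  f <- utils::read.csv(paste0(stem, "_faces.csv"))
  surface_mesh(as.matrix(v), as.matrix(f))
}

#' Write a surface mesh as ASCII-encoded GIFTI
#'
#' Minimal GIFTI 1.0 writer (ASCII data encoding) with pointset and triangle
#' arrays; readable by standard neuroimaging tools.
#' @param mesh a [surface_mesh()].
#' @param path output path (`.surf.gii`).
#' @export
write_surface_gifti <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L          # GIFTI triangles are 0-based
  da <- function(intent, dtype, dat, dims) {
    paste0(
      '<DataArray Intent="', intent, '" DataType="', dtype,
      '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="',
      dims[1], '" Dim1="3" Encoding="ASCII" Endian="LittleEndian" ',
      'ExternalFileName="" ExternalFileOffset="">\n<Data>\n',
      paste(apply(dat, 1, paste, collapse = " "), collapse = "\n"),
      "\n</Data>\n</DataArray>")
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", v, nrow(v)), "\n",
    da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", f, nrow(f)), "\n",
    "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Write laminar effects as tidy CSV
#' @param effects a [orientation_specific_response()] array (or the
#'   `effects` element of a [run_pipeline()] result).
#' @param path output path.
#' @export
write_effects_csv <- function(effects, path) {
  g <- expand.grid(layer = dimnames(effects)[[1]],
                   stimulus = dimnames(effects)[[2]],
                   task = dimnames(effects)[[3]], stringsAsFactors = FALSE)
  g$amplitude <- effects[cbind(g$layer, g$stimulus, g$task)]
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}

# Resolved-config + results bundle written next to the outputs, with a small
# manifest so every stage is re-runnable from disk.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg_json <- cfg
  cfg_json$truth <- list(amplitude = cfg$truth$amplitude,
                         superficial_bias_gain = cfg$truth$superficial_bias_gain,
                         noise_sd = cfg$truth$noise_sd,
                         tsnr_target = cfg$truth$tsnr_target)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_effects_csv(res$effects, file.path(out_dir, "laminar_effects.csv"))
  write_events_tsv(res$design, file.path(out_dir, "events.tsv"))
  write_layer_matrix_csv(res$layers, file.path(out_dir, "layer_volumes.csv"))
  jsonlite::write_json(
    list(roi45 = res$rois$roi45, roi135 = res$rois$roi135),
    file.path(out_dir, "rois.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = cfg$seed,
         files = c("config.json", "laminar_effects.csv", "events.tsv",
                   "layer_volumes.csv", "rois.json"),
         tsnr = as.list(res$tsnr)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
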