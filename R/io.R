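## Dataset read/write: NIfTI (float32, lossless for our purposes) or PNG
## (8-bit grayscale, 1/255 precision), plus a plain-text CSV manifest.

write_image_file <- function(img, path, format) {
  if (format == "png") {
    png::writePNG(img, target = path)
  } else {
    RNifti::writeNifti(array(img, c(dim(img), 1L)), path, datatype = "float")
  }
  invisible(path)
}

read_image_file <- function(path) {
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  } else {
    arr <- RNifti::readNifti(path)
    matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2])
  }
}

#' Write a domain dataset to disk
#'
#' One image file and one mask file per slice plus a CSV manifest with
#' header `subject_id,slice_idx,image_path,mask_path,domain,
#' infiltration_fraction`. NIfTI stores float32 (round-trips exactly for
#' the generator's values); PNG is 8-bit grayscale, precise to 1/255.
#' Masks round-trip exactly in either format.
#'
#' @param dataset a [DomainDataset-class].
#' @param directory output directory (created if missing).
#' @param format `"nifti"` or `"png"`.
#' @return (invisibly) the manifest data.frame; also written as
#'   `manifest.csv` in `directory`.
#' @export
writeDataset <- function(dataset, directory, format = c("nifti", "png")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "DomainDataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  ext <- if (format == "png") "png" else "nii.gz"
  rows <- lapply(dataset@slices, function(sl) {
    stem <- sprintf("%s_slice%02d", sl@subjectId, sl@sliceIndex)
    ip <- file.path(directory, paste0(stem, "_img.", ext))
    mp <- file.path(directory, paste0(stem, "_mask.", ext))
    write_image_file(sl@image, ip, format)
    if (length(sl@muscleMask))
      write_image_file(matrix(as.numeric(sl@muscleMask), nrow(sl@muscleMask)),
                       mp, format)
    else mp <- NA_character_
    frac <- if (is(sl, "PhantomSlice")) sl@realizedInfiltrationFraction
            else NA_real_
    data.frame(subject_id = sl@subjectId, slice_idx = sl@sliceIndex,
               image_path = ip, mask_path = mp,
               domain = dataset@domainLabel,
               infiltration_fraction = frac,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' Images whose values fall outside \[0, 1\] (e.g. raw-unit NIfTI from a
#' scanner export) are brought onto the internal scale by per-slice
#' min-max normalization — the adopted intensity convention for external
#' data.
#'
#' @param directory directory containing `manifest.csv`.
#' @return a [DomainDataset-class]; slices are [ImageSlice-class] objects
#'   (masks attached where the manifest lists them).
#' @export
readDataset <- function(directory) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", directory)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  slices <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image_file(manifest$image_path[i])
    if (min(img) < 0 || max(img) > 1) {       # raw units: per-slice min-max
      rng <- range(img)
      img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
             else img * 0
    }
    mask <- if (!is.na(manifest$mask_path[i])) {
      m <- read_image_file(manifest$mask_path[i])
      matrix(as.integer(m > 0.5), nrow(m))
    } else matrix(integer(0), 0, 0)
    new("ImageSlice", image = pmin(pmax(img, 0), 1), muscleMask = mask,
        subjectId = manifest$subject_id[i],
        sliceIndex = as.integer(manifest$slice_idx[i]))
  })
  new("DomainDataset", slices = slices,
      domainLabel = manifest$domain[1])
}
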