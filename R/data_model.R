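# Core domain containers and file IO.
#
# Coordinate contract: all public positions are (x, y) in pixel units,
# 0-based, anchored at pixel centers, x rightward and y downward. A frame is
# stored as an H x W matrix, so intensity at (x, y) is frames[y + 1, x + 1].
# Conversions to millimetres use pixel_spacing = (dy, dx) and happen only in
# the metric / clinical layers.

#' Cine image sequence
#'
#' Container for a time-resolved long-axis cine: a stack of T frames of
#' H x W scalar intensities with the in-plane pixel spacing and the imaging
#' view (2-chamber or 4-chamber).
#'
#' @param frames numeric H x W x T array, or a list of T H x W matrices, of
#'   finite non-negative intensities.
#' @param pixel_spacing numeric length-2 vector \code{c(dy, dx)} in
#'   mm/pixel, both positive.
#' @param view `"2ch"` or `"4ch"`.
#' @return An object of class `cine_sequence` with elements `frames`
#'   (H x W x T array), `pixel_spacing`, `view`, and `frame_count`.
#' @export
cine_sequence <- function(frames, pixel_spacing, view = c("2ch", "4ch")) {
  view <- match.arg(view)
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  .assert(length(dim(frames)) == 3L, "frames must be an H x W x T array")
  d <- dim(frames)
  .assert(d[1] >= 8L && d[2] >= 8L, "frames must be at least 8 x 8 pixels")
  .assert(d[3] >= 1L, "need at least one frame")
  .assert(all(is.finite(frames)), "frame intensities must be finite")
  pixel_spacing <- as.numeric(pixel_spacing)
  .assert(length(pixel_spacing) == 2L && all(pixel_spacing > 0),
          "pixel_spacing must be two positive values (dy, dx)")
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 view = view, frame_count = d[3]),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cine_sequence: %d frames of %d x %d (%s view), spacing %.3g x %.3g mm\n",
              d[3], d[1], d[2], x$view, x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Mitral valve annotation
#'
#' Two tracked mitral-valve insertion points per frame. `start` is the
#' anterior (2ch) or lateral (4ch) point, `end` the inferior (2ch) or
#' septal (4ch) point.
#'
#' @param start,end numeric T x 2 matrices of (x, y) pixel positions.
#' @return An object of class `mv_annotation` with `start`, `end`, and
#'   `frame_count`.
#' @export
mv_annotation <- function(start, end) {
  start <- rbind(start); end <- rbind(end)
  .assert(ncol(start) == 2L && ncol(end) == 2L, "points must be (x, y) pairs")
  .assert(nrow(start) == nrow(end), "start and end need one pair per frame")
  .assert(all(is.finite(start)) && all(is.finite(end)), "points must be finite")
  d <- sqrt(rowSums((start - end)^2))
  if (any(d == 0)) stop("degenerate valve: coincident MV points in frame ",
                        paste(which(d == 0) - 1L, collapse = ", "))
  structure(list(start = unname(start), end = unname(end),
                 frame_count = nrow(start)),
            class = "mv_annotation")
}

#' Read a cine stack from NIfTI or multi-page TIFF
#'
#' @param path path to a `.nii`/`.nii.gz` file (3-D volume interpreted as a
#'   cine) or a multi-page TIFF.
#' @param spacing_override optional `c(dy, dx)` in mm, used when the file
#'   header carries no usable spacing (always the case for TIFF).
#' @param view passed to [cine_sequence()].
#' @param axis_order for NIfTI: `"hwt"` if the volume is H x W x T (default,
#'   as written by [write_cine()]), `"thw"` if frames are on the first axis.
#' @return A [cine_sequence()].
#' @export
read_cine <- function(path, spacing_override = NULL, view = c("2ch", "4ch"),
                      axis_order = c("hwt", "thw")) {
  view <- match.arg(view)
  axis_order <- match.arg(axis_order)
  .assert(file.exists(path), paste("file not found:", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))  # plain array, no header attrs
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    .assert(length(dim(arr)) == 3L, "NIfTI cine must be 3-D")
    if (axis_order == "thw") arr <- aperm(arr, c(2, 3, 1))
    pd <- RNifti::pixdim(img)
    spacing <- if (axis_order == "thw") pd[c(2, 3)] else pd[c(1, 2)]
    if (!all(is.finite(spacing)) || any(spacing <= 0)) spacing <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    arr <- simplify2array(pages)
    spacing <- NULL
  } else {
    stop("unsupported cine format: ", ext)
  }
  spacing <- spacing %||% spacing_override
  if (is.null(spacing)) stop("missing pixel spacing: file header has none and ",
                             "no spacing_override was given")
  cine_sequence(arr, spacing, view)
}

#' Write a cine stack to NIfTI or TIFF
#'
#' @param cine a [cine_sequence()].
#' @param path destination; format chosen by extension (`.nii`/`.nii.gz` or
#'   `.tif`/`.tiff`). TIFF pages are written as 32-bit floats and carry no
#'   spacing, so reading them back needs a `spacing_override`.
#' @return `path`, invisibly.
#' @export
write_cine <- function(cine, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(cine$frames)
    RNifti::pixdim(img) <- c(cine$pixel_spacing, 1)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(cine$frame_count),
                    function(t) cine$frames[, , t])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else stop("unsupported cine format: ", ext)
  invisible(path)
}

#' Read mitral-valve points from JSON or CSV
#'
#' JSON input is an array of objects
#' \code{\{"frame": int, "start": [x, y], "end": [x, y]\}}; CSV input has
#' columns `frame, x_start, y_start, x_end, y_end`. Frames are 0-based and
#' must cover `0 .. frame_count - 1`; with `fill_missing = TRUE` a missing
#' frame is copied from its nearest annotated neighbour.
#'
#' @param path input file.
#' @param frame_count expected number of frames T.
#' @param fill_missing allow nearest-frame fill-in of missing entries.
#' @param image_shape optional `c(H, W)`; when given, points are checked to
#'   lie inside the image bounds.
#' @return An [mv_annotation()].
#' @export
read_mv_points <- function(path, frame_count, fill_missing = FALSE,
                           image_shape = NULL) {
  .assert(file.exists(path), paste("file not found:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    frames <- as.integer(rec$frame)
    st <- do.call(rbind, rec$start); en <- do.call(rbind, rec$end)
  } else if (ext == "csv") {
    rec <- utils::read.csv(path)
    frames <- as.integer(rec$frame)
    st <- cbind(rec$x_start, rec$y_start); en <- cbind(rec$x_end, rec$y_end)
  } else stop("unsupported MV point format: ", ext)
  if (anyDuplicated(frames)) stop("duplicate frame entries in MV points")
  if (any(frames < 0 | frames >= frame_count))
    stop("out-of-bounds frame index in MV points")
  start <- matrix(NA_real_, frame_count, 2)
  end <- matrix(NA_real_, frame_count, 2)
  start[frames + 1L, ] <- st; end[frames + 1L, ] <- en
  missing <- which(is.na(start[, 1]))
  if (length(missing)) {
    if (!fill_missing)
      stop("frames missing MV annotations: ",
           paste(missing - 1L, collapse = ", "))
    present <- setdiff(seq_len(frame_count), missing)
    for (i in missing) {
      j <- present[which.min(abs(present - i))]
      start[i, ] <- start[j, ]; end[i, ] <- end[j, ]
    }
  }
  if (!is.null(image_shape)) {
    ok <- function(p) all(p[, 1] >= 0 & p[, 1] <= image_shape[2] - 1 &
                          p[, 2] >= 0 & p[, 2] <= image_shape[1] - 1)
    .assert(ok(start) && ok(end), "MV points outside image bounds")
  }
  mv_annotation(start, end)
}

#' Write mitral-valve points as JSON
#'
#' @param annotation an [mv_annotation()].
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_mv_points <- function(annotation, path) {
  rec <- lapply(seq_len(annotation$frame_count), function(t) {
    list(frame = t - 1L, start = annotation$start[t, ],
         end = annotation$end[t, ])
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Segmentation result
#'
#' Bundles the per-frame binary masks, the closed D-shaped polygons in image
#' pixel coordinates, and the mitral-valve chord that closes each polygon.
#' Each mask is, by construction, the rasterization of its polygon.
#'
#' @param masks H x W x T array (or list) of 0/1 masks.
#' @param contours list of T closed polygons (n x 2 matrices of (x, y)
#'   vertices, wall vertices first, then the MV end and start points).
#' @param mv_chord list of T 2 x 2 matrices, rows = (p_start, p_end).
#' @param diagnostics optional list of per-run diagnostics.
#' @return An object of class `la_segmentation`.
#' @export
la_segmentation <- function(masks, contours, mv_chord, diagnostics = list()) {
  if (is.list(masks)) masks <- simplify2array(masks)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  storage.mode(masks) <- "integer"
  .assert(all(masks %in% c(0L, 1L)), "masks must be binary")
  t_n <- dim(masks)[3]
  .assert(length(contours) == t_n && length(mv_chord) == t_n,
          "masks, contours and mv_chord must agree on frame count")
  structure(list(masks = masks, contours = contours, mv_chord = mv_chord,
                 frame_count = t_n, diagnostics = diagnostics),
            class = "la_segmentation")
}

#' @export
print.la_segmentation <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("la_segmentation: %d frames of %d x %d, mask area %.0f-%.0f px\n",
              d[3], d[1], d[2],
              min(apply(x$masks, 3, sum)), max(apply(x$masks, 3, sum))))
  invisible(x)
}

#' Write segmentation masks and contours
#'
#' Masks go to a NIfTI or TIFF stack of 0/1 values; contours and MV chords
#' go to a JSON file next to it (same basename, `.contours.json`) unless
#' `contours_path` is given.
#'
#' @param result an [la_segmentation()].
#' @param path mask stack destination (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param contours_path optional explicit JSON destination.
#' @return `path`, invisibly.
#' @export
write_masks <- function(result, path, contours_path = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(result$masks + 0)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(result$frame_count),
                    function(t) result$masks[, , t] + 0)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else stop("unsupported mask format: ", ext)
  cpath <- contours_path %||%
    paste0(sub("(\\.nii(\\.gz)?|\\.tiff?)$", "", path), ".contours.json")
  rec <- lapply(seq_len(result$frame_count), function(t) {
    list(frame = t - 1L,
         polygon = unname(result$contours[[t]]),
         mv = unname(result$mv_chord[[t]]))
  })
  jsonlite::write_json(rec, cpath, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read segmentation masks (and contours, when present) back
#'
#' @param path mask stack written by [write_masks()].
#' @param contours_path optional JSON path; defaults to the sibling
#'   `.contours.json` if it exists.
#' @return An [la_segmentation()]; when no contour file is found, contours
#'   and chords are empty lists of the right length.
#' @export
read_masks <- function(path, contours_path = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(pages)
  }
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  arr <- round(arr)
  t_n <- dim(arr)[3]
  cpath <- contours_path %||%
    paste0(sub("(\\.nii(\\.gz)?|\\.tiff?)$", "", path), ".contours.json")
  contours <- vector("list", t_n); chords <- vector("list", t_n)
  if (file.exists(cpath)) {
    rec <- jsonlite::fromJSON(cpath, simplifyDataFrame = FALSE)
    as_mat <- function(x) if (is.matrix(x)) x
                          else do.call(rbind, lapply(x, unlist))
    for (r in rec) {
      t <- r$frame + 1L
      contours[[t]] <- as_mat(r$polygon)
      chords[[t]] <- as_mat(r$mv)
    }
  }
  la_segmentation(arr, contours, chords)
}
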