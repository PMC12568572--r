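## PNG / CSV / JSON input-output helpers.

#' Write and read binary masks as single-channel PNG
#'
#' Foreground is stored as 255, background as 0.
#' @param mask Logical matrix.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write and read fundus images as 8-bit RGB PNG
#'
#' @param image `fundus_image` (raw RGB).
#' @param path Output file.
#' @export
write_fundus_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' @rdname write_fundus_png
#' @param pixel_pitch,eye,subject_id Metadata to attach (PNG carries none).
#' @export
read_fundus_png <- function(path, pixel_pitch = 10, eye = "OD",
                            subject_id = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) {
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  }
  px <- px[, , 1:3, drop = FALSE]
  structure(
    list(pixels = px, pixel_pitch = pixel_pitch, eye = eye,
         subject_id = subject_id),
    class = "fundus_image"
  )
}

#' Deterministic CSV writer
#'
#' Fixed field order, no row names, 15 significant digits — identical
#' inputs give byte-identical files.
#' @param df Data frame.
#' @param path Output file.
#' @export
write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) {
    df[[nm]] <- formatC(df[[nm]], digits = 15, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an ellipse pair (disc/cup) as JSON
#' @param ellipses `list(disc, cup)` from [detect_disc_cup()].
#' @param path Output file.
#' @export
write_ellipses_json <- function(ellipses, path) {
  jsonlite::write_json(ellipses, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
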