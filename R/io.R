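#' Read a Labelme annotation into an image sample
#'
#' Polygon shapes are rasterized in annotation order (later polygons
#' overwrite earlier ones); unlabelled pixels stay background. Shape labels
#' must belong to the class scheme. The companion image is loaded from
#' `imagePath` (PNG or TIFF) or decoded from an embedded `imageData` field.
#'
#' Rasterization is hard (no anti-aliasing) at native resolution: a pixel
#' belongs to a polygon when its center lies inside under the even-odd rule,
#' with half-open boundaries (left/top edges inclusive). Coordinates follow
#' the Labelme convention: `(x, y)` with the origin at the top-left pixel
#' center.
#'
#' @param path Path to the Labelme JSON file.
#' @return Sample list with `id`, `image` (`H x W x 3`, 0-255) and `mask`
#'   (`H x W`, 0-based labels).
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  scheme <- class_scheme()
  img <- NULL
  if (!is.null(doc$imageData) && nzchar(doc$imageData)) {
    img <- png::readPNG(jsonlite::base64_dec(doc$imageData))
  } else if (!is.null(doc$imagePath)) {
    ipath <- file.path(dirname(path), doc$imagePath)
    if (!file.exists(ipath)) stop("companion image not found: ", ipath)
    img <- if (grepl("\\.tiff?$", ipath, ignore.case = TRUE)) {
      requireNamespace("tiff")
      tiff::readTIFF(ipath)
    } else {
      png::readPNG(ipath)
    }
  } else {
    stop("annotation has neither imagePath nor imageData")
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img <- round(img[, , 1:3, drop = FALSE] * 255)
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  mask <- matrix(0L, h, w)
  for (shape in doc$shapes) {
    lbl <- shape$label
    if (!lbl %in% names(scheme)) {
      stop("unknown label '", lbl, "'; expected one of: ",
           paste(names(scheme), collapse = ", "))
    }
    pts <- do.call(rbind, lapply(shape$points, unlist))
    filled <- cpp_fill_polygon(pts[, 1L], pts[, 2L], h, w)
    sel <- matrix(filled, h, w, byrow = TRUE)
    mask[sel] <- scheme[[lbl]]
  }
  list(id = sub("\\.json$", "", basename(path)), image = img, mask = mask,
       truth = NULL)
}

mask_palette <- function() {
  # frozen palette: 0=black, 1=green, 2=red, 3=yellow
  matrix(c(0, 0, 0, 0, 1, 0, 1, 0, 0, 1, 1, 0), nrow = 4L, byrow = TRUE)
}

#' Write / read a label mask as a palette PNG
#'
#' Masks are stored as PNGs restricted to the frozen four-colour palette
#' (black = background, green = shoot, red = root, yellow = seed); reading
#' inverts the palette exactly, so the round trip is lossless.
#'
#' @param mask Integer `H x W` matrix with values in 0..3.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  if (any(!mask %in% 0:3)) {
    stop("mask values must be class indices 0..3")
  }
  pal <- mask_palette()
  idx <- as.integer(mask) + 1L
  img <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (c in 1:3) img[, , c] <- matrix(pal[idx, c], nrow(mask))
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @return `read_mask_png()` returns the integer label matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  pal <- mask_palette()
  key <- round(img[, , 1L]) * 4 + round(img[, , 2L]) * 2 + round(img[, , 3L])
  palkey <- pal[, 1L] * 4 + pal[, 2L] * 2 + pal[, 3L]
  mask <- matrix(match(key, palkey) - 1L, nrow(key))
  if (any(is.na(mask))) stop("PNG contains colours outside the mask palette")
  mask
}

#' Split sample ids into training and validation sets
#'
#' Deterministic shuffle under `seed`, then partition with
#' `floor(ratio * n)` training ids and the remainder in validation — 115
#' ids at ratio 0.8 give the 92/23 split.
#'
#' @param ids Character or integer vector of sample ids.
#' @param ratio Training fraction in (0, 1).
#' @param seed Shuffle seed.
#' @return List with `train_ids`, `val_ids` and `ratio`.
#' @export
split_dataset <- function(ids, ratio = 0.8, seed = 1L) {
  if (length(ids) == 0L) stop("ids must be non-empty")
  stopifnot(ratio > 0, ratio < 1)
  shuffled <- with_seed(seed, sample(ids))
  ntrain <- floor(ratio * length(ids))
  list(train_ids = shuffled[seq_len(ntrain)],
       val_ids = shuffled[setdiff(seq_along(ids), seq_len(ntrain))],
       ratio = ratio)
}
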