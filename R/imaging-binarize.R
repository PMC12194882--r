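# Image binarization and mask I/O. Images are plain numeric matrices in
# [0, 1] (row = image row); EBImage supplies thresholding, morphology and
# file I/O behind these wrappers.

as_gray_matrix <- function(image) {
  if (inherits(image, "Image")) {
    d <- dim(image)
    if (length(d) == 3) image <- image[, , 1]
    image <- t(EBImage::imageData(image))
  }
  m <- as.matrix(image)
  storage.mode(m) <- "double"
  m
}

#' Binarize a grayscale image
#'
#' Optionally applies a global linear contrast enhancement (a gain of
#' \code{contrast_stretch} percent about mid-gray, clamped to [0, 1]),
#' then thresholds by Otsu's method or at a fixed level.
#'
#' @param image numeric matrix (values in [0, 1]) or EBImage Image.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold threshold level for \code{method = "fixed"}.
#' @param contrast_stretch contrast gain in percent (e.g. 30); 0 disables.
#' @return Logical matrix (TRUE = foreground).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     contrast_stretch = 0) {
  method <- match.arg(method)
  m <- as_gray_matrix(image)
  if (contrast_stretch > 0) {
    m <- pmin(1, pmax(0, (m - 0.5) * (1 + contrast_stretch / 100) + 0.5))
  }
  if (method == "otsu") {
    if (diff(range(m)) < 1e-12) {
      stop("cannot Otsu-threshold a constant image")
    }
    th <- EBImage::otsu(EBImage::Image(t(m)), range = range(m))
  } else {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    th <- threshold
  }
  m > th
}

#' Read / write binary masks and grayscale images
#'
#' Thin wrappers over EBImage for 8/16-bit PNG and TIFF files.
#'
#' @param file image path.
#' @return \code{read_gray}: numeric matrix in [0, 1]; \code{read_mask}:
#'   logical matrix (pixels > 0.5).
#' @export
read_gray <- function(file) {
  as_gray_matrix(EBImage::readImage(file))
}

#' @rdname read_gray
#' @export
read_mask <- function(file) {
  read_gray(file) > 0.5
}

#' @rdname read_gray
#' @param image numeric or logical matrix to write.
#' @export
write_gray <- function(image, file) {
  m <- as.matrix(image)
  storage.mode(m) <- "double"
  EBImage::writeImage(EBImage::Image(t(m)), file)
  invisible(file)
}

# connected components >= min_area; returns list(label matrix, tibble of
# centroids/areas). 8-connectivity via EBImage::bwlabel.
label_components <- function(mask, min_area_px = 0) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (max(lab) == 0) {
    return(list(labels = lab,
                table = tibble::tibble(label = integer(0), area = integer(0),
                                       y = numeric(0), x = numeric(0))))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area_px)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  cy <- tapply(idx[, 1], labs, mean)
  cx <- tapply(idx[, 2], labs, mean)
  tab <- tibble::tibble(label = as.integer(names(cy)),
                        area = areas[as.integer(names(cy))],
                        y = as.numeric(cy), x = as.numeric(cx))
  tab <- tab[tab$label %in% keep, , drop = FALSE]
  lab[!(lab %in% keep)] <- 0L
  list(labels = lab, table = tab)
}
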