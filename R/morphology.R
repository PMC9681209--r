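# Micrometre-calibrated binary-mask morphology and the invasiveness index.
#
# Erosion and dilation are implemented by thresholding the Euclidean
# distance transform (EBImage::distmap), so structuring radii are physical
# distances in micrometres and pixelation bias stays within discretisation
# tolerance across resolutions.

#' Construct a calibrated binary mask
#'
#' @param pixels Numeric or logical matrix; any non-zero pixel is
#'   foreground.
#' @param pixel_size Pixel side length in micrometres per pixel.
#' @param role `"staining"` or `"tissue"`.
#' @return A list with class `calibrated_mask`: `mask` (0/1 matrix),
#'   `pixel_size`, `role`.
#' @export
calibrated_mask <- function(pixels, pixel_size,
                            role = c("staining", "tissue")) {
  role <- match.arg(role)
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(
    list(mask = (pixels != 0) * 1, pixel_size = pixel_size, role = role),
    class = "calibrated_mask"
  )
}

#' Total foreground area of a mask in square micrometres
#' @param x A `calibrated_mask`.
#' @return Area in um^2.
#' @export
mask_area <- function(x) {
  stopifnot(inherits(x, "calibrated_mask"))
  sum(x$mask) * x$pixel_size^2
}

#' Erode or dilate a calibrated mask by a physical radius
#'
#' Erosion keeps foreground pixels whose Euclidean distance to the nearest
#' background pixel exceeds `radius`; dilation adds background pixels
#' within `radius` of the foreground. `radius = 0` is the identity.
#'
#' @param x A `calibrated_mask`.
#' @param radius Radius in micrometres.
#' @return The transformed `calibrated_mask`.
#' @export
erode_mask <- function(x, radius) {
  stopifnot(inherits(x, "calibrated_mask"))
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0 || sum(x$mask) == 0) return(x)
  # pad a one-pixel background ring: everything outside the image counts
  # as background, so masks touching the border erode from the edge too
  nr <- nrow(x$mask); nc <- ncol(x$mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2L:(nr + 1L), 2L:(nc + 1L)] <- x$mask
  d <- EBImage::distmap(padded)[2L:(nr + 1L), 2L:(nc + 1L)]
  x$mask <- (d > radius / x$pixel_size) * 1
  x
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(x, radius) {
  stopifnot(inherits(x, "calibrated_mask"))
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0 || sum(x$mask) == 0 || all(x$mask == 1)) return(x)
  d <- EBImage::distmap(1 - x$mask)
  x$mask <- ((x$mask + (d <= radius / x$pixel_size)) > 0) * 1
  x
}

#' Exclude staining near the tissue edge
#'
#' Erodes the tissue mask by `margin` micrometres; staining outside the
#' eroded tissue is ignored downstream, excluding tumours at the section
#' edge.
#'
#' @param tissue A `calibrated_mask` with role `"tissue"`.
#' @param margin Erosion margin in micrometres (default 35).
#' @return The eroded tissue `calibrated_mask`.
#' @export
erode_tissue <- function(tissue, margin = 35) {
  erode_mask(tissue, margin)
}

label_components <- function(mask_obj) {
  lab <- EBImage::bwlabel(mask_obj$mask)
  n <- max(lab)
  if (n == 0L) {
    return(list(labels = lab,
                table = data.frame(id = integer(0), area_um2 = numeric(0))))
  }
  counts <- tabulate(lab[lab > 0], nbins = n)
  list(labels = lab,
       table = data.frame(id = seq_len(n),
                          area_um2 = counts * mask_obj$pixel_size^2))
}

#' Detect tumour-core components
#'
#' Morphological opening of the staining mask with an `open_radius`
#' structuring radius (erode then dilate by equal amounts, removing small
#' islands and thin processes while restoring the core border), followed
#' by connected-component labelling and removal of components smaller than
#' `min_area` square micrometres.
#'
#' @param staining A `calibrated_mask` of the staining.
#' @param open_radius Opening radius in micrometres (default 10).
#' @param min_area Minimum component area in um^2 (default 10000);
#'   components strictly smaller are discarded.
#' @return A list: `mask` (a `calibrated_mask` of retained cores),
#'   `components` (data.frame `id`, `area_um2`), `n_components`,
#'   `total_area_um2`.
#' @export
detect_core <- function(staining, open_radius = 10, min_area = 10000) {
  stopifnot(inherits(staining, "calibrated_mask"))
  opened <- dilate_mask(erode_mask(staining, open_radius), open_radius)
  comp <- label_components(opened)
  keep <- comp$table$id[comp$table$area_um2 >= min_area]
  opened$mask <- (matrix(comp$labels %in% keep, nrow(opened$mask))) * 1
  tab <- comp$table[comp$table$id %in% keep, , drop = FALSE]
  rownames(tab) <- NULL
  list(mask = opened, components = tab, n_components = nrow(tab),
       total_area_um2 = sum(tab$area_um2))
}

#' Detect gross-tumour components
#'
#' Dilates the staining by `d1` micrometres to bridge gaps between nearby
#' staining, erodes by `e1` and re-dilates by `d2` to smooth and restore
#' the border (default 75/100/25, a net-zero radius change on solid
#' shapes). Components that do not intersect any tumour-core pixel are
#' discarded. Components touching the image border are kept and flagged.
#'
#' @param staining A `calibrated_mask` of the staining.
#' @param cores Result of [detect_core()] (its `mask` is used for the
#'   containment rule).
#' @param d1,e1,d2 Dilation/erosion/dilation radii in micrometres.
#' @return A list like [detect_core()]'s, with a `border` flag column in
#'   `components`.
#' @export
detect_gross <- function(staining, cores, d1 = 75, e1 = 100, d2 = 25) {
  stopifnot(inherits(staining, "calibrated_mask"))
  g <- dilate_mask(erode_mask(dilate_mask(staining, d1), e1), d2)
  comp <- label_components(g)
  core_mask <- cores$mask$mask
  keep <- integer(0)
  border <- logical(0)
  if (nrow(comp$table) > 0L) {
    nr <- nrow(comp$labels); nc <- ncol(comp$labels)
    for (id in comp$table$id) {
      sel <- comp$labels == id
      if (any(core_mask[sel] > 0)) {
        keep <- c(keep, id)
        border <- c(border,
                    any(sel[1L, ]) || any(sel[nr, ]) ||
                    any(sel[, 1L]) || any(sel[, nc]))
      }
    }
  }
  g$mask <- (matrix(comp$labels %in% keep, nrow(g$mask))) * 1
  tab <- comp$table[comp$table$id %in% keep, , drop = FALSE]
  tab$border <- border
  rownames(tab) <- NULL
  list(mask = g, components = tab, n_components = nrow(tab),
       total_area_um2 = sum(tab$area_um2))
}

#' Invasiveness index
#'
#' Gross tumour area divided by tumour core area; a dimensionless measure
#' of infiltration that is independent of tumour size. 1 means no
#' detectable infiltration beyond the core.
#'
#' @param core_area,gross_area Areas in um^2.
#' @return `gross_area / core_area`, or `NA_real_` when the core area is
#'   zero.
#' @export
invasiveness_index <- function(core_area, gross_area) {
  ifelse(core_area > 0, gross_area / core_area, NA_real_)
}

#' Run the full morphology pipeline on one section
#'
#' Composes tissue-margin exclusion, core detection, gross-tumour
#' detection and the invasiveness index.
#'
#' @param tissue A `calibrated_mask` of the detected tissue.
#' @param staining A `calibrated_mask` of the staining; must share
#'   `pixel_size` and dimensions with `tissue`.
#' @param tissue_margin Tissue erosion margin in micrometres (default 35).
#' @param open_radius,min_area Core-detection parameters
#'   (default 10 um, 10000 um^2).
#' @param d1,e1,d2 Gross-detection radii (default 75/100/25 um).
#' @return A list with class `invasiveness_result`: `tissue_area_um2`,
#'   `core_area_um2`, `gross_area_um2`, `ii`, `n_core_components`,
#'   `n_gross_components`.
#' @export
run_section <- function(tissue, staining, tissue_margin = 35,
                        open_radius = 10, min_area = 10000,
                        d1 = 75, e1 = 100, d2 = 25) {
  stopifnot(inherits(tissue, "calibrated_mask"),
            inherits(staining, "calibrated_mask"))
  if (tissue$pixel_size != staining$pixel_size) {
    stop("tissue and staining masks have different pixel sizes")
  }
  if (!all(dim(tissue$mask) == dim(staining$mask))) {
    stop("tissue and staining masks have different dimensions")
  }
  tis <- erode_tissue(tissue, tissue_margin)
  st <- staining
  st$mask <- st$mask * tis$mask
  cores <- detect_core(st, open_radius, min_area)
  gross <- detect_gross(st, cores, d1, e1, d2)
  structure(
    list(
      tissue_area_um2 = mask_area(tis),
      core_area_um2 = cores$total_area_um2,
      gross_area_um2 = gross$total_area_um2,
      ii = invasiveness_index(cores$total_area_um2, gross$total_area_um2),
      n_core_components = cores$n_components,
      n_gross_components = gross$n_components
    ),
    class = "invasiveness_result"
  )
}

#' Aggregate section-level invasiveness to one specimen value
#'
#' @param results List of `invasiveness_result` objects (e.g. the stained
#'   levels of one specimen).
#' @param method `"mean"` (default) or `"median"`.
#' @return The aggregated invasiveness index (sections with undefined II
#'   are dropped; `NA` when none remain).
#' @export
aggregate_sections <- function(results, method = c("mean", "median")) {
  method <- match.arg(method)
  ii <- vapply(results, function(r) r$ii, numeric(1))
  ii <- ii[!is.na(ii)]
  if (length(ii) == 0L) return(NA_real_)
  if (method == "mean") mean(ii) else median(ii)
}

# ---- mask I/O ---------------------------------------------------------------

#' Read / write binary masks as PNG or TIFF
#'
#' Greyscale images are binarised with an explicit user threshold on the
#' `[0, 1]` intensity scale; multi-channel images use the first channel.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size Micrometres per pixel.
#' @param threshold Intensity threshold; pixels strictly above it are
#'   foreground (default 0.5).
#' @param role Mask role, passed to [calibrated_mask()].
#' @return `read_mask()` returns a `calibrated_mask`.
#' @export
read_mask <- function(path, pixel_size, threshold = 0.5,
                      role = c("staining", "tissue")) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  calibrated_mask((img > threshold) * 1, pixel_size, role = role)
}

#' @rdname read_mask
#' @param x A `calibrated_mask`.
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "calibrated_mask"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x$mask, path),
    tif = ,
    tiff = tiff::writeTIFF(x$mask, path),
    stop("unsupported mask format: .", ext)
  )
  invisible(path)
}
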