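# Synthetic histology phantoms: a solid tumour core plus an infiltrative
# halo of small disks, with analytic truth areas.

draw_disk <- function(mask, cx, cy, r_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- max(1L, floor(cx - r_px)):min(nr, ceiling(cx + r_px))
  ci <- max(1L, floor(cy - r_px)):min(nc, ceiling(cy + r_px))
  sub <- outer((ri - cx)^2, (ci - cy)^2, "+") <= r_px^2
  mask[ri, ci] <- pmax(mask[ri, ci], sub * 1)
  mask
}

#' Generate a synthetic tumour mask with a core and an infiltrative halo
#'
#' Places one solid disk (the tumour core) at the image centre and
#' scatters small disks (infiltrating cells) in an annulus around it.
#' Halo positions are rejection-sampled so the disks never touch the core
#' and stay inside the image margin; the analytic area of every disk is
#' recorded as truth.
#'
#' @param image_size Image side length in pixels (square image).
#' @param pixel_size Micrometres per pixel.
#' @param core_radius Core radius in micrometres; the core diameter must
#'   fit in the image.
#' @param halo `data.frame` with columns `radius` (um) and `count`, one
#'   row per halo disk size; `NULL` or zero rows for no halo.
#' @param halo_span Width of the halo annulus beyond the core edge, in
#'   micrometres (default 250).
#' @param halo_gap Minimum clearance between a halo disk edge and the core
#'   edge, in micrometres (default 30).
#' @param seed Integer seed.
#' @return A list: `staining` and `tissue` (`calibrated_mask`s; the
#'   tissue covers the whole image), and `truth` with `core_area_um2`
#'   (analytic), `halo` (`data.frame` of disk centres/radii/areas) and
#'   `seed`.
#' @export
gen_tumour_mask <- function(image_size = 512L, pixel_size = 1,
                            core_radius = 100,
                            halo = NULL, halo_span = 250, halo_gap = 30,
                            seed = 1L) {
  extent <- image_size * pixel_size
  if (2 * core_radius >= extent) {
    stop("core diameter must be smaller than the image extent")
  }
  withr::with_seed(seed, {
    m <- matrix(0, image_size, image_size)
    cx <- (image_size + 1) / 2
    r_core_px <- core_radius / pixel_size
    m <- draw_disk(m, cx, cx, r_core_px)

    halo_truth <- data.frame(x_um = numeric(0), y_um = numeric(0),
                             radius_um = numeric(0), area_um2 = numeric(0))
    if (!is.null(halo) && nrow(halo) > 0L) {
      for (i in seq_len(nrow(halo))) {
        r_um <- halo$radius[i]
        for (k in seq_len(halo$count[i])) {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            d_um <- runif(1, core_radius + halo_gap + r_um,
                          core_radius + halo_span)
            th <- runif(1, 0, 2 * pi)
            x_um <- (cx - 0.5) * pixel_size + d_um * cos(th)
            y_um <- (cx - 0.5) * pixel_size + d_um * sin(th)
            if (x_um - r_um < pixel_size || y_um - r_um < pixel_size ||
                x_um + r_um > extent - pixel_size ||
                y_um + r_um > extent - pixel_size) next
            placed <- TRUE
            break
          }
          if (!placed) {
            stop("could not place a halo disk; shrink the halo or ",
                 "enlarge the image")
          }
          m <- draw_disk(m, x_um / pixel_size + 0.5, y_um / pixel_size + 0.5,
                         r_um / pixel_size)
          halo_truth <- rbind(halo_truth, data.frame(
            x_um = x_um, y_um = y_um, radius_um = r_um,
            area_um2 = pi * r_um^2
          ))
        }
      }
    }
    list(
      staining = calibrated_mask(m, pixel_size, role = "staining"),
      tissue = calibrated_mask(matrix(1, image_size, image_size),
                               pixel_size, role = "tissue"),
      truth = list(core_area_um2 = pi * core_radius^2,
                   halo = halo_truth, seed = seed)
    )
  })
}
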