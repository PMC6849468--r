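#' Segmentation configuration
#'
#' Parameters of the image-processing chain that isolates the digital
#' plant object from a raw RGB view: region of interest, hue windows
#' for the green plant and the blue support cage, a grey-intensity
#' threshold that suppresses the bright background, a minimum
#' connected-component area, and an optional morphological closing
#' radius.
#'
#' @param roi `NULL` for the full frame, or an integer vector
#'   `c(row_min, row_max, col_min, col_max)` in pixel coordinates.
#' @param grey_threshold pixels whose grey intensity (luma) is at or
#'   above this value are treated as background; in `[0, 1]`.
#' @param plant_hue_window,cage_hue_window `[low, high]` hue windows in
#'   degrees; must be disjoint.
#' @param saturation_min minimum saturation for a pixel to be colour-
#'   classified at all; achromatic (white/grey/shadow) pixels fall
#'   below it.
#' @param min_component_area connected components (8-connectivity)
#'   smaller than this many pixels are removed.
#' @param morphology_radius radius in pixels of a final binary closing;
#'   0 disables it (the default, which keeps pixel counts exact on
#'   clean scenes).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(roi = NULL, grey_threshold = 0.95,
                                plant_hue_window = c(60, 180),
                                cage_hue_window = c(200, 260),
                                saturation_min = 0.25,
                                min_component_area = 4L,
                                morphology_radius = 0L) {
  grey_threshold <- check_number(grey_threshold, "grey_threshold", min = 0, max = 1)
  saturation_min <- check_number(saturation_min, "saturation_min", min = 0, max = 1)
  min_component_area <- check_number(min_component_area, "min_component_area",
                                     min = 1, integer = TRUE)
  morphology_radius <- check_number(morphology_radius, "morphology_radius",
                                    min = 0, integer = TRUE)
  win_ok <- function(w, name) {
    if (!is.numeric(w) || length(w) != 2L || w[1L] >= w[2L] ||
        w[1L] < 0 || w[2L] > 360)
      stop_bad_arg(sprintf("`%s` must be c(low, high) in [0, 360] degrees", name))
    w
  }
  plant_hue_window <- win_ok(plant_hue_window, "plant_hue_window")
  cage_hue_window <- win_ok(cage_hue_window, "cage_hue_window")
  if (max(plant_hue_window[1L], cage_hue_window[1L]) <
      min(plant_hue_window[2L], cage_hue_window[2L]))
    stop_bad_arg("plant and cage hue windows must be disjoint")
  if (!is.null(roi)) {
    if (!is.numeric(roi) || length(roi) != 4L)
      stop_bad_arg("`roi` must be c(row_min, row_max, col_min, col_max) or NULL")
    if (roi[1L] > roi[2L] || roi[3L] > roi[4L] || any(roi < 1))
      stop_bad_arg("`roi` is empty or out of bounds")
    roi <- as.integer(roi)
  }
  structure(list(roi = roi, grey_threshold = grey_threshold,
                 plant_hue_window = plant_hue_window,
                 cage_hue_window = cage_hue_window,
                 saturation_min = saturation_min,
                 min_component_area = as.integer(min_component_area),
                 morphology_radius = as.integer(morphology_radius)),
            class = "segmentation_config")
}

# 8-connected component labels of a logical mask, via the pixel
# adjacency graph (EBImage::bwlabel is 4-connected, so it is not used
# here). Returns an integer matrix, 0 for background.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, h, w)
  if (!length(idx)) return(out)
  node <- match(seq_len(h * w), idx)  # pixel -> node id (NA off-mask)
  edges <- integer(0)
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1L]; cc <- c + off[2L]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    nb <- (cc[ok] - 1L) * h + rr[ok]
    keep <- mask[nb]
    if (any(keep))
      edges <- c(edges, rbind(node[idx[ok][keep]], node[nb[keep]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# Remove 8-connected components smaller than min_area pixels.
remove_small_components <- function(mask, min_area) {
  if (min_area <= 1L || !any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  lab %in% keep & mask
}

#' Segment the digital plant object from an RGB view
#'
#' Runs the image-processing chain: (1) crop to the region of
#' interest, (2) classify pixels by hue/saturation into plant, cage and
#' background classes, (3) threshold the grey-converted intensity to
#' suppress bright background and glare, (4) discard cage-class pixels,
#' (5) remove 8-connected components smaller than
#' `min_component_area`, (6) optionally apply a binary closing. The
#' surviving foreground is the digital plant object whose pixel count
#' is the raw material of the EB and TVA traits.
#'
#' @param image RGB array (`height x width x 3`, values in `[0, 1]`),
#'   or a `scene` from [render_scene()].
#' @param config a [segmentation_config()].
#' @param view,das,pot_id,variety,n_level optional metadata attached to
#'   the result (taken from the scene spec when a scene is supplied).
#' @return An object of class `digital_object`: list with `mask`
#'   (logical matrix, same size as the ROI-cropped image),
#'   `pixel_count`, and the metadata fields.
#' @examples
#' sc <- render_scene(scene_spec(plant_pixel_count = 800, seed = 1))
#' obj <- segment_plant(sc, segmentation_config())
#' obj$pixel_count  # 800
#' @export
segment_plant <- function(image, config = segmentation_config(),
                          view = NA_character_, das = NA_real_,
                          pot_id = NA_character_, variety = NA_character_,
                          n_level = NA_character_) {
  if (inherits(image, "scene")) {
    if (is.na(view)) view <- image$spec$view
    image <- image$image
  }
  if (!inherits(config, "segmentation_config"))
    stop_bad_arg("`config` must be created with segmentation_config()")
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stop_bad_arg("`image` must be an RGB array (height x width x 3)")
  if (dim(image)[3L] > 3L) image <- image[, , 1:3, drop = FALSE]

  if (!is.null(config$roi)) {
    roi <- config$roi
    if (roi[2L] > dim(image)[1L] || roi[4L] > dim(image)[2L])
      stop_bad_arg("`roi` exceeds the image bounds")
    image <- image[roi[1L]:roi[2L], roi[3L]:roi[4L], , drop = FALSE]
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  rgb <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  hsv <- rgb_to_hsv_mat(rgb)

  chromatic <- hsv$s >= config$saturation_min
  plant <- chromatic &
    hsv$h >= config$plant_hue_window[1L] & hsv$h <= config$plant_hue_window[2L]
  cage <- chromatic &
    hsv$h >= config$cage_hue_window[1L] & hsv$h <= config$cage_hue_window[2L]

  grey <- 0.299 * rgb[, 1L] + 0.587 * rgb[, 2L] + 0.114 * rgb[, 3L]
  plant <- plant & grey < config$grey_threshold
  plant <- plant & !cage

  mask <- matrix(plant, h, w)
  mask <- remove_small_components(mask, config$min_component_area)
  if (config$morphology_radius > 0L) {
    brush <- EBImage::makeBrush(2L * config$morphology_radius + 1L, "disc")
    mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), h, w)
  }

  structure(list(mask = mask, pixel_count = sum(mask), view = view,
                 das = das, pot_id = pot_id, variety = variety,
                 n_level = n_level),
            class = "digital_object")
}

#' @export
print.digital_object <- function(x, ...) {
  cat(sprintf("<digital_object> %d foreground px (%d x %d mask)%s\n",
              x$pixel_count, nrow(x$mask), ncol(x$mask),
              if (!is.na(x$view)) paste0(", view ", x$view) else ""))
  invisible(x)
}
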