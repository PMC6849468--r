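#' Estimated shoot biomass (EB) from one plant's four views
#'
#' EB is the pixel sum of the segmented plant object over the three
#' side views (0, 120 and 240 degree rotations) and the top view,
#' expressed in kilopixels (1 kPix = 1000 pixels). The four views are
#' summed, not averaged.
#'
#' @param objects list of exactly four [segment_plant()] results, one
#'   per view in `side_0`, `side_120`, `side_240`, `top`, from the same
#'   pot and imaging day.
#' @return EB in kilopixels.
#' @export
estimated_biomass <- function(objects) {
  if (!is.list(objects) || !all(vapply(objects, inherits, logical(1), "digital_object")))
    stop_bad_arg("`objects` must be a list of digital_object results")
  views <- vapply(objects, function(o) o$view, character(1))
  if (length(views) != 4L || !setequal(views, .scene_views) ||
      anyDuplicated(views))
    stop_bad_arg("need exactly one object per view {",
                 paste(.scene_views, collapse = ", "), "}; got: ",
                 paste(sort(views), collapse = ", "))
  ids <- unique(vapply(objects, function(o) paste(o$pot_id, o$das), character(1)))
  if (length(ids) != 1L)
    stop_bad_arg("all four views must come from the same pot and imaging day")
  sum(vapply(objects, function(o) o$pixel_count, numeric(1))) / 1000
}

#' Top-view area (TVA) of a plant
#'
#' TVA is the pixel sum of the segmented top-view object in kilopixels.
#'
#' @param object a [segment_plant()] result with `view = "top"`.
#' @return TVA in kilopixels.
#' @export
top_view_area <- function(object) {
  if (!inherits(object, "digital_object"))
    stop_bad_arg("`object` must be a digital_object")
  if (is.na(object$view) || object$view != "top")
    stop_bad_arg("TVA requires the top view; got view = ",
                 object$view %||% NA)
  object$pixel_count / 1000
}

read_view_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_bad_arg("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop_bad_arg("unsupported image format: ", path))
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop_bad_arg("not an RGB image: ", path)
  img
}

#' Extract a digital trait table from an image manifest
#'
#' Segments every image listed in the manifest and assembles one trait
#' record (EB and TVA, kilopixels) per pot x imaging day. Groups with
#' missing or duplicated views, or with unreadable files, are reported
#' in the `"skipped"` attribute (and as warnings) and skipped;
#' processing continues.
#'
#' @param manifest data frame with columns `pot_id`, `variety`,
#'   `n_level`, `das`, `view`, `path`.
#' @param config a [segmentation_config()].
#' @return Data frame with columns `pot_id`, `variety`, `n_level`,
#'   `das`, `eb_kpix`, `tva_kpix`, ordered by pot and day, with a
#'   `"skipped"` attribute describing any incomplete groups.
#' @export
extract_trait_table <- function(manifest, config = segmentation_config()) {
  check_columns(manifest, c("pot_id", "variety", "n_level", "das", "view", "path"),
                "manifest")
  if (anyNA(manifest[c("pot_id", "das", "view", "path")]))
    stop_bad_arg("manifest rows must be complete (pot_id, das, view, path)")
  key <- interaction(manifest$pot_id, manifest$das, drop = TRUE)
  rows <- list(); skipped <- list()
  for (k in levels(key)) {
    grp <- manifest[key == k, , drop = FALSE]
    if (!setequal(grp$view, .scene_views) || nrow(grp) != 4L) {
      skipped[[k]] <- data.frame(pot_id = grp$pot_id[1L], das = grp$das[1L],
                                 reason = paste("incomplete view set:",
                                                paste(sort(grp$view), collapse = ", ")))
      next
    }
    objs <- vector("list", 4L)
    ok <- TRUE
    for (i in seq_len(4L)) {
      img <- tryCatch(read_view_image(grp$path[i]), error = function(e) e)
      if (inherits(img, "error")) {
        warning("could not read image ", grp$path[i], ": ",
                conditionMessage(img), call. = FALSE)
        skipped[[k]] <- data.frame(pot_id = grp$pot_id[1L], das = grp$das[1L],
                                   reason = paste("unreadable image:", grp$path[i]))
        ok <- FALSE
        break
      }
      objs[[i]] <- segment_plant(img, config, view = grp$view[i],
                                 das = grp$das[i], pot_id = grp$pot_id[i],
                                 variety = grp$variety[i],
                                 n_level = grp$n_level[i])
    }
    if (!ok) next
    top <- objs[[which(grp$view == "top")]]
    rows[[k]] <- data.frame(pot_id = grp$pot_id[1L], variety = grp$variety[1L],
                            n_level = grp$n_level[1L], das = grp$das[1L],
                            eb_kpix = estimated_biomass(objs),
                            tva_kpix = top_view_area(top))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pot_id = character(), variety = character(),
               n_level = character(), das = numeric(),
               eb_kpix = numeric(), tva_kpix = numeric())
  out <- out[order(out$pot_id, out$das), , drop = FALSE]
  rownames(out) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, c(skipped, make.row.names = FALSE)) else
    data.frame(pot_id = character(), das = numeric(), reason = character())
  if (nrow(skipped))
    warning(sprintf("%d pot x day group(s) skipped; see attr(x, 'skipped')",
                    nrow(skipped)), call. = FALSE)
  attr(out, "skipped") <- skipped
  out
}
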