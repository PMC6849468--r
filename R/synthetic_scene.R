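#' Pixel label codes used in synthetic scenes
#'
#' Ground-truth classes recorded in the label raster that accompanies
#' every rendered scene: `background` (white pot/backdrop, including the
#' grey pot band), `plant` (visible green plant material), `cage` (blue
#' support-cage pixels, including cage pixels that occlude the plant)
#' and `speckle` (small isolated green noise specks used to exercise
#' component-size filtering).
#'
#' @format Named integer vector of length 4.
#' @export
scene_label_codes <- c(background = 0L, plant = 1L, cage = 2L, speckle = 3L)

.scene_views <- c("side_0", "side_120", "side_240", "top")

#' Specify a synthetic plant scene
#'
#' Describes one camera view of a potted wheat plant for
#' [render_scene()]: image size, the exact number of ground-truth plant
#' pixels to draw, the fraction of those occluded by the blue support
#' cage, and the number of isolated green noise speckles.
#'
#' @param view one of `"side_0"`, `"side_120"`, `"side_240"`, `"top"`.
#' @param image_height,image_width image size in pixels (>= 64).
#' @param plant_pixel_count exact number of plant pixels to draw before
#'   cage occlusion; must not exceed half the image area.
#' @param cage_fraction proportion in `[0, 1)` of plant pixels occluded
#'   by the cage (re-labelled `cage` in the ground truth).
#' @param noise_speckle_count number of isolated single-pixel green
#'   speckles, placed at least 2 pixels away from any plant pixel.
#' @param seed integer seed; rendering is deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @seealso [render_scene()]
#' @export
scene_spec <- function(view = "side_0", image_height = 96L, image_width = 96L,
                       plant_pixel_count = 1000L, cage_fraction = 0,
                       noise_speckle_count = 0L, seed = 1L) {
  if (!is.character(view) || length(view) != 1L || !view %in% .scene_views)
    stop_bad_arg("`view` must be one of: ", paste(.scene_views, collapse = ", "))
  image_height <- check_number(image_height, "image_height", min = 64, integer = TRUE)
  image_width <- check_number(image_width, "image_width", min = 64, integer = TRUE)
  plant_pixel_count <- check_number(plant_pixel_count, "plant_pixel_count",
                                    min = 0, integer = TRUE)
  area <- image_height * image_width
  if (plant_pixel_count > 0.5 * area)
    stop_bad_arg(sprintf(
      "plant_pixel_count (%d) exceeds half the image area (%d of %d pixels)",
      plant_pixel_count, floor(0.5 * area), area))
  cage_fraction <- check_number(cage_fraction, "cage_fraction", min = 0, max = 1)
  if (cage_fraction >= 1) stop_bad_arg("`cage_fraction` must be < 1")
  noise_speckle_count <- check_number(noise_speckle_count, "noise_speckle_count",
                                      min = 0, integer = TRUE)
  seed <- check_number(seed, "seed", integer = TRUE)
  structure(list(view = view,
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 plant_pixel_count = as.integer(plant_pixel_count),
                 cage_fraction = cage_fraction,
                 noise_speckle_count = as.integer(noise_speckle_count),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Grow a 4-connected, direction-biased blob of up to `n` new cells.
# `occ` is the current plant occupancy; growth starts from `start`
# (linear index; may already be occupied, in which case only new cells
# count). Returns the linear indices of the new cells.
grow_blob <- function(occ, start, n, h, w, margin = 2L) {
  theta <- stats::runif(1, 0, 2 * pi)
  dir <- c(cos(theta), sin(theta))
  per <- c(-dir[2L], dir[1L])
  r0 <- (start - 1L) %% h + 1L
  c0 <- (start - 1L) %/% h + 1L

  in_bounds <- function(r, c)
    r > margin & r <= h - margin & c > margin & c <= w - margin

  neigh <- function(idx) {
    r <- (idx - 1L) %% h + 1L
    c <- (idx - 1L) %/% h + 1L
    rr <- c(r - 1L, r + 1L, r, r)
    cc <- c(c, c, c - 1L, c + 1L)
    ok <- in_bounds(rr, cc)
    (cc[ok] - 1L) * h + rr[ok]
  }

  score_of <- function(idx) {
    r <- (idx - 1L) %% h + 1L
    c <- (idx - 1L) %/% h + 1L
    along <- (r - r0) * dir[1L] + (c - c0) * dir[2L]
    across <- (r - r0) * per[1L] + (c - c0) * per[2L]
    abs(along) - 0.6 * abs(across) + stats::runif(length(idx), 0, 1.2)
  }

  new_cells <- integer(0)
  in_cand <- matrix(FALSE, h, w)
  if (!occ[start]) {
    cand <- start
  } else {
    nb <- neigh(start)
    cand <- nb[!occ[nb]]
  }
  if (!length(cand)) return(new_cells)
  in_cand[cand] <- TRUE
  scores <- score_of(cand)

  while (length(new_cells) < n && length(cand)) {
    k <- which.max(scores)
    cell <- cand[k]
    cand <- cand[-k]; scores <- scores[-k]
    in_cand[cell] <- FALSE
    if (occ[cell]) next
    occ[cell] <- TRUE
    new_cells <- c(new_cells, cell)
    nb <- neigh(cell)
    nb <- nb[!occ[nb] & !in_cand[nb]]
    if (length(nb)) {
      in_cand[nb] <- TRUE
      cand <- c(cand, nb)
      scores <- c(scores, score_of(nb))
    }
  }
  new_cells
}

#' Render a synthetic plant scene with ground-truth labels
#'
#' Draws a plant as a union of elongated green blobs on a white
#' background with a grey pot band, optionally occluded by a blue
#' support cage and contaminated with isolated green noise speckles.
#' The returned label raster records the true class of every pixel (see
#' [scene_label_codes]); before occlusion the scene contains exactly
#' `spec$plant_pixel_count` plant pixels, and occluded pixels are
#' re-labelled `cage`, so visible plant pixels number exactly
#' `plant_pixel_count - round(cage_fraction * plant_pixel_count)`.
#'
#' Plant blobs are each at least 30 pixels (or the whole remaining
#' count), so that no genuine plant component falls below a typical
#' component-size filter; speckles are single pixels at least 2 pixels
#' away from the plant. Rendering is deterministic given the spec.
#'
#' @param spec a [scene_spec()].
#' @return A list of class `scene` with elements `image` (height x
#'   width x 3 RGB array in `[0, 1]`), `labels` (integer matrix of
#'   ground-truth codes) and `spec`.
#' @examples
#' sc <- render_scene(scene_spec(plant_pixel_count = 500, seed = 3))
#' sum(sc$labels == scene_label_codes[["plant"]])  # exactly 500
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    stop_bad_arg("`spec` must be created with scene_spec()")
  h <- spec$image_height; w <- spec$image_width
  margin <- 2L
  with_seed(spec$seed, {
    occ <- matrix(FALSE, h, w)
    placed <- 0L
    attempts <- 0L
    min_blob <- 30L
    while (placed < spec$plant_pixel_count) {
      attempts <- attempts + 1L
      if (attempts > 2000L)
        stop_bad_arg(sprintf(
          "could not place %d plant pixels in a %d x %d scene (drawable area exhausted)",
          spec$plant_pixel_count, h, w))
      remaining <- spec$plant_pixel_count - placed
      target <- if (remaining <= 2L * min_blob) remaining
                else min(sample(seq(60L, 300L), 1L), remaining)
      if (remaining - target < min_blob && remaining - target > 0L)
        target <- remaining
      if (remaining < min_blob && placed > 0L) {
        # extend an existing blob instead of starting a sub-threshold one
        start <- sample(which(occ), 1L)
      } else {
        free <- which(!occ)
        rr <- (free - 1L) %% h + 1L
        cc <- (free - 1L) %/% h + 1L
        free <- free[rr > margin & rr <= h - margin & cc > margin & cc <= w - margin]
        if (!length(free))
          stop_bad_arg(sprintf(
            "could not place %d plant pixels in a %d x %d scene (drawable area exhausted)",
            spec$plant_pixel_count, h, w))
        start <- if (length(free) == 1L) free else sample(free, 1L)
      }
      cells <- grow_blob(occ, start, target, h, w, margin)
      occ[cells] <- TRUE
      placed <- placed + length(cells)
    }

    labels <- matrix(scene_label_codes[["background"]], h, w)
    labels[occ] <- scene_label_codes[["plant"]]

    # isolated green speckles, >= 2 px (Chebyshev) from any plant pixel
    if (spec$noise_speckle_count > 0L) {
      halo <- occ
      for (dr in -2:2) for (dc in -2:2) {
        if (dr == 0L && dc == 0L) next
        src <- occ
        rs <- max(1L, 1L - dr):min(h, h - dr)
        cs <- max(1L, 1L - dc):min(w, w - dc)
        halo[rs + dr, cs + dc] <- halo[rs + dr, cs + dc] | src[rs, cs]
      }
      free <- which(!halo & labels == scene_label_codes[["background"]])
      rr <- (free - 1L) %% h + 1L
      cc <- (free - 1L) %/% h + 1L
      free <- free[rr > margin & rr <= h - margin & cc > margin & cc <= w - margin]
      if (length(free) < spec$noise_speckle_count)
        stop_bad_arg("not enough free area for the requested noise speckles")
      spk <- sample(free, spec$noise_speckle_count)
      labels[spk] <- scene_label_codes[["speckle"]]
    }

    # blue cage: vertical bars over the background plus exact occlusion
    n_occlude <- round(spec$cage_fraction * spec$plant_pixel_count)
    bar_cols <- integer(0)
    if (spec$cage_fraction > 0 || n_occlude > 0L) {
      nbars <- 3L
      starts <- sample(seq(margin + 1L, w - margin - 2L), nbars)
      bar_cols <- sort(unique(as.integer(outer(starts, 0:1, `+`))))
      bg_in_bars <- labels[, bar_cols] == scene_label_codes[["background"]]
      labels[, bar_cols][bg_in_bars] <- scene_label_codes[["cage"]]
      if (n_occlude > 0L) {
        plant_idx <- which(labels == scene_label_codes[["plant"]])
        pc <- (plant_idx - 1L) %/% h + 1L
        pr <- (plant_idx - 1L) %% h + 1L
        dist_to_bar <- vapply(pc, function(x) min(abs(x - bar_cols)), numeric(1))
        ord <- order(dist_to_bar, pc, pr)
        occluded <- matrix(FALSE, h, w)
        occluded[plant_idx[ord[seq_len(n_occlude)]]] <- TRUE
        labels[occluded] <- scene_label_codes[["cage"]]
        # occlusion may cut a blob and strand visible fragments below a
        # component-size filter; trade such fragments for occluded
        # pixels attached to large components so that visible plant
        # pixel counts stay exact and filter-safe
        min_fragment <- 8L
        for (pass in 1:20) {
          vis <- labels == scene_label_codes[["plant"]]
          lab <- label_components8(vis)
          sizes <- tabulate(lab)
          frag_comps <- which(sizes < min_fragment)
          if (!length(frag_comps)) break
          frag_idx <- which(vis & matrix(lab %in% frag_comps, h, w))
          big <- lab > 0 & !(matrix(lab %in% frag_comps, h, w))
          bigd <- big
          for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0L && dc == 0L) next
            rs <- max(1L, 1L - dr):min(h, h - dr)
            cs <- max(1L, 1L - dc):min(w, w - dc)
            bigd[rs + dr, cs + dc] <- bigd[rs + dr, cs + dc] | big[rs, cs]
          }
          labels[frag_idx] <- scene_label_codes[["cage"]]
          occluded[frag_idx] <- TRUE
          # return occluded pixels one by one, each attached to a large
          # visible component (or to a pixel already returned)
          for (i in seq_along(frag_idx)) {
            cand <- which(occluded & bigd)
            if (!length(cand))
              stop_bad_arg("cannot occlude the requested cage_fraction ",
                           "without stranding sub-threshold plant fragments")
            take <- cand[1L]
            labels[take] <- scene_label_codes[["plant"]]
            occluded[take] <- FALSE
            tr <- (take - 1L) %% h + 1L
            tc <- (take - 1L) %/% h + 1L
            rs <- max(1L, tr - 1L):min(h, tr + 1L)
            cs <- max(1L, tc - 1L):min(w, tc + 1L)
            bigd[rs, cs] <- TRUE
          }
        }
      }
    }

    # paint: achromatic white backdrop + grey pot band; plant/speckle in
    # green hues, cage in blue hues
    n <- h * w
    v_bg <- stats::runif(n, 0.93, 1.0)
    rgb <- cbind(v_bg, v_bg, v_bg)
    pot_rows <- labels == scene_label_codes[["background"]] &
      row(labels) > round(0.85 * h)
    v_pot <- stats::runif(sum(pot_rows), 0.70, 0.80)
    rgb[pot_rows, ] <- cbind(v_pot, v_pot, v_pot)

    paint <- function(idx, h_lo, h_hi, s_lo, s_hi, v_lo, v_hi) {
      k <- length(idx)
      if (!k) return()
      rgb[idx, ] <<- hsv_to_rgb_mat(stats::runif(k, h_lo, h_hi),
                                    stats::runif(k, s_lo, s_hi),
                                    stats::runif(k, v_lo, v_hi))
    }
    paint(which(labels == scene_label_codes[["plant"]]), 95, 140, 0.55, 0.90, 0.45, 0.85)
    paint(which(labels == scene_label_codes[["speckle"]]), 95, 140, 0.60, 0.90, 0.50, 0.80)
    paint(which(labels == scene_label_codes[["cage"]]), 215, 245, 0.60, 0.95, 0.50, 0.90)

    image <- array(rgb, dim = c(h, w, 3L))
    structure(list(image = image, labels = labels, spec = spec),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  counts <- table(factor(x$labels, levels = scene_label_codes,
                         labels = names(scene_label_codes)))
  cat(sprintf("<scene> %s view, %d x %d px\n", x$spec$view,
              x$spec$image_height, x$spec$image_width))
  print(counts)
  invisible(x)
}

#' Write a scene to disk as PNG images
#'
#' Writes the RGB image and, optionally, the single-channel label
#' raster (class codes stored as `code / 255` grey levels, see
#' [scene_label_codes]).
#'
#' @param scene a `scene` from [render_scene()].
#' @param image_path output path for the RGB PNG.
#' @param labels_path optional output path for the label PNG.
#' @return `image_path`, invisibly.
#' @export
write_scene_png <- function(scene, image_path, labels_path = NULL) {
  if (!inherits(scene, "scene")) stop_bad_arg("`scene` must be a scene object")
  png::writePNG(scene$image, image_path)
  if (!is.null(labels_path))
    png::writePNG(scene$labels / 255, labels_path)
  invisible(image_path)
}

#' Read a scene label raster written by [write_scene_png()]
#'
#' @param path label PNG path.
#' @return Integer matrix of class codes.
#' @export
read_scene_labels <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
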