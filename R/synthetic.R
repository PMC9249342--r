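#' Specification of one synthetic cell class
#'
#' Cells are rendered as filled, axis-aligned ellipses with a per-cell
#' radius, aspect jitter and colour jitter. The radius range controls which
#' COCO area band the class occupies: a class with radii in `[3, 11]` px has
#' bounding-box areas strictly below the 32x32 "small" boundary even at
#' maximal aspect jitter.
#'
#' @param name Class name.
#' @param count Integer range `c(lo, hi)`: cells per image.
#' @param radius Range `c(lo, hi)` of the base radius, pixels.
#' @param aspect_jitter Relative width/height perturbation; the two semi-axes
#'   are `r * sqrt(a)` and `r / sqrt(a)` with `a ~ U(1 - j, 1 + j)`.
#' @param color RGB triple in `[0, 1]`.
#' @param color_jitter Additive uniform colour noise half-width.
#' @param max_iou Maximum bounding-box IoU a new cell may have with any
#'   already placed cell; violating placements are retried.
#' @return A `cell_class_spec` list.
#' @export
cell_class_spec <- function(name, count, radius, aspect_jitter = 0.15,
                            color = c(0.7, 0.5, 0.5), color_jitter = 0.04,
                            max_iou = 0.25) {
  stopifnot(length(count) == 2, count[1] >= 0, count[2] >= count[1],
            length(radius) == 2, radius[1] > 0, radius[2] >= radius[1],
            aspect_jitter >= 0, aspect_jitter < 1, length(color) == 3)
  structure(list(name = name, count = count, radius = radius,
                 aspect_jitter = aspect_jitter, color = color,
                 color_jitter = color_jitter, max_iou = max_iou),
            class = "cell_class_spec")
}

#' Scene specification for the synthetic blood-smear generator
#'
#' The defaults emulate the class/size structure of blood-smear detection
#' data: a numerous medium-sized red-blood-cell-like class, one large
#' white-blood-cell-like cell per image, and a small, platelet-like class
#' whose bounding boxes all fall in the COCO "small" area band
#' (area < 32x32 px^2). Photorealism is out of scope — the loss-weighting
#' method under study depends only on box geometry, and flat-shaded ellipses
#' with distinct colours keep the three classes learnable by a tiny backbone.
#'
#' @param image_size Square image side, pixels.
#' @param classes Named-order list of [cell_class_spec()]s; list position is
#'   the COCO category id.
#' @param background RGB triple of the background.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param max_retries Placement retries before a cell is dropped.
#' @param seed Master seed; per-image seeds are derived by a counter.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 128,
                       classes = list(
                         cell_class_spec("rbc", count = c(4, 7),
                                         radius = c(16, 26),
                                         color = c(0.85, 0.5, 0.5)),
                         cell_class_spec("wbc", count = c(1, 1),
                                         radius = c(50, 60),
                                         aspect_jitter = 0.05,
                                         color = c(0.45, 0.35, 0.7),
                                         max_iou = 0.6),
                         cell_class_spec("platelet", count = c(1, 4),
                                         radius = c(3, 11),
                                         color = c(0.5, 0.2, 0.55),
                                         max_iou = 0.2)
                       ),
                       background = c(0.93, 0.89, 0.87), noise_sd = 0.02,
                       max_retries = 20, seed = 1) {
  stopifnot(image_size >= 32, all(vapply(classes, inherits, logical(1),
                                         "cell_class_spec")))
  structure(list(image_size = image_size, classes = classes,
                 background = background, noise_sd = noise_sd,
                 max_retries = max_retries, seed = as.integer(seed)),
            class = "scene_spec")
}

render_ellipse <- function(img, cx, cy, rx, ry, col) {
  h <- dim(img)[1]; w <- dim(img)[2]
  i0 <- max(1L, floor(cy - ry)); i1 <- min(h, ceiling(cy + ry))
  j0 <- max(1L, floor(cx - rx)); j1 <- min(w, ceiling(cx + rx))
  if (i1 < i0 || j1 < j0) return(img)
  ii <- i0:i1; jj <- j0:j1
  yv <- ((ii - 0.5) - cy) / ry
  xv <- ((jj - 0.5) - cx) / rx
  mask <- outer(yv^2, xv^2, "+") <= 1
  for (c in 1:3) {
    sub <- img[ii, jj, c]
    sub[mask] <- col[c]
    img[ii, jj, c] <- sub
  }
  img
}

#' Generate one synthetic blood-smear scene
#'
#' Places ellipses class by class under the per-class pairwise-IoU
#' constraint (bounded retries; a cell that cannot be placed is dropped with
#' a message), renders larger cells first so small ones stay visible, and
#' returns tight bounding boxes of the ellipses.
#'
#' @param spec A [scene_spec()].
#' @param seed Seed for this scene (defaults to the spec's master seed).
#' @return A `plb_scene`: list with `image` (`H x W x 3` array in `[0, 1]`)
#'   and `boxes` (tibble with `class`, `category_id`, box columns, `area`).
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  sz <- spec$image_size
  with_seed(seed, {
    placed <- list()
    for (ci in seq_along(spec$classes)) {
      cl <- spec$classes[[ci]]
      n <- if (cl$count[1] == cl$count[2]) cl$count[1] else
        sample(cl$count[1]:cl$count[2], 1)
      for (k in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(spec$max_retries)) {
          r <- stats::runif(1, cl$radius[1], cl$radius[2])
          a <- stats::runif(1, 1 - cl$aspect_jitter, 1 + cl$aspect_jitter)
          rx <- r * sqrt(a); ry <- r / sqrt(a)
          rmax <- max(rx, ry)
          if (2 * rmax >= sz) next
          cx <- stats::runif(1, rmax, sz - rmax)
          cy <- stats::runif(1, rmax, sz - rmax)
          box <- c(cx - rx, cy - ry, cx + rx, cy + ry)
          if (length(placed)) {
            prev <- do.call(rbind, lapply(placed, `[[`, "box"))
            if (max(box_iou(matrix(box, 1), prev)) > cl$max_iou) next
          }
          col <- pmin(pmax(cl$color + stats::runif(3, -cl$color_jitter,
                                                   cl$color_jitter), 0), 1)
          placed[[length(placed) + 1]] <- list(
            box = box, category_id = ci, class = cl$name,
            cx = cx, cy = cy, rx = rx, ry = ry, col = col
          )
          ok <- TRUE
          break
        }
        if (!ok) {
          message(sprintf("generate_scene: dropped a '%s' cell after %d retries",
                          cl$name, spec$max_retries))
        }
      }
    }
    img <- array(rep(spec$background, each = sz * sz), c(sz, sz, 3))
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(sz * sz * 3, sd = spec$noise_sd),
                         c(sz, sz, 3))
    }
    # render big-to-small so small cells are never fully occluded
    ord <- order(-vapply(placed, function(p) p$rx * p$ry, numeric(1)))
    for (p in placed[ord]) {
      img <- render_ellipse(img, p$cx, p$cy, p$rx, p$ry, p$col)
    }
    img <- pmin(pmax(img, 0), 1)
    boxes <- if (length(placed)) {
      m <- do.call(rbind, lapply(placed, `[[`, "box"))
      box_tbl(m[, 1], m[, 2], m[, 3], m[, 4],
              category_id = vapply(placed, `[[`, integer(1), "category_id"),
              class = vapply(placed, `[[`, character(1), "class")) |>
        dplyr::mutate(area = box_area(m))
    } else {
      box_tbl(numeric(0), numeric(0), numeric(0), numeric(0),
              category_id = integer(0), class = character(0),
              area = numeric(0))
    }
    structure(list(image = img, boxes = boxes, seed = seed), class = "plb_scene")
  })
}

# Per-image seed derived from the master seed by a counter; kept within the
# 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 1009 + i) %% 2147483647)
}

#' Generate a synthetic blood-smear dataset
#'
#' Renders `n_images` scenes with counter-derived per-image seeds (so a
#' dataset can be extended without reshuffling existing images) and collects
#' COCO-style annotations. When `out_dir` is given, PNG images, an
#' `annotations.json` (COCO layout, no timestamps) and a `manifest.yaml`
#' with the spec, seed and size-band census are written.
#'
#' @param spec A [scene_spec()].
#' @param n_images Number of images.
#' @param out_dir Optional output directory.
#' @return A `plb_dataset`: list with `images` (list of arrays),
#'   `annotations` (tibble: `id`, `image_id`, `category_id`, `class`, box
#'   columns, `area`, `band`), `categories` (tibble `id`, `name`),
#'   `manifest` (list incl. the size-band census), and `out_dir`.
#' @export
generate_dataset <- function(spec, n_images, out_dir = NULL) {
  scenes <- lapply(seq_len(n_images), function(i) {
    generate_scene(spec, derive_seed(spec$seed, i))
  })
  ann <- purrr::imap_dfr(scenes, function(s, i) {
    if (nrow(s$boxes) == 0) return(NULL)
    dplyr::mutate(s$boxes, image_id = i, .before = 1)
  })
  if (nrow(ann) == 0) {
    ann <- tibble::tibble(id = integer(0), image_id = integer(0),
                          x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0),
                          category_id = integer(0), class = character(0),
                          area = numeric(0), band = character(0))
  } else {
    ann <- dplyr::mutate(ann, id = dplyr::row_number(), .before = 1) |>
      dplyr::mutate(band = assign_size_band(.data$area))
  }
  categories <- tibble::tibble(
    id = seq_along(spec$classes),
    name = vapply(spec$classes, `[[`, character(1), "name")
  )
  census <- as.list(table(factor(ann$band, levels = c("small", "medium", "large"))))
  manifest <- list(
    seed = spec$seed, n_images = n_images, image_size = spec$image_size,
    census = census,
    classes = lapply(spec$classes, function(cl) {
      list(name = cl$name, count = cl$count, radius = cl$radius,
           aspect_jitter = cl$aspect_jitter, max_iou = cl$max_iou)
    })
  )
  ds <- structure(
    list(images = lapply(scenes, `[[`, "image"), annotations = ann,
         categories = categories, manifest = manifest, out_dir = out_dir),
    class = "plb_dataset"
  )
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file_names <- sprintf("img_%04d.png", seq_along(ds$images))
  for (i in seq_along(ds$images)) {
    png::writePNG(ds$images[[i]], file.path(out_dir, file_names[i]))
  }
  write_coco(ds$annotations, ds$categories,
             tibble::tibble(id = seq_along(ds$images), file_name = file_names,
                            width = ds$manifest$image_size,
                            height = ds$manifest$image_size),
             file.path(out_dir, "annotations.json"))
  yaml::write_yaml(ds$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir Directory with PNG images and `annotations.json`.
#' @return A `plb_dataset` list (images loaded into memory).
#' @export
read_dataset <- function(dir) {
  coco <- read_coco(file.path(dir, "annotations.json"))
  images <- lapply(coco$images$file_name, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  manifest_path <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else NULL
  structure(list(images = images, annotations = coco$annotations,
                 categories = coco$categories, manifest = manifest,
                 out_dir = dir),
            class = "plb_dataset")
}

#' @export
print.plb_dataset <- function(x, ...) {
  cat(sprintf("<plb_dataset> %d images, %d annotations, %d classes\n",
              length(x$images), nrow(x$annotations), nrow(x$categories)))
  print(dplyr::count(x$annotations, .data$class, .data$band))
  invisible(x)
}
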