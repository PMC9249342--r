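#' Write annotations in COCO JSON layout
#'
#' Boxes are stored as `[x, y, width, height]` (top-left corner plus size),
#' the standard COCO encoding. No timestamps are written, so identical
#' inputs yield byte-identical files.
#'
#' @param annotations Tibble with `id`, `image_id`, `category_id` and box
#'   columns.
#' @param categories Tibble with `id`, `name`.
#' @param images Tibble with `id`, `file_name`, `width`, `height`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coco <- function(annotations, categories, images, path) {
  anns <- purrr::pmap(annotations, function(id, image_id, category_id,
                                            x_min, y_min, x_max, y_max, ...) {
    list(id = id, image_id = image_id, category_id = category_id,
         bbox = c(x_min, y_min, x_max - x_min, y_max - y_min),
         area = (x_max - x_min) * (y_max - y_min), iscrowd = 0L)
  })
  obj <- list(
    images = purrr::pmap(images, function(id, file_name, width, height, ...) {
      list(id = id, file_name = file_name, width = width, height = height)
    }),
    annotations = anns,
    categories = purrr::pmap(categories, function(id, name, ...) {
      list(id = id, name = name)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style annotations
#'
#' @param path A COCO annotation JSON file.
#' @return List with tibbles `annotations` (corner-format box columns plus
#'   `area` and `band`), `categories` and `images`.
#' @export
read_coco <- function(path) {
  obj <- jsonlite::read_json(path)
  categories <- purrr::map_dfr(obj$categories, function(ct) {
    tibble::tibble(id = as.integer(ct$id), name = as.character(ct$name))
  })
  images <- purrr::map_dfr(obj$images, function(im) {
    tibble::tibble(id = as.integer(im$id), file_name = im$file_name,
                   width = as.numeric(im$width), height = as.numeric(im$height))
  })
  annotations <- purrr::map_dfr(obj$annotations, function(an) {
    b <- as.numeric(unlist(an$bbox))
    tibble::tibble(id = as.integer(an$id), image_id = as.integer(an$image_id),
                   category_id = as.integer(an$category_id),
                   x_min = b[1], y_min = b[2],
                   x_max = b[1] + b[3], y_max = b[2] + b[4])
  })
  if (nrow(annotations)) {
    annotations$class <- categories$name[match(annotations$category_id, categories$id)]
    annotations$area <- box_area(annotations)
    annotations$band <- assign_size_band(annotations$area)
  }
  list(annotations = annotations, categories = categories, images = images)
}

#' Write / read detections in COCO results layout
#'
#' @param detections Tibble with `image_id`, `category_id`, `score` and box
#'   columns.
#' @param path JSON file.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` a detections tibble.
#' @export
write_detections <- function(detections, path) {
  res <- purrr::pmap(detections, function(image_id, category_id, score,
                                          x_min, y_min, x_max, y_max, ...) {
    list(image_id = image_id, category_id = category_id,
         bbox = c(x_min, y_min, x_max - x_min, y_max - y_min), score = score)
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  purrr::map_dfr(jsonlite::read_json(path), function(d) {
    b <- as.numeric(unlist(d$bbox))
    tibble::tibble(image_id = as.integer(d$image_id),
                   category_id = as.integer(d$category_id),
                   x_min = b[1], y_min = b[2],
                   x_max = b[1] + b[3], y_max = b[2] + b[4],
                   score = as.numeric(d$score))
  })
}
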