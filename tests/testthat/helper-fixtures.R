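# Small scene/dataset fixtures built in code.

tiny_spec <- function(seed = 1, image_size = 96) {
  scene_spec(
    image_size = image_size,
    classes = list(
      cell_class_spec("rbc", count = c(2, 3), radius = c(14, 20),
                      color = c(0.85, 0.5, 0.5)),
      cell_class_spec("platelet", count = c(1, 2), radius = c(3, 8),
                      color = c(0.5, 0.2, 0.55), max_iou = 0.2)
    ),
    seed = seed
  )
}

# Every object the same square box: one class, fixed radius, no jitter.
equal_area_spec <- function(seed = 1) {
  scene_spec(
    image_size = 96,
    classes = list(
      cell_class_spec("cell", count = c(3, 3), radius = c(10, 10),
                      aspect_jitter = 0, color = c(0.6, 0.3, 0.5),
                      max_iou = 0.05)
    ),
    seed = seed
  )
}

tiny_detector_config <- function(seed = 1, ...) {
  detector_config(image_size = 96, seed = seed, ...)
}
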