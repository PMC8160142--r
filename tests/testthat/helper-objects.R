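# shared objects, built once per test run
.cache <- new.env(parent = emptyenv())

default_geom <- function() viewing_geometry()

default_profile <- function() {
  if (is.null(.cache$profile)) .cache$profile <- calibrate_profile()
  .cache$profile
}

default_field <- function(seed = 1) {
  key <- paste0("field", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- generate_field(default_profile(), 2000, seed = seed)
  }
  .cache[[key]]
}

fixture_sentences <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_fixtures(36, seed = 11)
  .cache$fx
}

cached_reference <- function(k = 1, logmar = 1.0) {
  key <- sprintf("ref%d_%.1f", k, logmar)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- render_reference(fixture_sentences()[k, ], logmar,
                                      default_geom())
  }
  .cache[[key]]
}

# a tiny synthetic rendered_text for oracle tests: a luminance block placed
# on the default screen
synthetic_reference <- function(block, origin_x, origin_y,
                                geom = default_geom()) {
  structure(
    list(block = block, origin_px = c(x = origin_x, y = origin_y),
         width_px = geom$width_px, height_px = geom$height_px,
         xheight_px = 20, target_xheight_px = 20, logmar = 1.0,
         cex = NA_real_, family = "synthetic", line_spacing = 1.5,
         condense = 1, distance_cm = geom$distance_cm,
         words = tibble::tibble(), lines = character(0),
         text = NA_character_, sentence_id = NA_integer_),
    class = "rendered_text"
  )
}
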