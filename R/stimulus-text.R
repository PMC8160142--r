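#' x-height of a print size in arcminutes
#'
#' Print size follows the acuity-letter convention used by continuous-text
#' reading charts: a letter's critical detail subtends `10^logMAR` arcmin and
#' the lowercase x-height is five critical details, so
#' `x-height = 5 * 10^logMAR` arcmin.
#'
#' @param logmar Print size in logMAR (vectorized).
#' @return x-height in arcminutes.
#' @export
#' @examples
#' xheight_arcmin(0)    # 5 arcmin
#' xheight_arcmin(1.0)  # 50 arcmin
xheight_arcmin <- function(logmar) {
  stopifnot(all(is.finite(logmar)))
  5 * 10^logmar
}

#' Target x-height in pixels for a print size
#'
#' @param logmar Print size in logMAR.
#' @param geom A [viewing_geometry()].
#' @param distance_cm Viewing distance; defaults to the nominal distance in
#'   `geom`.
#' @return x-height in (fractional) pixels.
#' @export
xheight_px <- function(logmar, geom, distance_cm = geom$distance_cm) {
  deg <- xheight_arcmin(logmar) / 60
  distance_cm * tan(deg * pi / 180) / geom$cm_per_px
}

# ---------------------------------------------------------------------------
# fixture sentences

the_wordlist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "wordlist.tsv", package = "phosread")
      if (path == "") path <- file.path("inst", "extdata", "wordlist.tsv")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Packaged elementary vocabulary
#'
#' The word list used by [make_fixtures()]: lowercase elementary-school
#' vocabulary tagged by part of speech. The real MNREAD corpus is licensed
#' and is not shipped; these fixtures emulate its printed constraints only.
#'
#' @return A tibble with columns `word`, `pos`.
#' @export
fixture_vocabulary <- function() tibble::as_tibble(the_wordlist())

# draw one clause worth of tokens from a simple grammar
sample_clause <- function(pools) {
  pick <- function(pos) sample(pools[[pos]], 1)
  toks <- c(pick("det"))
  if (stats::runif(1) < 0.5) toks <- c(toks, pick("adj"))
  toks <- c(toks, pick("noun"), pick("verb"))
  tail_kind <- sample(c("pp", "obj", "adv"), 1, prob = c(0.45, 0.35, 0.2))
  if (tail_kind == "pp") {
    toks <- c(toks, pick("prep"), pick("det"))
    if (stats::runif(1) < 0.4) toks <- c(toks, pick("adj"))
    toks <- c(toks, pick("noun"))
  } else if (tail_kind == "obj") {
    toks <- c(toks, pick("det"))
    if (stats::runif(1) < 0.4) toks <- c(toks, pick("adj"))
    toks <- c(toks, pick("noun"))
  } else {
    toks <- c(toks, pick("adv"))
  }
  toks
}

sample_sentence_words <- function(pools) {
  words <- sample_clause(pools)
  n_extra <- sample(0:2, 1, prob = c(0.25, 0.5, 0.25))
  for (k in seq_len(n_extra)) {
    words <- c(words, sample(pools$conj, 1), sample_clause(pools))
  }
  words
}

# split words into 3 lines of 18-20 characters whose joined length is 60
split_three_lines <- function(words) {
  n <- length(words)
  lens <- nchar(words)
  cum <- cumsum(lens + 1) - 1 # length of words[1..k] joined by spaces
  for (i in 1:(n - 2)) {
    l1 <- cum[i]
    if (l1 < 18 || l1 > 20) next
    for (j in (i + 1):(n - 1)) {
      l2 <- cum[j] - cum[i] - 1
      if (l2 < 18 || l2 > 20) next
      l3 <- cum[n] - cum[j] - 1
      if (l3 >= 18 && l3 <= 20) {
        return(c(paste(words[1:i], collapse = " "),
                 paste(words[(i + 1):j], collapse = " "),
                 paste(words[(j + 1):n], collapse = " ")))
      }
    }
  }
  NULL
}

#' Generate fixture sentences in the MNREAD print style
#'
#' Assembles sentences from the packaged elementary vocabulary by seeded
#' template filling (determiner/adjective/noun/verb clauses joined by simple
#' conjunctions). Every sentence has exactly 60 characters including spaces
#' and no terminal period, contains no punctuation and no capitalized proper
#' nouns, and is pre-split into three lines of 18-20 characters. Output is
#' deterministic per seed.
#'
#' @param n Number of sentences.
#' @param seed Integer RNG seed.
#' @param max_tries Retry budget per sentence.
#' @return A tibble with columns `sentence_id`, `text`, `line1`, `line2`,
#'   `line3`.
#' @export
#' @examples
#' fx <- make_fixtures(3, seed = 7)
#' nchar(fx$text)
make_fixtures <- function(n, seed = 1, max_tries = 20000L) {
  stopifnot(n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  wl <- the_wordlist()
  pools <- split(wl$word, wl$pos)
  out <- vector("list", n)
  seen <- character(0)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      words <- sample_sentence_words(pools)
      text <- paste(words, collapse = " ")
      if (nchar(text) != 60 || text %in% seen) next
      lines <- split_three_lines(words)
      if (is.null(lines)) next
      out[[k]] <- tibble::tibble(sentence_id = k, text = text,
                                 line1 = lines[1], line2 = lines[2],
                                 line3 = lines[3])
      seen <- c(seen, text)
      ok <- TRUE
      break
    }
    if (!ok) stop("fixture generation exhausted its retry budget", call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Validate a fixture sentence
#'
#' Checks the printed-sentence constraints: exactly 60 characters including
#' spaces and excluding any terminal period; lowercase letters and single
#' spaces only (no punctuation, no capitalized proper nouns); exactly three
#' lines that reconstitute the text when joined with single spaces.
#'
#' @param text The 60-character sentence.
#' @param lines Character vector of its three lines.
#' @return `TRUE` if valid, otherwise `FALSE` with a `reason` attribute.
#' @export
validate_sentence <- function(text, lines) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (length(text) != 1 || is.na(text)) return(fail("text must be one string"))
  if (nchar(text) != 60) return(fail("text must have exactly 60 characters"))
  if (grepl("[^a-z ]", text)) {
    return(fail("only lowercase letters and spaces are allowed"))
  }
  if (grepl("(^ )|( $)|(  )", text)) return(fail("malformed spacing"))
  if (length(lines) != 3) return(fail("exactly three lines required"))
  if (paste(lines, collapse = " ") != text) {
    return(fail("lines must reconstitute the text"))
  }
  TRUE
}

# ---------------------------------------------------------------------------
# rasterization

# package-local cache for font calibration measurements
.render_cache <- new.env(parent = emptyenv())

# The default face is the Hershey stroked serif built into R's graphics
# engine: a Times-like proportional serif that renders identically on every
# device. `stroke_frac` sets the pen width as a fraction of the x-height so
# stroke weight scales with print size. System font families can be passed
# instead of "hershey-serif" when an outline serif is installed.
is_hershey <- function(family) startsWith(family, "hershey")

# pen width (lwd) for a given x-height in px; cairo lwd 1 is 1/96 inch and
# the devices here run at 72 px/inch
stroke_lwd <- function(xheight_px, stroke_frac = 0.16) {
  xheight_px * stroke_frac * 96 / 72
}

text_draw <- function(x, y, s, cex, family, lwd) {
  if (is_hershey(family)) {
    graphics::text(x, y, s, col = "white", vfont = c("serif", "plain"),
                   cex = cex, adj = c(0.5, 0), lwd = lwd)
  } else {
    graphics::text(x, y, s, col = "white", family = family, cex = cex,
                   adj = c(0.5, 0))
  }
}

text_width <- function(s, cex, family) {
  if (is_hershey(family)) {
    graphics::strwidth(s, units = "user", vfont = c("serif", "plain"),
                       cex = cex)
  } else {
    graphics::strwidth(s, units = "user", cex = cex, family = family)
  }
}

# measure the ink height of a glyph rendered at a given cex, with subpixel
# precision: 0.5-crossing interpolation on the per-row intensity profile
measure_glyph_height_px <- function(glyph = "x", cex, family, lwd = 1,
                                    device_px = NULL) {
  if (is.null(device_px)) device_px <- max(128, ceiling(cex * 4))
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path), add = TRUE)
  grDevices::png(path, width = device_px, height = device_px,
                 type = "cairo", bg = "black")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, device_px), ylim = c(device_px, 0))
  text_draw(device_px / 2, device_px * 0.75, glyph, cex, family, lwd)
  grDevices::dev.off()
  img <- png::readPNG(path)
  lum <- if (length(dim(img)) == 3) img[, , 1] else img
  profile <- apply(lum, 1, max)
  above <- which(profile >= 0.5)
  if (length(above) == 0) return(0)
  top <- min(above)
  bot <- max(above)
  # interpolate the 0.5 crossings just outside the solid extent
  frac_top <- if (top > 1 && profile[top] > profile[top - 1]) {
    (profile[top] - 0.5) / (profile[top] - profile[top - 1])
  } else 0
  frac_bot <- if (bot < length(profile) && profile[bot] > profile[bot + 1]) {
    (profile[bot] - 0.5) / (profile[bot] - profile[bot + 1])
  } else 0
  (bot - top + 1) + frac_top + frac_bot
}

# find the cex whose rasterized lowercase x-height best matches target_px
calibrate_cex <- function(target_px, family = "hershey-serif",
                          stroke_frac = 0.16) {
  memo_key <- sprintf("cex_%s_%.6f_%.3f", family, target_px, stroke_frac)
  if (!is.null(.render_cache[[memo_key]])) return(.render_cache[[memo_key]])
  lwd <- if (is_hershey(family)) stroke_lwd(target_px, stroke_frac) else 1
  key <- paste0("xh1_", family)
  if (is.null(.render_cache[[key]])) {
    ref_cex <- 40
    ref_lwd <- if (is_hershey(family)) stroke_lwd(40 * 0.5, stroke_frac) else 1
    .render_cache[[key]] <- measure_glyph_height_px("x", ref_cex, family,
                                                    lwd = ref_lwd,
                                                    device_px = 2048) / ref_cex
  }
  per_cex <- .render_cache[[key]]
  cex <- target_px / per_cex
  # measured correction steps absorb size-dependent rasterization and the
  # stroke-width contribution to the ink extent
  for (k in 1:2) {
    measured <- measure_glyph_height_px("x", cex, family, lwd = lwd)
    if (measured <= 0) break
    if (abs(measured - target_px) / target_px < 0.005) break
    cex <- cex * target_px / measured
  }
  measured <- measure_glyph_height_px("x", cex, family, lwd = lwd)
  out <- list(cex = cex, measured_px = measured, lwd = lwd)
  .render_cache[[memo_key]] <- out
  out
}

#' Render a reference text stimulus
#'
#' Rasterizes a three-line sentence centered on the screen, white serif text
#' on a black background, scaled so that the lowercase x-height subtends
#' `5 * 10^logmar` arcmin at the viewing distance. Baseline-to-baseline line
#' spacing is `line_spacing` x-heights. The luminance raster is stored as a
#' cropped block around the ink (everything outside is exactly 0) together
#' with per-word tight bounding boxes from the rasterizer.
#'
#' @param sentence One row of a [make_fixtures()] table (or any list with
#'   `text`, `line1`, `line2`, `line3`).
#' @param logmar Print size in logMAR.
#' @param geom A [viewing_geometry()].
#' @param distance_cm Head-to-screen distance used for size compensation;
#'   defaults to the nominal distance.
#' @param family Font face: the default `"hershey-serif"` uses R's built-in
#'   Times-like stroked serif (device-independent); any installed outline
#'   family name may be given instead.
#' @param line_spacing Baseline-to-baseline spacing in x-height units.
#' @param stroke_frac Pen width as a fraction of x-height (Hershey faces
#'   only).
#' @param condense Horizontal advance scale. The Hershey serif's character
#'   advances are about 25% wider than Times-style metrics; the default 0.8
#'   brings line widths to Times-like proportions (about 18 x-heights for a
#'   20-character line). Set to 1 for the face's native advances.
#' @return A `rendered_text` object: luminance block in \[0, 1\], block
#'   origin on screen, measured `xheight_px`, per-word boxes, and metadata.
#' @export
render_reference <- function(sentence, logmar, geom,
                             distance_cm = geom$distance_cm,
                             family = "hershey-serif", line_spacing = 1.5,
                             stroke_frac = 0.16, condense = 0.8) {
  lines <- c(sentence$line1, sentence$line2, sentence$line3)
  ok <- validate_sentence(sentence$text, lines)
  if (!isTRUE(ok)) stop("invalid sentence: ", attr(ok, "reason"), call. = FALSE)
  stopifnot(condense > 0, condense <= 1)

  target_px <- xheight_px(logmar, geom, distance_cm)
  cal <- calibrate_cex(target_px, family, stroke_frac)
  cex <- cal$cex
  xh <- cal$measured_px
  if (abs(xh - target_px) / target_px > 0.02) {
    stop(sprintf("rasterized x-height %.2f px misses the %.2f px target by >2%%",
                 xh, target_px), call. = FALSE)
  }

  w <- geom$width_px
  h <- geom$height_px
  # draw on a wider canvas, then resample columns by `condense` so the
  # printed advances match Times-like metrics
  ww <- ceiling(w / condense) + 8L
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path), add = TRUE)
  grDevices::png(path, width = ww, height = h, type = "cairo", bg = "black")
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ww), ylim = c(h, 0))
  step <- line_spacing * target_px
  baselines <- h / 2 + target_px / 2 + c(-step, 0, step)
  widths <- vapply(lines, function(l) text_width(l, cex, family), 0)
  space_w <- text_width("m m", cex, family) - text_width("mm", cex, family)
  if (max(widths) * condense > w || baselines[1] - 2 * target_px < 0 ||
      baselines[3] + target_px > h) {
    max_feasible <- logmar + log10(min(w / (max(widths) * condense), 1))
    stop(sprintf("stimulus too large for the screen; maximum feasible size is about %.2f logMAR",
                 max_feasible), call. = FALSE)
  }
  word_rows <- list()
  for (li in 1:3) {
    x0 <- ww / 2 - widths[li] / 2
    text_draw(ww / 2, baselines[li], lines[li], cex, family, cal$lwd)
    words <- strsplit(lines[li], " ", fixed = TRUE)[[1]]
    xw <- unname(vapply(words, function(s) text_width(s, cex, family), 0))
    starts <- x0 + cumsum(c(0, utils::head(xw, -1) + space_w))
    word_rows[[li]] <- tibble::tibble(
      line = li, word = words,
      x0 = starts, x1 = starts + xw,
      y0 = baselines[li] - 1.8 * target_px,
      y1 = baselines[li] + 0.7 * target_px,
      baseline = baselines[li]
    )
  }
  grDevices::dev.off()
  img <- png::readPNG(path)
  lum <- if (length(dim(img)) == 3) img[, , 1] else img
  words <- dplyr::bind_rows(word_rows)

  if (condense < 1) {
    lum <- condense_columns(lum, condense, ww, w)
    # wide-canvas x maps to screen x about the common center
    words$x0 <- (words$x0 - ww / 2) * condense + w / 2
    words$x1 <- (words$x1 - ww / 2) * condense + w / 2
  }

  ink_rows <- which(apply(lum > 0, 1, any))
  ink_cols <- which(apply(lum > 0, 2, any))
  if (length(ink_rows) == 0) stop("rendered text produced no ink", call. = FALSE)
  r0 <- max(1L, min(ink_rows) - 2L); r1 <- min(h, max(ink_rows) + 2L)
  c0 <- max(1L, min(ink_cols) - 2L); c1 <- min(w, max(ink_cols) + 2L)
  block <- lum[r0:r1, c0:c1, drop = FALSE]

  words <- tighten_word_boxes(words, block, c0 - 1L, r0 - 1L)

  structure(
    list(block = block,
         origin_px = c(x = c0 - 1L, y = r0 - 1L), # top-left corner, 0-based
         width_px = w, height_px = h,
         xheight_px = xh, target_xheight_px = target_px,
         logmar = logmar, cex = cex, family = family,
         line_spacing = line_spacing, condense = condense,
         distance_cm = distance_cm,
         words = words, lines = lines, text = sentence$text,
         sentence_id = if (!is.null(sentence$sentence_id)) sentence$sentence_id else NA_integer_),
    class = "rendered_text"
  )
}

# linear column resampling of a luminance raster from a wide canvas (ww
# columns) onto the screen width (w columns), preserving the center column
condense_columns <- function(lum, condense, ww, w) {
  out <- matrix(0, nrow = nrow(lum), ncol = w)
  # source pixel-center coordinate for each destination column center
  u <- (seq_len(w) - 0.5 - w / 2) / condense + ww / 2
  j0 <- floor(u - 0.5) + 1L
  frac <- (u - 0.5) - (j0 - 1L)
  ok <- j0 >= 1L & j0 + 1L <= ww
  cols <- which(ok)
  if (length(cols) > 0) {
    out[, cols] <- lum[, j0[cols], drop = FALSE] * rep(1 - frac[cols], each = nrow(lum)) +
      lum[, j0[cols] + 1L, drop = FALSE] * rep(frac[cols], each = nrow(lum))
  }
  out
}

# shrink nominal word boxes to the tight ink bounding box inside them
tighten_word_boxes <- function(words, block, off_x, off_y) {
  nr <- nrow(block); nc <- ncol(block)
  for (i in seq_len(nrow(words))) {
    cs <- max(1L, floor(words$x0[i] - off_x)) : min(nc, ceiling(words$x1[i] - off_x))
    rs <- max(1L, floor(words$y0[i] - off_y)) : min(nr, ceiling(words$y1[i] - off_y))
    sub <- block[rs, cs, drop = FALSE]
    ink_r <- which(apply(sub > 0, 1, any))
    ink_c <- which(apply(sub > 0, 2, any))
    if (length(ink_r) > 0) {
      words$x0[i] <- off_x + cs[min(ink_c)] - 1
      words$x1[i] <- off_x + cs[max(ink_c)]
      words$y0[i] <- off_y + rs[min(ink_r)] - 1
      words$y1[i] <- off_y + rs[max(ink_r)]
    }
  }
  words
}

#' @export
print.rendered_text <- function(x, ...) {
  cat(sprintf("<rendered_text> %.1f logMAR, x-height %.1f px, block %d x %d px at (%d, %d)\n",
              x$logmar, x$xheight_px, ncol(x$block), nrow(x$block),
              x$origin_px[["x"]], x$origin_px[["y"]]))
  cat(" ", x$text, "\n")
  invisible(x)
}

#' Full-screen luminance raster of a rendered text
#'
#' @param ref A [render_reference()] result.
#' @return A `height_px x width_px` matrix in \[0, 1\].
#' @export
as_luminance_matrix <- function(ref) {
  stopifnot(inherits(ref, "rendered_text"))
  out <- matrix(0, nrow = ref$height_px, ncol = ref$width_px)
  r0 <- ref$origin_px[["y"]]
  c0 <- ref$origin_px[["x"]]
  out[r0 + seq_len(nrow(ref$block)), c0 + seq_len(ncol(ref$block))] <- ref$block
  out
}

# luminance lookup for (possibly off-screen / off-block) integer pixel
# indices: col i (x), row j (y), both 1-based on the extended grid
ref_luminance_at <- function(ref, cols, rows) {
  out <- matrix(0, nrow = length(rows), ncol = length(cols))
  r0 <- ref$origin_px[["y"]]
  c0 <- ref$origin_px[["x"]]
  rr <- rows - r0
  cc <- cols - c0
  rsel <- which(rr >= 1 & rr <= nrow(ref$block))
  csel <- which(cc >= 1 & cc <= ncol(ref$block))
  if (length(rsel) > 0 && length(csel) > 0) {
    out[rsel, csel] <- ref$block[rr[rsel], cc[csel], drop = FALSE]
  }
  out
}

# a uniform synthetic reference (testing aid): constant luminance everywhere
uniform_reference <- function(level, geom) {
  structure(
    list(block = matrix(level, nrow = geom$height_px, ncol = geom$width_px),
         origin_px = c(x = 0L, y = 0L),
         width_px = geom$width_px, height_px = geom$height_px,
         xheight_px = NA_real_, target_xheight_px = NA_real_,
         logmar = NA_real_, cex = NA_real_, family = NA_character_,
         line_spacing = NA_real_, distance_cm = geom$distance_cm,
         words = tibble::tibble(), lines = character(0),
         text = NA_character_, sentence_id = NA_integer_),
    class = "rendered_text"
  )
}

#' Export a rendered text as a PNG file
#'
#' @param ref A [render_reference()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_png <- function(ref, path) {
  png::writePNG(as_luminance_matrix(ref), path)
  invisible(path)
}
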