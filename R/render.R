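#' Render an item to SVG
#'
#' Three modes: `"stem"` draws the 3x3 matrix with the ninth cell empty (as
#' administered), `"full"` includes the solution in the ninth cell, and
#' `"response_panel"` draws all 20 construction elements as separate
#' selectable `<g>` groups (the palette the respondent clicks). Output is a
#' single SVG 1.1 document as a character string, byte-deterministic for a
#' given item.
#'
#' Geometry: 600x600 canvas for the matrix (200-px cells, 4-px borders),
#' 1000x200 for the response panel (10x2 grid of 100-px tiles). Elements are
#' drawn in black; selection highlighting is an interaction concern and is
#' not part of the static export.
#'
#' @param item a `matrix_item`
#' @param mode `"stem"`, `"full"`, or `"response_panel"`
#' @param path optional file path; when given the SVG is also written there
#' @return SVG document as a length-1 character vector (invisibly when
#'   `path` is given)
#' @export
render_svg <- function(item, mode = c("stem", "full", "response_panel"),
                       path = NULL) {
  stopifnot(inherits(item, "matrix_item"))
  if (length(mode) != 1L || !mode %in% c("stem", "full", "response_panel")) {
    stop_config("unknown render mode; use stem, full, or response_panel")
  }
  svg <- if (mode == "response_panel") render_panel_svg(item)
         else render_matrix_svg(item, include_solution = mode == "full")
  if (!is.null(path)) {
    writeLines(svg, path, useBytes = TRUE)
    return(invisible(svg))
  }
  svg
}

fmt <- function(x) sprintf("%.2f", x)

# Map unit-cell coordinates into a canvas cell with a margin.
cell_transform <- function(coords, x0, y0, size) {
  cbind(x0 + coords[, 1L] * size, y0 + coords[, 2L] * size,
        deparse.level = 0)
}

primitive_svg <- function(prim, x0, y0, size, stroke_width) {
  co <- cell_transform(prim$coords, x0, y0, size)
  pts <- paste(fmt(co[, 1L]), fmt(co[, 2L]), sep = ",", collapse = " ")
  sw <- fmt(stroke_width)
  switch(prim$kind,
    segment = sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s" stroke-linecap="round"/>',
      fmt(co[1, 1]), fmt(co[1, 2]), fmt(co[2, 1]), fmt(co[2, 2]), sw),
    polyline = sprintf(
      '<polyline points="%s" fill="none" stroke="black" stroke-width="%s"/>',
      pts, sw),
    polygon = sprintf(
      '<polygon points="%s" fill="black" stroke="none"/>', pts),
    arc = arc_path_svg(co, sw),
    stop_config(sprintf("unknown primitive kind '%s'", prim$kind))
  )
}

# Arc stored as start / mid / end points; recover the circle through them.
arc_path_svg <- function(co, sw) {
  p1 <- co[1, ]; p2 <- co[2, ]; p3 <- co[3, ]
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
            p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-9) {  # degenerate: draw as polyline
    pts <- paste(fmt(co[, 1]), fmt(co[, 2]), sep = ",", collapse = " ")
    return(sprintf(
      '<polyline points="%s" fill="none" stroke="black" stroke-width="%s"/>',
      pts, sw))
  }
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  cx <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) +
         s3 * (p1[2] - p2[2])) / d
  cy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) +
         s3 * (p2[1] - p1[1])) / d
  r <- sqrt((p1[1] - cx)^2 + (p1[2] - cy)^2)
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p2[2] - p1[2]) * (p3[1] - p1[1])
  sweep <- if (cross > 0) 1L else 0L
  sprintf(
    '<path d="M %s %s A %s %s 0 0 %d %s %s" fill="none" stroke="black" stroke-width="%s"/>',
    fmt(p1[1]), fmt(p1[2]), fmt(r), fmt(r), sweep, fmt(p3[1]), fmt(p3[2]),
    sw)
}

element_group_svg <- function(element_id, x0, y0, size, stroke_width,
                              group_class = "glyph") {
  g <- glyph_elements()[[element_id + 1L]]
  body <- vapply(g$geometry, primitive_svg, character(1), x0 = x0, y0 = y0,
                 size = size, stroke_width = stroke_width)
  sprintf('<g class="%s" data-element="%d">\n%s\n</g>', group_class,
          element_id, paste(body, collapse = "\n"))
}

render_matrix_svg <- function(item, include_solution) {
  canvas <- 600; cell <- 200; border <- 4; inset <- 14
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            canvas, canvas, canvas, canvas),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>',
            canvas, canvas)
  )
  for (idx in 1:9) {
    row <- (idx - 1L) %/% 3L
    col <- (idx - 1L) %% 3L
    x0 <- col * cell; y0 <- row * cell
    content <- if (idx == 9L && !include_solution) integer(0)
               else item$cells[[idx]]
    inner <- vapply(content, element_group_svg, character(1),
                    x0 = x0 + inset, y0 = y0 + inset,
                    size = cell - 2 * inset, stroke_width = 6)
    lines <- c(lines,
      sprintf('<g id="cell-%d">', idx),
      sprintf('<rect x="%s" y="%s" width="%d" height="%d" fill="none" stroke="black" stroke-width="%d"/>',
              fmt(x0 + border / 2), fmt(y0 + border / 2), cell - border,
              cell - border, border),
      inner,
      '</g>')
  }
  lines <- c(lines, '</svg>')
  paste(lines, collapse = "\n")
}

render_panel_svg <- function(item) {
  tile <- 100; ncol <- 10; nrow <- 2; inset <- 8
  w <- tile * ncol; h <- tile * nrow
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="white"/>', w, h)
  )
  for (id in 0:(N_ELEMENTS - 1L)) {
    row <- id %/% ncol
    col <- id %% ncol
    x0 <- col * tile; y0 <- row * tile
    lines <- c(lines,
      sprintf('<g id="element-%d" class="construction-element">', id),
      sprintf('<rect x="%s" y="%s" width="%d" height="%d" fill="none" stroke="black" stroke-width="2"/>',
              fmt(x0 + 1), fmt(y0 + 1), tile - 2, tile - 2),
      element_group_svg(id, x0 + inset, y0 + inset, tile - 2 * inset,
                        stroke_width = 3),
      '</g>')
  }
  lines <- c(lines, '</svg>')
  paste(lines, collapse = "\n")
}
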