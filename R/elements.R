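#' Construction-element taxonomy
#'
#' The response format of the bank is construction based: respondents build
#' the missing ninth cell of a 3x3 matrix by selecting from a fixed palette
#' of 20 geometric construction elements. The palette is organised as 5
#' element families, each closed under 90-degree rotation: the four members
#' of a family ("orbit positions" 0-3) are successive 90-degree clockwise
#' rotations of one base glyph about the cell centre (0.5, 0.5). This
#' structure is what makes the rotation construction rule well defined: one
#' rotation step maps orbit k to orbit (k + 1) mod 4 within the same family.
#'
#' Families (base glyph drawn in the top-left region of the unit cell):
#' \describe{
#'   \item{0 corner square}{small filled square in a corner}
#'   \item{1 edge bar}{rectangle hugging one cell edge}
#'   \item{2 diagonal stroke}{short oblique segment in one quadrant}
#'   \item{3 quarter arc}{quarter-circle arc anchored at one corner}
#'   \item{4 inner dot}{small diamond between centre and one edge}
#' }
#'
#' Element ids are `family_id * 4 + orbit_index`, a bijection onto 0..19.
#'
#' @return A list of 20 elements. Each element is a list with fields
#'   `element_id`, `family_id`, `orbit_index`, `label`, and `geometry`
#'   (a list of drawing primitives; each primitive has `kind` in
#'   `c("segment", "polyline", "polygon", "arc")` and `coords`, an n x 2
#'   matrix of unit-cell coordinates; arcs store start / mid / end points).
#' @examples
#' glyphs <- glyph_elements()
#' length(glyphs)            # 20
#' glyphs[[1]]$family_id     # 0
#' @export
glyph_elements <- function() {
  .glyph_cache()
}

#' @rdname glyph_elements
#' @return `element_table()` returns the id map as a data.frame with columns
#'   `element_id`, `family_id`, `orbit_index`, `family_name`.
#' @export
element_table <- function() {
  g <- glyph_elements()
  data.frame(
    element_id = vapply(g, `[[`, integer(1), "element_id"),
    family_id = vapply(g, `[[`, integer(1), "family_id"),
    orbit_index = vapply(g, `[[`, integer(1), "orbit_index"),
    family_name = vapply(g, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  )
}

N_FAMILIES <- 5L
ORBIT_SIZE <- 4L
N_ELEMENTS <- 20L

family_names <- c("corner_square", "edge_bar", "diagonal_stroke",
                  "quarter_arc", "inner_dot")

#' Elements of one family
#' @param family_id integer 0-4
#' @return integer vector of the family's four element ids (orbit order)
#' @export
family_elements <- function(family_id) {
  stopifnot(family_id %in% 0:(N_FAMILIES - 1L))
  as.integer(family_id) * ORBIT_SIZE + 0:(ORBIT_SIZE - 1L)
}

#' Family of an element
#' @param element_id integer vector of element ids (0-19)
#' @return integer vector of family ids
#' @export
element_family <- function(element_id) {
  stopifnot(all(element_id %in% 0:(N_ELEMENTS - 1L)))
  as.integer(element_id) %/% ORBIT_SIZE
}

#' One rotation-orbit step
#'
#' Maps each element to the next (clockwise) or previous (counter-clockwise)
#' member of its family's rotation cycle.
#'
#' @param element_id integer vector of element ids
#' @param direction `"CW"` or `"CCW"`
#' @return integer vector of stepped element ids, sorted
#' @export
orbit_step <- function(element_id, direction = c("CW", "CCW")) {
  direction <- match.arg(direction)
  if (length(element_id) == 0L) return(integer(0))
  stopifnot(all(element_id %in% 0:(N_ELEMENTS - 1L)))
  fam <- as.integer(element_id) %/% ORBIT_SIZE
  orb <- as.integer(element_id) %% ORBIT_SIZE
  step <- if (direction == "CW") 1L else -1L
  sort(fam * ORBIT_SIZE + (orb + step) %% ORBIT_SIZE)
}

# 90-degree clockwise rotation about the cell centre, exact in rationals:
# (x, y) -> (y, 1 - x). Applied to rows of an n x 2 coordinate matrix.
rot90cw_coords <- function(coords) {
  cbind(coords[, 2L], 1 - coords[, 1L], deparse.level = 0)
}

rotate_geometry <- function(geometry, k) {
  k <- k %% 4L
  if (k == 0L) return(geometry)
  lapply(geometry, function(prim) {
    co <- prim$coords
    for (i in seq_len(k)) co <- rot90cw_coords(co)
    list(kind = prim$kind, coords = co)
  })
}

# Base (orbit 0) glyph geometry per family, unit-cell frame [0,1]^2.
base_geometries <- function() {
  sq <- function(x0, y0, x1, y1) {
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
  }
  list(
    # corner square, top-left corner
    list(list(kind = "polygon", coords = sq(0.08, 0.08, 0.30, 0.30))),
    # edge bar along the top edge
    list(list(kind = "polygon", coords = sq(0.35, 0.04, 0.65, 0.12))),
    # diagonal stroke in the top-left quadrant
    list(list(kind = "segment",
              coords = matrix(c(0.14, 0.40, 0.40, 0.14), ncol = 2,
                              byrow = TRUE))),
    # quarter arc about the top-left corner, radius 0.55
    list(list(kind = "arc",
              coords = matrix(c(0.55, 0.00,
                                0.55 / sqrt(2), 0.55 / sqrt(2),
                                0.00, 0.55), ncol = 2, byrow = TRUE))),
    # inner diamond just above the centre
    list(list(kind = "polygon",
              coords = matrix(c(0.50, 0.20, 0.56, 0.27, 0.50, 0.34,
                                0.44, 0.27), ncol = 2, byrow = TRUE)))
  )
}

.glyph_env <- new.env(parent = emptyenv())

.glyph_cache <- function() {
  if (!is.null(.glyph_env$glyphs)) return(.glyph_env$glyphs)
  bases <- base_geometries()
  glyphs <- vector("list", N_ELEMENTS)
  for (fam in 0:(N_FAMILIES - 1L)) {
    for (orb in 0:(ORBIT_SIZE - 1L)) {
      id <- fam * ORBIT_SIZE + orb
      glyphs[[id + 1L]] <- list(
        element_id = id,
        family_id = fam,
        orbit_index = orb,
        label = family_names[fam + 1L],
        geometry = rotate_geometry(bases[[fam + 1L]], orb)
      )
    }
  }
  .glyph_env$glyphs <- glyphs
  glyphs
}
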