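# Topology diagrams as standalone SVG documents: a linear 1D view (glyphs +
# contact arcs), an SSE-level contact map, and a 2D cartoon graph. All three
# renderers are pure functions of their inputs: identical calls produce
# byte-identical SVG (deterministic layout, no timestamps).

#' Default contact-class palette
#'
#' One color per contact class: SSE-type pair (HH, HE, EE) crossed with
#' orientation (P, A).
#'
#' @return named character vector of six colors.
#' @export
default_palette <- function() {
  c("HH.P" = "#1f77b4", "HH.A" = "#aec7e8",
    "HE.P" = "#2ca02c", "HE.A" = "#98df8a",
    "EE.P" = "#d62728", "EE.A" = "#ff9896")
}

# N-to-C chain gradient: red -> green -> blue, sampled at t in [0, 1].
chain_gradient <- function(t) {
  m <- grDevices::colorRamp(c("red", "green", "blue"))(pmax(0, pmin(1, t)))
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

contact_class <- function(composition, i, j, orientation) {
  ty <- sort(c(substr(composition, i, i), substr(composition, j, j)),
             decreasing = TRUE)   # "H" before "E" -> HH, HE, EE
  paste0(paste(ty, collapse = ""), ".", orientation)
}

svg_doc <- function(width, height, body) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n',
                 width, height, width, height),
         paste(body, collapse = "\n"),
         "\n</svg>\n")
}

# Strand up/down assignment: within each connected component of the
# strand-strand contact graph the lowest-index strand points up and the
# others follow by composing P (same way) / A (flipped) labels along a
# breadth-first traversal; strands without strand contacts point up.
strand_directions <- function(t) {
  comp <- t$composition
  n <- nchar(comp)
  is_e <- strsplit(comp, "")[[1]] == "E"
  up <- rep(TRUE, n)
  co <- t$contacts
  ee <- co[is_e[co$i] & is_e[co$j], , drop = FALSE]
  if (nrow(ee) == 0) return(up)
  sign <- rep(NA_integer_, n)
  adj <- function(k) {
    rows <- which(ee$i == k | ee$j == k)
    lapply(rows, function(r) {
      other <- if (ee$i[r] == k) ee$j[r] else ee$i[r]
      list(other = other, flip = ee$orientation[r] == "A")
    })
  }
  for (root in which(is_e)) {
    if (!is.na(sign[root])) next
    sign[root] <- 1L
    queue <- root
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      for (nb in adj(k)) {
        if (!is.na(sign[nb$other])) next
        sign[nb$other] <- if (nb$flip) -sign[k] else sign[k]
        queue <- c(queue, nb$other)
      }
    }
  }
  up[!is.na(sign)] <- sign[!is.na(sign)] > 0
  up
}

#' Render the linear topology diagram
#'
#' SSE glyphs laid out left to right in sequence order: helices as
#' rectangles whose width scales with residue count, strands as triangles
#' (up for the reference orientation of their sheet component, down for
#' strands antiparallel to it). Glyph fill follows the N-to-C chain gradient
#' (red to green to blue) sampled at the SSE midpoint; straight baseline
#' segments join consecutive glyphs; each spatial contact is drawn as an arc
#' above the baseline colored by its contact class.
#'
#' @param t a `Topology` with `sse_lengths` set.
#' @param palette named color vector covering the six contact classes.
#' @param unit_width horizontal pixels per residue.
#' @param glyph_height glyph height in pixels.
#' @return SVG document as a single character string.
#' @export
render_linear <- function(t, palette = default_palette(), unit_width = 3,
                          glyph_height = 26) {
  stopifnot(inherits(t, "Topology"))
  if (is.null(t$sse_lengths))
    stop("linear rendering requires sse_lengths on the topology")
  comp <- strsplit(t$composition, "")[[1]]
  n <- length(comp)
  len <- t$sse_lengths
  gap <- 14; margin <- 20
  tri_w <- 16
  widths <- ifelse(comp == "H", pmax(unit_width * len, unit_width), tri_w)
  x0 <- margin + c(0, cumsum(widths + gap))[seq_len(n)]
  xc <- x0 + widths / 2
  total <- sum(len)
  mid <- (cumsum(len) - len / 2) / total
  fill <- chain_gradient(mid)
  up <- strand_directions(t)
  base_y <- 150; half <- glyph_height / 2
  body <- character(0)
  # contact arcs above the baseline
  co <- t$contacts
  for (r in seq_len(nrow(co))) {
    i <- co$i[r]; j <- co$j[r]
    cls <- contact_class(t$composition, i, j, co$orientation[r])
    rx <- (xc[j] - xc[i]) / 2
    ry <- min(90, 18 + rx / 2)
    body <- c(body, sprintf(
      '<path class="contact-arc" d="M %.1f %.1f A %.1f %.1f 0 0 1 %.1f %.1f" fill="none" stroke="%s" stroke-width="2"/>',
      xc[i], base_y - half, rx, ry, xc[j], base_y - half,
      unname(palette[cls])))
  }
  # baseline connectors
  if (n > 1) for (k in seq_len(n - 1))
    body <- c(body, sprintf(
      '<line class="baseline" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333" stroke-width="1.5"/>',
      x0[k] + widths[k], base_y, x0[k + 1], base_y))
  # glyphs
  for (k in seq_len(n)) {
    if (comp[k] == "H") {
      body <- c(body, sprintf(
        '<rect class="helix" x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="%s" stroke="#222"/>',
        x0[k], base_y - half, widths[k], glyph_height, fill[k]))
    } else {
      ys <- if (up[k]) c(base_y + half, base_y + half, base_y - half)
      else c(base_y - half, base_y - half, base_y + half)
      body <- c(body, sprintf(
        '<polygon class="strand strand-%s" points="%.1f,%.1f %.1f,%.1f %.1f,%.1f" fill="%s" stroke="#222"/>',
        if (up[k]) "up" else "down",
        x0[k], ys[1], x0[k] + widths[k], ys[2], xc[k], ys[3], fill[k]))
    }
    body <- c(body, sprintf(
      '<text class="sse-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%d%s</text>',
      xc[k], base_y + half + 14, k, comp[k]))
  }
  w <- ceiling(margin * 2 + sum(widths) + gap * (n - 1))
  svg_doc(w, 200, body)
}

#' Render the SSE contact map
#'
#' An n x n grid; cells (i, j) and (j, i) are filled with the contact-class
#' color when SSEs i and j are in spatial contact, the diagonal is neutral,
#' and axis labels give SSE index and type.
#'
#' @param t a `Topology`.
#' @param palette named color vector covering the six contact classes.
#' @param cell cell size in pixels.
#' @return SVG document as a character string.
#' @export
render_contact_map <- function(t, palette = default_palette(), cell = 22) {
  stopifnot(inherits(t, "Topology"))
  comp <- strsplit(t$composition, "")[[1]]
  n <- length(comp)
  margin <- 28
  body <- character(0)
  co <- t$contacts
  key <- paste(co$i, co$j)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- margin + (j - 1) * cell; y <- margin + (i - 1) * cell
    if (i == j) {
      fill <- "#d8d8d8"; cls <- "diag-cell"
    } else {
      r <- match(paste(min(i, j), max(i, j)), key)
      if (!is.na(r)) {
        fill <- unname(palette[contact_class(t$composition, min(i, j),
                                             max(i, j), co$orientation[r])])
        cls <- "contact-cell"
      } else {
        fill <- "#ffffff"; cls <- "empty-cell"
      }
    }
    body <- c(body, sprintf(
      '<rect class="%s" x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#bbb"/>',
      cls, x, y, cell, cell, fill))
  }
  for (k in seq_len(n)) {
    lab <- sprintf("%d%s", k, comp[k])
    body <- c(body, sprintf(
      '<text class="axis-label" x="%d" y="%d" font-size="9" text-anchor="middle">%s</text>',
      margin + (k - 1) * cell + cell %/% 2, margin - 8, lab))
    body <- c(body, sprintf(
      '<text class="axis-label" x="%d" y="%d" font-size="9" text-anchor="end">%s</text>',
      margin - 6, margin + (k - 1) * cell + cell %/% 2 + 3, lab))
  }
  size <- margin * 2 + n * cell
  svg_doc(size, size, body)
}

#' Render the 2D cartoon topology graph
#'
#' One node per SSE (circle for helices, triangle for strands) on a
#' deterministic circular layout; solid black edges link sequence-adjacent
#' SSEs and red dashed edges mark spatial contacts.
#'
#' @param t a `Topology`.
#' @param radius layout circle radius in pixels.
#' @return SVG document as a character string.
#' @export
render_cartoon <- function(t, radius = 90) {
  stopifnot(inherits(t, "Topology"))
  comp <- strsplit(t$composition, "")[[1]]
  n <- length(comp)
  size <- 2 * (radius + 40)
  cx <- size / 2; cy <- size / 2
  ang <- 2 * pi * (seq_len(n) - 1) / n - pi / 2
  px <- cx + radius * cos(ang); py <- cy + radius * sin(ang)
  body <- character(0)
  if (n > 1) for (k in seq_len(n - 1))
    body <- c(body, sprintf(
      '<line class="sequence-edge" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#000" stroke-width="1.5"/>',
      px[k], py[k], px[k + 1], py[k + 1]))
  co <- t$contacts
  for (r in seq_len(nrow(co)))
    body <- c(body, sprintf(
      '<line class="contact-edge" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#d62728" stroke-width="1.5" stroke-dasharray="5,4"/>',
      px[co$i[r]], py[co$i[r]], px[co$j[r]], py[co$j[r]]))
  for (k in seq_len(n)) {
    if (comp[k] == "H") {
      body <- c(body, sprintf(
        '<circle class="node node-helix" cx="%.1f" cy="%.1f" r="11" fill="#ffd" stroke="#222"/>',
        px[k], py[k]))
    } else {
      body <- c(body, sprintf(
        '<polygon class="node node-strand" points="%.1f,%.1f %.1f,%.1f %.1f,%.1f" fill="#dfd" stroke="#222"/>',
        px[k] - 11, py[k] + 9, px[k] + 11, py[k] + 9, px[k], py[k] - 11))
    }
    body <- c(body, sprintf(
      '<text class="node-label" x="%.1f" y="%.1f" font-size="9" text-anchor="middle">%d%s</text>',
      px[k], py[k] + 3, k, comp[k]))
  }
  svg_doc(size, size, body)
}

#' Render all three topology views to files
#'
#' Writes `<stem>.linear.svg`, `<stem>.map.svg` and `<stem>.cartoon.svg`.
#'
#' @param t a `Topology` (with `sse_lengths` for the linear view).
#' @param stem output path stem.
#' @param palette contact-class palette.
#' @return character vector of the three paths, invisibly.
#' @export
render_all <- function(t, stem, palette = default_palette()) {
  paths <- paste0(stem, c(".linear.svg", ".map.svg", ".cartoon.svg"))
  writeLines(render_linear(t, palette), paths[1])
  writeLines(render_contact_map(t, palette), paths[2])
  writeLines(render_cartoon(t), paths[3])
  invisible(paths)
}
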