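# Static heatmap rendering. Features are drawn as rows and samples as
# columns (the display transpose of the internal samples x features
# convention). Output is composed directly by the package — PNG rasters
# via png::writePNG, SVG and HTML as text — so a fixed experiment and
# spec always produce byte-identical files, independent of any graphics
# device or font stack.

#' Create a heatmap specification
#'
#' @param sampleBarFields sample-metadata columns drawn as categorical
#'   color tracks above the heatmap (one track per field).
#' @param featureBarField optional feature-metadata column drawn as a
#'   color track right of the heatmap.
#' @param colorScale "log" (default; cells colored by
#'   \code{log2(x + logCutoff)}, so zeros sit at the colormap minimum)
#'   or "linear".
#' @param logCutoff positive offset for the log display scale.
#' @param colormap an \code{hcl.colors} palette name (perceptually
#'   uniform "Viridis" by default).
#' @return a validated \code{\linkS4class{HeatmapSpec}}.
#' @export
heatmapSpec <- function(sampleBarFields = character(0),
                        featureBarField = NULL, colorScale = "log",
                        logCutoff = 1, colormap = "Viridis") {
  methods::new("HeatmapSpec",
    sampleBarFields = as.character(sampleBarFields),
    featureBarField = if (is.null(featureBarField)) character(0)
                      else as.character(featureBarField),
    colorScale = colorScale, logCutoff = logCutoff, colormap = colormap)
}

# Stable category -> hex color via a string hash into a fixed
# qualitative palette; the assignment never depends on which other
# categories are present (hash collisions share a color).
.barPalette <- function() grDevices::hcl.colors(64, "Dynamic")

.categoryColor <- function(category) {
  pal <- .barPalette()
  vapply(as.character(category), function(s) {
    if (is.na(s) || !nzchar(s)) return("#FFFFFF")
    pal[.stringHash(s, length(pal))]
  }, "", USE.NAMES = FALSE)
}

.checkSpecFields <- function(exp, spec) {
  missS <- setdiff(spec@sampleBarFields, names(sampleData(exp)))
  if (length(missS))
    .stopInvalid("sample bar field(s) not in sample metadata: %s",
                 paste(missS, collapse = ", "))
  if (length(spec@featureBarField) &&
      !spec@featureBarField %in% names(featureData(exp)))
    .stopInvalid("feature bar field '%s' not in feature metadata",
                 spec@featureBarField)
}

# Shared view model: cell colors (features x samples, display
# orientation) plus bar tracks with legends.
.heatmapView <- function(exp, spec) {
  if (nSamples(exp) == 0 || nFeatures(exp) == 0)
    .stopInvalid("cannot render an empty experiment")
  methods::validObject(spec)
  .checkSpecFields(exp, spec)
  m <- .denseData(exp)
  v <- if (spec@colorScale == "log") log2(pmax(m, 0) + spec@logCutoff) else m
  rng <- range(v)
  u <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
       else matrix(0.5, nrow(v), ncol(v))
  pal <- grDevices::hcl.colors(256, spec@colormap)
  colIdx <- matrix(pal[pmin(256L, 1L + as.integer(u * 255))],
                   nrow(v), ncol(v))
  cells <- t(colIdx)                   # features x samples for display
  sampleBars <- lapply(spec@sampleBarFields, function(f) {
    vals <- as.character(sampleData(exp)[[f]])
    list(field = f, values = vals, colors = .categoryColor(vals))
  })
  featureBar <- if (length(spec@featureBarField)) {
    vals <- as.character(featureData(exp)[[spec@featureBarField]])
    list(field = spec@featureBarField, values = vals,
         colors = .categoryColor(vals))
  } else NULL
  list(cells = cells, sampleBars = sampleBars, featureBar = featureBar,
       featureIds = featureIds(exp), sampleIds = sampleIds(exp))
}

.hex2rgb <- function(hex) t(grDevices::col2rgb(hex)) / 255

.renderPNG <- function(view, file) {
  nf <- nrow(view$cells); ns <- ncol(view$cells)
  cs <- max(1L, min(16L, 800L %/% max(nf, ns)))  # pixels per cell
  nBars <- length(view$sampleBars)
  hasFBar <- !is.null(view$featureBar)
  gap <- 1L
  h <- nBars * (cs + gap) + nf * cs
  w <- ns * cs + if (hasFBar) gap + cs else 0L
  img <- array(1, dim = c(h, w, 3))
  put <- function(img, r0, c0, colorMatRGB, cellH, cellW) {
    # colorMatRGB: n x m x 3; paint each logical cell as cellH x cellW
    for (ch in 1:3) {
      big <- matrix(colorMatRGB[, , ch], dim(colorMatRGB)[1], dim(colorMatRGB)[2])
      big <- big[rep(seq_len(nrow(big)), each = cellH),
                 rep(seq_len(ncol(big)), each = cellW), drop = FALSE]
      img[r0 + seq_len(nrow(big)) - 1L, c0 + seq_len(ncol(big)) - 1L, ch] <- big
    }
    img
  }
  toRGBArr <- function(hexMat) {
    rgb <- .hex2rgb(as.vector(hexMat))
    array(rgb, dim = c(nrow(hexMat), ncol(hexMat), 3))
  }
  r <- 1L
  for (bar in view$sampleBars) {
    img <- put(img, r, 1L, toRGBArr(matrix(bar$colors, 1)), cs, cs)
    r <- r + cs + gap
  }
  img <- put(img, r, 1L, toRGBArr(view$cells), cs, cs)
  if (hasFBar)
    img <- put(img, r, ns * cs + gap + 1L,
               toRGBArr(matrix(view$featureBar$colors, ncol = 1)), cs, cs)
  png::writePNG(img, file)
  invisible(file)
}

.svgEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

.renderSVGString <- function(view) {
  nf <- nrow(view$cells); ns <- ncol(view$cells)
  cs <- 12
  nBars <- length(view$sampleBars)
  hasFBar <- !is.null(view$featureBar)
  labelW <- 120
  top <- nBars * (cs + 2)
  legendItems <- unique(unlist(c(
    lapply(view$sampleBars, function(b) b$values),
    if (hasFBar) view$featureBar$values), use.names = FALSE))
  legendItems <- legendItems[!is.na(legendItems) & nzchar(legendItems)]
  legendH <- 18 * length(legendItems) + 24
  w <- labelW + ns * cs + (if (hasFBar) cs + 2 else 0) + 160
  h <- top + nf * cs + legendH + 10
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="monospace" font-size="10">',
    w, h))
  rect <- function(x, y, ww, hh, fill)
    sprintf('<rect x="%g" y="%g" width="%g" height="%g" fill="%s"/>',
            x, y, ww, hh, fill)
  y <- 0
  for (bar in view$sampleBars) {
    out <- c(out, vapply(seq_len(ns), function(j)
      rect(labelW + (j - 1) * cs, y, cs, cs, bar$colors[j]), ""))
    out <- c(out, sprintf('<text x="%g" y="%g" text-anchor="end">%s</text>',
                          labelW - 4, y + cs - 2, .svgEscape(bar$field)))
    y <- y + cs + 2
  }
  for (i in seq_len(nf)) {
    out <- c(out, vapply(seq_len(ns), function(j)
      rect(labelW + (j - 1) * cs, y + (i - 1) * cs, cs, cs,
           view$cells[i, j]), ""))
    if (nf <= 60) {
      lab <- view$featureIds[i]
      if (nchar(lab) > 14) lab <- paste0(substr(lab, 1, 12), "..")
      out <- c(out, sprintf('<text x="%g" y="%g" text-anchor="end">%s</text>',
                            labelW - 4, y + i * cs - 2, .svgEscape(lab)))
    }
  }
  if (hasFBar) {
    x0 <- labelW + ns * cs + 2
    out <- c(out, vapply(seq_len(nf), function(i)
      rect(x0, y + (i - 1) * cs, cs, cs, view$featureBar$colors[i]), ""))
  }
  ly <- y + nf * cs + 16
  out <- c(out, sprintf('<text x="%g" y="%g">legend:</text>', 4, ly))
  for (k in seq_along(legendItems)) {
    out <- c(out, rect(4, ly + 18 * k - 10, 12, 12,
                       .categoryColor(legendItems[k])),
             sprintf('<text x="%g" y="%g">%s</text>', 20, ly + 18 * k,
                     .svgEscape(legendItems[k])))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render an experiment as a static heatmap
#'
#' Features are rows, samples are columns; cell color encodes the
#' (default log-scaled) abundance through a perceptually uniform
#' colormap, with one categorical color track per requested sample
#' metadata field above the matrix and an optional feature track on the
#' right. The output format follows the file extension: \code{.png}
#' (raster tracks, no text), \code{.svg} (labels and a category
#' legend), or \code{.html} (delegates to \code{\link{exportHtml}}).
#' Rendering is a pure view: the experiment is not reordered or
#' modified, and a fixed experiment + spec yields a byte-identical
#' file.
#'
#' @param exp a non-empty FeatureExperiment (order it beforehand with
#'   the sorting/clustering functions).
#' @param spec a \code{\link{heatmapSpec}}.
#' @param file output path ending in .png, .svg or .html.
#' @return invisibly, the output path.
#' @export
renderHeatmap <- function(exp, spec, file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "html") return(exportHtml(exp, spec, file))
  view <- .heatmapView(exp, spec)
  if (ext == "png") .renderPNG(view, file)
  else if (ext == "svg") writeLines(.renderSVGString(view), file)
  else .stopInvalid("unsupported heatmap format '.%s' (png, svg, html)", ext)
  invisible(file)
}

#' Export a self-contained interactive-free HTML heatmap
#'
#' Writes a single HTML file embedding (i) the full abundance matrix,
#' identifiers in display order, metadata color tracks and optional
#' per-feature annotation summaries as a JSON payload, and (ii) a
#' static SVG rendering. The file references no external resources and
#' opens without network access; the embedded JSON reproduces the
#' experiment's values exactly (full-precision serialization).
#'
#' @param exp a non-empty FeatureExperiment.
#' @param spec a \code{\link{heatmapSpec}}.
#' @param file output path.
#' @param store optional \code{\linkS4class{AnnotationStore}}; when
#'   given, each feature's annotation terms are embedded in the payload.
#' @return invisibly, the output path.
#' @export
exportHtml <- function(exp, spec, file, store = NULL) {
  view <- .heatmapView(exp, spec)
  m <- .denseData(exp)
  payload <- list(
    sampleIds = sampleIds(exp),
    featureIds = featureIds(exp),
    matrix = unname(apply(m, 1, function(r) unname(r), simplify = FALSE)),
    sampleBars = view$sampleBars,
    featureBar = view$featureBar,
    colorScale = spec@colorScale,
    normalizedTotal = if (length(normalizedTotal(exp)))
      normalizedTotal(exp) else NULL)
  if (!is.null(store))
    payload$featureAnnotations <- lapply(featureIds(exp), function(f)
      lapply(featureAnnotations(store, f), function(a)
        list(type = a$type, terms = a$terms)))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>heatmap export</title>",
    "<style>body{font-family:monospace;margin:12px}</style>",
    "</head><body>",
    sprintf("<h3>%d features x %d samples</h3>",
            nFeatures(exp), nSamples(exp)),
    .renderSVGString(view),
    sprintf("<script type=\"application/json\" id=\"experiment-data\">%s</script>",
            json),
    "</body></html>")
  writeLines(html, file)
  invisible(file)
}
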