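# RSML (Root System Markup Language) 1.0 output. Coordinates are written
# in pixels with the resolution (pixels per mm) recorded in the metadata
# block, which keeps the stored geometry raw. The document is assembled
# as text for speed (a crown can hold thousands of polyline points) and
# parsed back through xml2 before writing, so malformed output can never
# be produced.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write root-tip paths as an RSML document
#'
#' Emits one `<root>` element per collar-to-tip path with its polyline in
#' pixel coordinates, and a per-point diameter annotation where medial
#' radii are available.
#'
#' @param paths a set of root-tip paths ([root_tip_paths()]), or a list of
#'   two-column (row, col) matrices. May be empty.
#' @param scale optional scale calibration ([scale_from_marker()]); its
#'   `pixels_per_mm` goes into the metadata resolution field (1 when
#'   absent, with unit "pixel").
#' @param image_meta named character list copied into the metadata block
#'   (e.g. `label`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(paths, scale = NULL, image_meta = list(), path) {
  plist <- rsml_path_list(paths)
  for (p in plist) {
    if (nrow(p$coords) < 2) {
      stop_input("every RSML path needs at least 2 points")
    }
  }
  resolution <- if (!is.null(scale)) scale$pixels_per_mm else 1
  unit <- if (!is.null(scale)) "mm" else "pixel"

  props <- vapply(names(image_meta), function(key) {
    sprintf('    <property name="%s" value="%s"/>',
            xml_escape(key), xml_escape(as.character(image_meta[[key]])))
  }, character(1))

  roots <- vapply(seq_along(plist), function(k) {
    p <- plist[[k]]
    # RSML x is horizontal (col), y vertical (row)
    pts <- sprintf('          <point x="%s" y="%s"/>',
                   format(p$coords[, 2], digits = 10, trim = TRUE),
                   format(p$coords[, 1], digits = 10, trim = TRUE))
    fns <- ""
    if (!is.null(p$radius) && !all(is.na(p$radius))) {
      smp <- sprintf('            <sample value="%s"/>',
                     format(diameter_px(p$radius), digits = 10, trim = TRUE))
      fns <- paste0(
        "        <functions>\n",
        '          <function name="diameter" domain="polyline">\n',
        paste(smp, collapse = "\n"),
        "\n          </function>\n        </functions>\n")
    }
    paste0(
      sprintf('      <root id="%d">\n', k),
      "        <geometry>\n          <polyline>\n",
      paste(pts, collapse = "\n"),
      "\n          </polyline>\n        </geometry>\n",
      fns,
      "      </root>")
  }, character(1))

  doc_text <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<rsml>\n",
    "  <metadata>\n",
    "    <version>1</version>\n",
    sprintf("    <unit>%s</unit>\n", unit),
    sprintf("    <resolution>%s</resolution>\n",
            format(resolution, digits = 15)),
    sprintf("    <last-modified>%s</last-modified>\n",
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "    <software>rootcrown</software>\n",
    if (length(props)) paste0(paste(props, collapse = "\n"), "\n") else "",
    "  </metadata>\n",
    "  <scene>\n",
    '    <plant id="1">\n',
    if (length(roots)) paste0(paste(roots, collapse = "\n"), "\n") else "",
    "    </plant>\n",
    "  </scene>\n",
    "</rsml>\n")

  doc <- xml2::read_xml(doc_text)   # guarantees well-formedness
  xml2::write_xml(doc, path)
  invisible(path)
}

# Normalize the accepted path inputs to list(coords=matrix, radius=vector).
rsml_path_list <- function(paths) {
  if (inherits(paths, "rtp_set")) {
    return(lapply(paths$points, function(pt) {
      list(coords = cbind(pt$row, pt$col), radius = pt$radius)
    }))
  }
  if (is.list(paths)) {
    return(lapply(paths, function(p) {
      if (is.matrix(p)) list(coords = p, radius = NULL) else p
    }))
  }
  stop_input("unsupported path container for RSML output")
}
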