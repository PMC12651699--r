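#' Read and write LabelImg-style Pascal VOC XML annotations
#'
#' Ground-truth tooth annotations follow the Pascal VOC XML dialect that
#' LabelImg emits: an `<annotation>` root with `<size>` and one `<object>`
#' per tooth holding the two-digit FDI code in `<name>` and the box in
#' `<bndbox>`. VOC boxes are 1-based inclusive pixel coordinates; on read
#' they are converted to the package's 0-based half-open convention
#' (`xmin - 1, xmax`), and converted back on write, so a read/write round
#' trip is lossless.
#'
#' Only permanent-tooth codes (11-48) are accepted; deciduous codes (51-85)
#' or arbitrary class names raise an error of class
#' `dentalign_invalid_code`.
#'
#' @param path File path of the XML document.
#' @return `read_voc_xml()`: a list of class `voc_annotation` with
#'   `image_id` (the `<filename>` without extension), `width`, `height`,
#'   `depth`, and `annotations` — a detections tibble (labels as linear
#'   indices, score 1) with an extra `fdi` string column.
#' @export
read_voc_xml <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Annotation file not found: ", path),
                 class = c("dentalign_io_error", "dentalign_error"))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    rlang::abort(paste0("Cannot parse VOC XML ", path, ": ", conditionMessage(e)),
                 class = c("dentalign_parse_error", "dentalign_error"))
  })
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) {
    rlang::abort(paste0("VOC XML ", path, " has no <size> element."),
                 class = c("dentalign_parse_error", "dentalign_error"))
  }
  num <- function(node, xpath) {
    v <- xml2::xml_double(xml2::xml_find_first(node, xpath))
    if (is.na(v)) {
      rlang::abort(paste0("VOC XML ", path, ": missing or non-numeric ", xpath),
                   class = c("dentalign_parse_error", "dentalign_error"))
    }
    v
  }
  width <- num(size, "./width")
  height <- num(size, "./height")
  depth_node <- xml2::xml_find_first(size, "./depth")
  depth <- if (inherits(depth_node, "xml_missing")) 1 else xml2::xml_double(depth_node)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  image_id <- if (is.na(fname) || fname == "") {
    tools::file_path_sans_ext(basename(path))
  } else {
    tools::file_path_sans_ext(fname)
  }
  objs <- xml2::xml_find_all(doc, "./object")
  names_chr <- vapply(objs, function(o) xml2::xml_text(xml2::xml_find_first(o, "./name")),
                      character(1))
  bad <- !grepl("^(1[1-8]|2[1-8]|3[1-8]|4[1-8])$", names_chr)
  if (any(bad)) {
    rlang::abort(
      paste0("VOC XML ", path, " has non-permanent-tooth label(s): ",
             paste(unique(names_chr[bad]), collapse = ", ")),
      class = c("dentalign_invalid_code", "dentalign_error")
    )
  }
  box <- function(o, what) num(o, paste0("./bndbox/", what))
  ann <- tibble::tibble(
    x_min = vapply(objs, box, numeric(1), what = "xmin") - 1,
    y_min = vapply(objs, box, numeric(1), what = "ymin") - 1,
    x_max = vapply(objs, box, numeric(1), what = "xmax"),
    y_max = vapply(objs, box, numeric(1), what = "ymax"),
    label = if (length(objs)) fdi_to_linear(names_chr) else integer(),
    score = rep(1, length(objs)),
    fdi = names_chr
  )
  if (any(ann$x_min < 0 | ann$y_min < 0 | ann$x_max > width | ann$y_max > height)) {
    rlang::abort(paste0("VOC XML ", path, " has boxes outside the image bounds."),
                 class = c("dentalign_parse_error", "dentalign_error"))
  }
  structure(
    list(image_id = image_id, width = width, height = height, depth = depth,
         annotations = as_detections(ann)),
    class = "voc_annotation"
  )
}

#' @param ann A `voc_annotation` object (or a list with the same fields).
#' @rdname read_voc_xml
#' @return `write_voc_xml()`: the path, invisibly.
#' @export
write_voc_xml <- function(ann, path) {
  a <- ann$annotations
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(ann$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$width))
  xml2::xml_add_child(size, "height", format(ann$height))
  xml2::xml_add_child(size, "depth", format(ann$depth %||% 1))
  for (i in seq_len(nrow(a))) {
    obj <- xml2::xml_add_child(doc, "object")
    fdi <- if ("fdi" %in% names(a)) a$fdi[i] else sprintf("%d", linear_to_fdi(a$label[i]))
    xml2::xml_add_child(obj, "name", fdi)
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format_px(a$x_min[i] + 1))
    xml2::xml_add_child(bb, "ymin", format_px(a$y_min[i] + 1))
    xml2::xml_add_child(bb, "xmax", format_px(a$x_max[i]))
    xml2::xml_add_child(bb, "ymax", format_px(a$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

format_px <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' @export
print.voc_annotation <- function(x, ...) {
  cat(sprintf("<voc_annotation> %s (%gx%g): %d tooth box(es)\n",
              x$image_id, x$width, x$height, nrow(x$annotations)))
  invisible(x)
}
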