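#' Read a Chimera marker (CMM) file as a subunit vector
#'
#' A subunit position can be picked interactively in UCSF Chimera and
#' saved as a marker file (an XML `marker_set`). The single marker's
#' coordinates are interpreted in Angstrom in the map's coordinate frame
#' with the origin at voxel (0,0,0); the vector runs from the map center
#' (`pixel_size * map_size_px / 2` per axis, overridable) to the marker.
#' The marker radius field is ignored.
#'
#' @param path Path to the CMM file.
#' @param map_size_px Map side length in pixels (scalar or length-3).
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param center Optional explicit map center (Angstrom, length 3)
#'   overriding the `pixel_size * map_size_px / 2` convention.
#' @return A [subunit_vector()].
#' @export
read_cmm <- function(path, map_size_px, pixel_size, center = NULL) {
  doc <- xml2::read_xml(path)
  markers <- xml2::xml_find_all(doc, ".//marker")
  if (length(markers) != 1) {
    stop("expected exactly 1 marker in ", path, ", found ", length(markers),
         call. = FALSE)
  }
  xyz <- unname(vapply(c("x", "y", "z"), function(a) {
    as.numeric(xml2::xml_attr(markers[[1]], a))
  }, numeric(1)))
  if (any(!is.finite(xyz))) stop("non-finite marker coordinates in ", path, call. = FALSE)
  if (is.null(center)) {
    size <- rep_len(map_size_px, 3)
    center <- pixel_size * size / 2
  }
  d <- xyz - center
  if (sqrt(sum(d^2)) < 1e-9) {
    stop("marker coincides with the map center: zero-length subunit vector",
         call. = FALSE)
  }
  subunit_vector(d)
}
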