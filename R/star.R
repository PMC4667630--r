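#' Read and write Relion-style STAR metadata tables
#'
#' STAR files carry labelled, whitespace-separated tables inside `loop_`
#' blocks, with labels like `_rlnAngleRot`. `read_star()` parses one
#' data block into a tibble whose column names are the labels without
#' the leading underscore (e.g. `rlnAngleRot`); free key--value pairs in
#' the block become scalar attributes (`star_pairs`). Files written by
#' Relion 3.1 and later, which carry a `data_optics` block, are
#' tolerated: the particle block is read and the optics columns are
#' merged in by `rlnOpticsGroup`. `write_star()` emits the legacy
#' single-block dialect.
#'
#' @param path File path.
#' @param block Name (without the `data_` prefix) or index of the block
#'   to read; by default the particle-bearing block.
#' @return A tibble; columns are typed by [utils::type.convert()].
#' @export
read_star <- function(path, block = NULL) {
  if (!file.exists(path)) stop("STAR file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blocks <- parse_star_blocks(lines, path)
  if (length(blocks) == 0) stop("no data block in STAR file: ", path, call. = FALSE)
  nm <- names(blocks)
  if (is.null(block)) {
    # Relion >= 3.1: merge optics into the particle table
    if (all(c("optics", "particles") %in% nm)) {
      return(merge_optics(blocks[["particles"]], blocks[["optics"]]))
    }
    pick <- if (length(blocks) == 1) 1L else which(nm != "optics")[1]
  } else if (is.character(block)) {
    pick <- match(block, nm)
    if (is.na(pick)) stop("no block 'data_", block, "' in ", path, call. = FALSE)
  } else {
    pick <- as.integer(block)
  }
  blocks[[pick]]
}

merge_optics <- function(particles, optics) {
  if (!"rlnOpticsGroup" %in% names(particles) ||
      !"rlnOpticsGroup" %in% names(optics)) {
    return(particles)
  }
  keep <- c("rlnOpticsGroup", setdiff(names(optics), names(particles)))
  dplyr::left_join(particles, optics[keep], by = "rlnOpticsGroup")
}

parse_star_blocks <- function(lines, path) {
  stripped <- sub("#.*$", "", lines)
  stripped <- trimws(stripped)
  starts <- grep("^data_", stripped)
  blocks <- list()
  for (b in seq_along(starts)) {
    from <- starts[b]
    to <- if (b < length(starts)) starts[b + 1] - 1 else length(stripped)
    name <- sub("^data_", "", stripped[from])
    body <- stripped[(from + 1):to]
    body_lines <- which(nzchar(body))
    pairs <- list()
    labels <- character()
    rows <- character()
    in_loop <- FALSE
    for (li in body_lines) {
      txt <- body[li]
      if (txt == "loop_") { in_loop <- TRUE; next }
      if (startsWith(txt, "_")) {
        if (in_loop) {
          labels <- c(labels, sub("^_", "", strsplit(txt, "\\s+")[[1]][1]))
        } else {
          kv <- strsplit(txt, "\\s+")[[1]]
          if (length(kv) < 2) {
            stop("malformed STAR key-value at line ", from + li, " of ", path,
                 call. = FALSE)
          }
          pairs[[sub("^_", "", kv[1])]] <- utils::type.convert(kv[2], as.is = TRUE)
        }
        next
      }
      if (in_loop) rows <- c(rows, txt)
    }
    if (in_loop && length(labels) == 0) {
      stop("malformed STAR loop (no labels) near line ", from, " of ", path,
           call. = FALSE)
    }
    if (length(labels) > 0) {
      if (anyDuplicated(labels)) {
        stop("duplicate STAR labels near line ", from, " of ", path, call. = FALSE)
      }
      if (length(rows) == 0) {
        cols <- stats::setNames(rep(list(logical(0)), length(labels)), labels)
        tab <- tibble::as_tibble(cols)
      } else {
        fields <- strsplit(rows, "\\s+")
        nf <- lengths(fields)
        if (any(nf != length(labels))) {
          bad <- which(nf != length(labels))[1]
          stop("malformed STAR row (", nf[bad], " fields, expected ",
               length(labels), ") near line ", from + body_lines[1] + bad,
               " of ", path, call. = FALSE)
        }
        m <- do.call(rbind, fields)
        cols <- lapply(seq_along(labels), function(j) {
          utils::type.convert(m[, j], as.is = TRUE)
        })
        tab <- tibble::as_tibble(stats::setNames(cols, labels))
      }
    } else {
      tab <- tibble::tibble()
    }
    attr(tab, "star_pairs") <- pairs
    attr(tab, "star_block") <- name
    blocks[[name]] <- tab
  }
  blocks
}

#' @rdname read_star
#' @param x A data frame. Column names become labels (a leading
#'   underscore is added; names not starting with `rln` are written
#'   as-is after the underscore).
#' @param block_name Data block name written after `data_`.
#' @return `write_star()` returns `path`, invisibly. Doubles are
#'   written with six decimal places.
#' @export
write_star <- function(x, path, block_name = "") {
  stopifnot(is.data.frame(x))
  labels <- paste0("_", names(x))
  cols <- lapply(x, function(col) {
    if (is.double(col)) sprintf("%.6f", col)
    else as.character(col)
  })
  header <- c(
    "",
    paste0("data_", block_name),
    "",
    "loop_",
    sprintf("%s #%d", labels, seq_along(labels))
  )
  body <- if (nrow(x) > 0) {
    do.call(paste, c(cols, sep = "\t"))
  } else {
    character()
  }
  writeLines(c(header, body, ""), path)
  invisible(path)
}

#' Convert a STAR particle table to the tidy particle representation
#'
#' Maps the `rln`-labelled columns of a Relion-style particle table to
#' the snake_case columns used throughout the package: `particle_id`,
#' `rot`, `tilt`, `psi` (degrees), `origin_x`, `origin_y` (pixels),
#' `defocus_u`, `defocus_v` (Angstrom), `astig_angle` (degrees),
#' `voltage` (kV), `cs` (mm), `amplitude_contrast`, `pixel_size`
#' (Angstrom/pixel) and, when present, `image_name`, `coord_x`,
#' `coord_y`. The pixel size is taken from `rlnPixelSize`,
#' `rlnImagePixelSize` or `rlnDetectorPixelSize` x 1e4 /
#' `rlnMagnification`, unless supplied explicitly.
#'
#' @param star A tibble from [read_star()].
#' @param pixel_size Pixel size override in Angstrom/pixel.
#' @return A tibble of particle records.
#' @export
as_particles <- function(star, pixel_size = NULL) {
  get0c <- function(nm, default = NA_real_) {
    if (nm %in% names(star)) star[[nm]] else rep(default, nrow(star))
  }
  ps <- pixel_size
  if (is.null(ps)) {
    if ("rlnPixelSize" %in% names(star)) ps <- star[["rlnPixelSize"]]
    else if ("rlnImagePixelSize" %in% names(star)) ps <- star[["rlnImagePixelSize"]]
    else if (all(c("rlnDetectorPixelSize", "rlnMagnification") %in% names(star))) {
      ps <- star[["rlnDetectorPixelSize"]] * 1e4 / star[["rlnMagnification"]]
    } else {
      stop("pixel size not found in table; pass pixel_size=", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    particle_id = seq_len(nrow(star)),
    rot = get0c("rlnAngleRot", 0),
    tilt = get0c("rlnAngleTilt", 0),
    psi = get0c("rlnAnglePsi", 0),
    origin_x = get0c("rlnOriginX", 0),
    origin_y = get0c("rlnOriginY", 0),
    defocus_u = get0c("rlnDefocusU"),
    defocus_v = get0c("rlnDefocusV"),
    astig_angle = get0c("rlnDefocusAngle", 0),
    voltage = get0c("rlnVoltage", 300),
    cs = get0c("rlnSphericalAberration", 2),
    amplitude_contrast = get0c("rlnAmplitudeContrast", 0.07),
    pixel_size = ps
  )
  if ("rlnImageName" %in% names(star)) out$image_name <- star[["rlnImageName"]]
  if ("rlnCoordinateX" %in% names(star)) out$coord_x <- star[["rlnCoordinateX"]]
  if ("rlnCoordinateY" %in% names(star)) out$coord_y <- star[["rlnCoordinateY"]]
  out
}

#' Convert sub-particle (or particle) records back to STAR labels
#'
#' The inverse of [as_particles()] for writing: renames the tidy
#' columns onto their `rln` labels so [write_star()] emits a table a
#' Relion-era workflow can consume. Sub-particle extraction coordinates
#' become `rlnCoordinateX/Y`.
#'
#' @param records A tibble of particle or sub-particle records.
#' @return A tibble with `rln`-labelled columns.
#' @export
as_star_table <- function(records) {
  map <- c(
    rot = "rlnAngleRot", tilt = "rlnAngleTilt", psi = "rlnAnglePsi",
    origin_x = "rlnOriginX", origin_y = "rlnOriginY",
    coord_x = "rlnCoordinateX", coord_y = "rlnCoordinateY",
    defocus_u = "rlnDefocusU", defocus_v = "rlnDefocusV",
    astig_angle = "rlnDefocusAngle", voltage = "rlnVoltage",
    cs = "rlnSphericalAberration", amplitude_contrast = "rlnAmplitudeContrast",
    image_name = "rlnImageName"
  )
  keep <- names(records)[names(records) %in% names(map)]
  out <- records[keep]
  names(out) <- unname(map[keep])
  if ("pixel_size" %in% names(records)) {
    out[["rlnPixelSize"]] <- records[["pixel_size"]]
  }
  tibble::as_tibble(out)
}
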