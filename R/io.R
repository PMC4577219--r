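# File interfaces: MetaImage volumes for label maps and fields, JSON scene
# descriptions with a label-encoding sidecar.
#
# MetaImage (.mha, local single file) is used because it is a trivially
# self-describing raster format readable by ITK/SimpleITK/3D Slicer.
# Labels are stored as 8-bit integers, fields as 64-bit floats, always
# with a JSON sidecar naming the label <-> tissue encoding.

#' Write a 3D array as a MetaImage volume
#'
#' @param x 3D numeric or integer array.
#' @param path output `.mha` path.
#' @param grid a `vox_grid` providing spacing/origin (mm).
#' @param type `"uchar"` for label maps (values 0..255) or `"double"`.
#' @export
write_metaimage <- function(x, path, grid, type = c("double", "uchar")) {
  type <- match.arg(type)
  stopifnot(length(dim(x)) == 3)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           sprintf("BinaryDataByteOrderMSB = False"),
           sprintf("DimSize = %d %d %d", dim(x)[1], dim(x)[2], dim(x)[3]),
           sprintf("ElementSpacing = %g %g %g", grid$spacing[1],
                   grid$spacing[2], grid$spacing[3]),
           sprintf("Offset = %g %g %g", grid$origin[1], grid$origin[2],
                   grid$origin[3]),
           sprintf("ElementType = %s",
                   if (type == "uchar") "MET_UCHAR" else "MET_DOUBLE"),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (type == "uchar") writeBin(as.integer(x), con, size = 1L)
  else writeBin(as.numeric(x), con, size = 8L)
  invisible(path)
}

#' Read a MetaImage volume written by [write_metaimage()]
#'
#' Supports local (single-file) MET_UCHAR and MET_DOUBLE volumes.
#'
#' @param path `.mha` path.
#' @return list with `data` (3D array), `spacing`, `origin`.
#' @export
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL (single-file) MetaImage volumes are supported")
  dims <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  n <- prod(dims)
  data <- switch(hdr$ElementType,
                 MET_UCHAR = readBin(con, "integer", n, size = 1L,
                                     signed = FALSE),
                 MET_DOUBLE = readBin(con, "numeric", n, size = 8L),
                 stop("unsupported ElementType: ", hdr$ElementType))
  list(data = array(data, dim = dims),
       spacing = as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]]),
       origin = as.numeric(strsplit(hdr$Offset, " ")[[1]]))
}

#' Export a scene: label volume, label-encoding sidecar, electrodes
#'
#' Writes `labels.mha`, `labels.json` (the integer <-> tissue encoding)
#' and `scene.json` (grid, electrodes, protocol).
#'
#' @param scene an `ire_scene`.
#' @param dir output directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metaimage(scene$labels, file.path(dir, "labels.mha"), scene$grid,
                  type = "uchar")
  codes <- sort(unique(as.integer(scene$labels)))
  jsonlite::write_json(
    list(format = "ireplan-labels", version = 1L,
         labels = setNames(as.list(label_name(codes)), codes)),
    file.path(dir, "labels.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(format = "ireplan-scene", version = 1L,
         grid = list(shape = scene$grid$shape, spacing = scene$grid$spacing,
                     origin = scene$grid$origin),
         electrodes = lapply(scene$electrodes, unclass),
         protocol = if (!is.null(scene$protocol))
           as.data.frame(scene$protocol)),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows", na = "null")
  invisible(dir)
}

#' Read a scene exported by [write_scene()]
#' @param dir directory with `labels.mha` and `scene.json`.
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "ireplan-scene"))
    stop("not an ireplan scene directory: ", dir)
  vol <- read_metaimage(file.path(dir, "labels.mha"))
  grid <- structure(list(shape = as.integer(meta$grid$shape),
                         spacing = as.numeric(meta$grid$spacing),
                         origin = as.numeric(meta$grid$origin)),
                    class = "vox_grid")
  electrodes <- lapply(seq_len(nrow(meta$electrodes %||% data.frame())),
                       function(i) {
    e <- meta$electrodes[i, ]
    electrode(tip = unlist(e$tip), axis = unlist(e$axis), index = e$index,
              radius = e$radius, exposure_length = e$exposure_length,
              insulated_length = e$insulated_length)
  })
  protocol <- if (!is.null(meta$protocol)) as_protocol(meta$protocol)
  structure(list(grid = grid,
                 labels = array(as.integer(vol$data), dim = grid$shape),
                 electrodes = electrodes, protocol = protocol),
            class = "ire_scene")
}
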