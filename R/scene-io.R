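#' Write a nucleus scene to TIFF stacks with a JSON header
#'
#' Each locale mask is written as a multi-page TIFF (one page per
#' z-slice, axis order z, y, x), alongside a JSON header recording the
#' voxel spacing, axis order, nucleus id and locale file names, and the
#' probe table as TSV.
#'
#' @param scene a [nucleus_scene()].
#' @param prefix output path prefix.
#' @return invisible character vector of files written.
#' @export
write_scene <- function(scene, prefix) {
  files <- character(0)
  for (loc in names(scene$masks)) {
    f <- paste0(prefix, "_", loc, ".tif")
    m <- scene$masks[[loc]]
    pages <- lapply(seq_len(dim(m)[1]), function(z) {
      pg <- m[z, , ]
      matrix(as.numeric(pg), nrow(pg), ncol(pg))
    })
    tiff::writeTIFF(pages, f)
    files <- c(files, f)
  }
  hdr <- paste0(prefix, "_header.json")
  jsonlite::write_json(
    list(voxel_nm = scene$voxel_nm, axis_order = c("z", "y", "x"),
         nucleus_id = scene$nucleus_id, locales = names(scene$masks),
         shape = dim(scene$masks[[1]])),
    hdr, auto_unbox = TRUE, digits = NA)
  files <- c(files, hdr)
  if (!is.null(scene$probes)) {
    pt <- paste0(prefix, "_probes.tsv")
    utils::write.table(scene$probes, pt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, pt)
  }
  invisible(files)
}

#' Read a nucleus scene written by [write_scene()]
#' @param prefix the path prefix used when writing.
#' @return A [nucleus_scene()].
#' @export
read_scene <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, "_header.json"),
                             simplifyVector = TRUE)
  masks <- list()
  for (loc in hdr$locales) {
    pages <- tiff::readTIFF(paste0(prefix, "_", loc, ".tif"), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    m <- array(FALSE, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) m[z, , ] <- pages[[z]] > 0.5
    masks[[loc]] <- m
  }
  probes_path <- paste0(prefix, "_probes.tsv")
  probes <- if (file.exists(probes_path))
    utils::read.table(probes_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  nucleus_scene(masks, hdr$voxel_nm, hdr$nucleus_id, probes)
}
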