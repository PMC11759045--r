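## Readers/writers for the package's on-disk formats: long-format community
## CSV, traits CSV, Newick trees, wavelength lists, and plot cubes as
## band-sequential ENVI (raw 32-bit float + text header; no geospatial
## raster package is required for these plot-scale files).

#' Write / read a community table
#'
#' Long CSV with columns `plot`, `site`, `species`, `percent_cover`.
#'
#' @param community a `community_table`.
#' @param path CSV path.
#' @return `write_community` the path, invisibly; `read_community` a
#'   `community_table`.
#' @export
write_community <- function(community, path) {
  cover <- community$cover
  idx <- which(cover > 0, arr.ind = TRUE)
  df <- data.frame(plot = rownames(cover)[idx[, 1]],
                   site = as.character(community$site[idx[, 1]]),
                   species = colnames(cover)[idx[, 2]],
                   percent_cover = cover[idx])
  df <- df[order(df$plot, df$species), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plots <- sort(unique(df$plot))
  species <- sort(unique(df$species))
  cover <- matrix(0, length(plots), length(species),
                  dimnames = list(plots, species))
  cover[cbind(match(df$plot, plots), match(df$species, species))] <-
    df$percent_cover
  site <- factor(df$site[match(plots, df$plot)])
  structure(list(cover = cover, site = site), class = "community_table")
}

#' Write / read a species-by-trait CSV (species ids in the first column)
#'
#' @param traits species x trait matrix.
#' @param path CSV path.
#' @export
write_traits <- function(traits, path) {
  df <- data.frame(species = rownames(traits), traits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a plot cube as band-sequential ENVI
#'
#' Raw 32-bit little-endian floats in band-sequential order plus a minimal
#' text header (`<path>.hdr`) and a wavelength list; the validity mask is
#' stored as an extra header entry.
#'
#' @param cube a [plot_cube].
#' @param path base path (binary written to `path`, header to `path.hdr`).
#' @export
write_envi_cube <- function(cube, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  ## BSQ: band-major, row-major pixels within band
  writeBin(as.numeric(cube$reflectance), con, size = 4, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", cube$ncol),
           sprintf("lines = %d", cube$nrow),
           sprintf("bands = %d", length(cube$wavelength)),
           "data type = 4", "interleave = bsq", "byte order = 0",
           sprintf("wavelength = { %s }",
                   paste(cube$wavelength, collapse = ", ")),
           sprintf("mask = { %s }",
                   paste(as.integer(cube$mask), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_envi_cube
#' @export
read_envi_cube <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getval <- function(key) {
    line <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    sub(".*= *", "", line)
  }
  ncol <- as.integer(getval("samples"))
  nrow <- as.integer(getval("lines"))
  bands <- as.integer(getval("bands"))
  getlist <- function(key) {
    start <- grep(paste0("^", key, " *= *\\{"), hdr)
    txt <- paste(hdr[start:length(hdr)], collapse = " ")
    txt <- sub(paste0(".*", key, " *= *\\{"), "", txt)
    txt <- sub("\\}.*", "", txt)
    as.numeric(strsplit(txt, ",")[[1]])
  }
  wl <- getlist("wavelength")
  mask <- as.logical(getlist("mask"))
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = nrow * ncol * bands, size = 4,
                  endian = "little")
  refl <- matrix(vals, nrow = nrow * ncol, ncol = bands)
  plot_cube(refl, wl, nrow = nrow, ncol = ncol, mask = mask)
}

#' Write a long metric table to CSV
#'
#' @param metrics data.frame from [compute_ground_metrics()] or
#'   [compute_spectral_metrics()].
#' @param path CSV path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
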