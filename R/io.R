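#' Read and write the package's plain-text data formats
#'
#' Pollen series (`site,taxon,date,count`), site metadata
#' (`site,lon,lat,alt`) and long-format daily met grids are exchanged as
#' CSV. The met layout has one row per cell and day with static `cell`,
#' `cell_x`, `cell_y`, `lon`, `lat`, `alt` columns and the seven daily
#' fields `tmax`, `tmin`, `vap`, `wind`, `prec`, `evap`, `rad`.
#'
#' @param path File path.
#' @return A tibble of the corresponding table.
#' @name pollen_io
NULL

#' @rdname pollen_io
#' @export
read_pollen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "taxon", "date", "count") %in% names(df)))
  df$date <- as.Date(df$date)
  if (any(df$count < 0)) stop("negative pollen counts in ", path, call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname pollen_io
#' @param pollen A pollen table.
#' @export
write_pollen_csv <- function(pollen, path) {
  df <- as.data.frame(pollen[, c("site", "taxon", "date", "count")])
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pollen_io
#' @export
read_met_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell", "lon", "lat", "alt", "date", "tmax", "tmin", "vap",
            "wind", "prec", "evap", "rad")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c)) {
    stop("met CSV lacks columns: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  tibble::as_tibble(df)
}

#' @rdname pollen_io
#' @param met A met grid table.
#' @export
write_met_csv <- function(met, path) {
  df <- as.data.frame(met)
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pollen_io
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "lon", "lat") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname pollen_io
#' @param sites A site table.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic world to a directory
#'
#' Emits `pollen.csv`, `sites.csv`, `met.csv` and `truth.csv` so a
#' generated world can be consumed as plain files.
#'
#' @param world A `pollen_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "pollen_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pollen_csv(world$pollen, file.path(dir, "pollen.csv"))
  write_sites_csv(world$sites, file.path(dir, "sites.csv"))
  write_met_csv(world$met, file.path(dir, "met.csv"))
  tr <- as.data.frame(world$truth)
  tr$date <- format(tr$date)
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
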