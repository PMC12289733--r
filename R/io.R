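#' Write / read results as self-describing HDF5 array files
#'
#' Results and collections are stored in HDF5 (the container format NetCDF4
#' itself builds on): the labelled activity array, one dataset per
#' coordinate table, the optional causal-inference series and a JSON-encoded
#' metadata block. Doubles round-trip bit-exactly.
#'
#' @param result an [nd_result()].
#' @param path output file path (conventionally `.h5`).
#' @return `write_result` returns `path` invisibly; `read_result` the
#'   reconstructed [nd_result()].
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "nd_result"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unname(result$activity), path, "activity")
  rhdf5::h5write(result$modes, path, "modes")
  rhdf5::h5write(unname(result$mode_roles), path, "mode_roles")
  rhdf5::h5createGroup(path, "coords")
  for (ax in names(result$coords)) {
    rhdf5::h5write(result$coords[[ax]], path, paste0("coords/", ax))
  }
  rhdf5::h5write(names(result$coords), path, "axis_order")
  if (!is.null(result$causes)) {
    rhdf5::h5write(result$causes, path, "causes")
  }
  rhdf5::h5write(
    as.character(jsonlite::serializeJSON(result$metadata, digits = NA)),
    path, "metadata_json")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)$name
  act <- rhdf5::h5read(path, "activity")
  modes <- as.character(rhdf5::h5read(path, "modes"))
  roles <- as.character(rhdf5::h5read(path, "mode_roles"))
  axes <- as.character(rhdf5::h5read(path, "axis_order"))
  coords <- stats::setNames(
    lapply(axes, function(ax) as.numeric(rhdf5::h5read(
      path, paste0("coords/", ax)))), axes)
  causes <- if ("causes" %in% contents) {
    as.numeric(rhdf5::h5read(path, "causes"))
  }
  meta <- jsonlite::unserializeJSON(
    as.character(rhdf5::h5read(path, "metadata_json")))
  rhdf5::h5closeAll()
  per_mode <- stats::setNames(lapply(seq_along(modes), function(i) {
    array(act[slice.index(act, 1L) == i], dim = dim(act)[-1L])
  }), modes)
  nd_result(per_mode, coords = coords,
            mode_roles = stats::setNames(roles, modes), causes = causes,
            metadata = meta)
}

#' Export a result, collection or table to disk
#'
#' Dispatches on the object type: results go to HDF5 via [write_result()],
#' collections to a single HDF5 file (one group per member plus the sweep
#' coordinates), tables (data.frames) to CSV with a header row. A tabular
#' export of a collection is undefined and raises an error.
#'
#' @param x an [nd_result()], `nd_collection`, or data.frame.
#' @param path output path.
#' @param format `"h5"` or `"csv"`; defaults to the natural format of `x`.
#' @return `path`, invisibly.
#' @export
export_result <- function(x, path, format = NULL) {
  if (inherits(x, "nd_result")) {
    if (!is.null(format) && format != "h5") {
      stop("nd_result exports only to h5", call. = FALSE)
    }
    return(write_result(x, path))
  }
  if (inherits(x, "nd_collection")) {
    if (!is.null(format) && format == "csv") {
      stop("tabular export undefined for collections", call. = FALSE)
    }
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x$sweep_axis, path, "sweep_axis")
    rhdf5::h5write(x$sweep_values, path, "sweep_values")
    for (i in seq_along(x$results)) {
      g <- sprintf("member_%04d", i)
      rhdf5::h5createGroup(path, g)
      r <- x$results[[i]]
      rhdf5::h5write(unname(r$activity), path, paste0(g, "/activity"))
      if (!is.null(r$causes)) {
        rhdf5::h5write(r$causes, path, paste0(g, "/causes"))
      }
    }
    rhdf5::h5write(x$modes, path, "modes")
    rhdf5::h5write(names(x$coords), path, "axis_order")
    rhdf5::h5createGroup(path, "coords")
    for (ax in names(x$coords)) {
      rhdf5::h5write(x$coords[[ax]], path, paste0("coords/", ax))
    }
    rhdf5::h5closeAll()
    return(invisible(path))
  }
  if (is.data.frame(x)) {
    if (!is.null(format) && format != "csv") {
      stop("tables export only to csv", call. = FALSE)
    }
    utils::write.csv(x, path, row.names = FALSE)
    return(invisible(path))
  }
  stop("unsupported object for export", call. = FALSE)
}
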