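#' Standardized multidimensional model result
#'
#' Every model in the package returns an `nd_result`: a labelled real-valued
#' array with named axes drawn from `(mode, time, x, y, z)`, always including
#' `mode` and `time`, so at most five dimensions. The mode axis carries at
#' least two unisensory modes and exactly one multisensory mode, which is what
#' makes any analysis function applicable to any model's output. An optional
#' causal-inference readout (`causes`, scalar or time series in \[0, 1\]) and a
#' free-form metadata record (model name, parameters, seed) travel with the
#' activity.
#'
#' Axis order is fixed as `(mode, time, x, y, z)` with absent spatial axes
#' dropped from the right; spatial coordinates are degrees, time is
#' milliseconds, both stored as explicit coordinate tables.
#'
#' @param activity named list of per-mode arrays. Each element holds one
#'   mode's activity with dimensions `(time, x, y, z)` restricted to the axes
#'   present in `coords`; a plain vector is accepted when only the time axis
#'   (or a single spatial axis with one time step) is present.
#' @param coords named list of coordinate vectors. Must contain `time` (ms)
#'   and zero to three of `x`, `y`, `z` (degrees), in that order.
#' @param mode_roles named character vector mapping each mode label to
#'   `"unisensory"` or `"multisensory"`. Order defines the mode axis order.
#' @param causes optional causal-inference readout: a scalar or a vector of
#'   `length(coords$time)`, values in \[0, 1\].
#' @param metadata named list of run metadata (model name, parameter record,
#'   seed, ...). Stored as-is.
#' @return An object of class `nd_result`.
#' @examples
#' r <- nd_result(
#'   activity = list(
#'     auditory = matrix(1, 2, 5), visual = matrix(2, 2, 5),
#'     multi = matrix(3, 2, 5)
#'   ),
#'   coords = list(time = c(0, 1), x = seq(0, 40, 10)),
#'   mode_roles = c(auditory = "unisensory", visual = "unisensory",
#'                  multi = "multisensory")
#' )
#' dim(get_mode(r, "auditory"))
#' @export
nd_result <- function(activity, coords, mode_roles, causes = NULL,
                      metadata = list()) {
  if (!is.list(activity) || is.null(names(activity)) ||
      any(!nzchar(names(activity)))) {
    stop("`activity` must be a named list of per-mode arrays", call. = FALSE)
  }
  modes <- names(mode_roles)
  if (is.null(modes) || !all(mode_roles %in% c("unisensory", "multisensory"))) {
    stop("`mode_roles` must be a named vector of 'unisensory'/'multisensory'",
         call. = FALSE)
  }
  if (!setequal(names(activity), modes)) {
    stop("activity modes and mode_roles labels differ", call. = FALSE)
  }
  if (sum(mode_roles == "unisensory") < 2L) {
    stop("insufficient unisensory modes: need at least 2", call. = FALSE)
  }
  if (sum(mode_roles == "multisensory") != 1L) {
    stop("exactly one multisensory mode is required", call. = FALSE)
  }

  axis_order <- c("time", "x", "y", "z")
  if (is.null(names(coords)) || !all(names(coords) %in% axis_order)) {
    stop("coords axes must be among (time, x, y, z)", call. = FALSE)
  }
  if (!"time" %in% names(coords)) {
    stop("a `time` coordinate table is required", call. = FALSE)
  }
  coords <- coords[intersect(axis_order, names(coords))]
  spatial <- setdiff(names(coords), "time")
  # spatial axes drop from the right: x before y before z
  if (!identical(spatial, utils::head(c("x", "y", "z"), length(spatial)))) {
    stop("spatial axes must be used in order x, then y, then z", call. = FALSE)
  }
  shape <- lengths(coords)
  if (any(shape == 0L)) stop("empty coordinate table", call. = FALSE)

  arr <- array(NA_real_, dim = c(length(modes), shape),
               dimnames = c(list(mode = modes),
                            stats::setNames(vector("list", length(shape)),
                                            names(coords))))
  for (m in modes) {
    a <- activity[[m]]
    if (is.null(dim(a))) {
      if (length(a) != prod(shape)) {
        stop(sprintf("mode '%s': length %d does not match coords (%s)",
                     m, length(a), paste(shape, collapse = " x ")),
             call. = FALSE)
      }
      a <- array(as.numeric(a), dim = shape)
    }
    if (!identical(unname(dim(a)), unname(as.integer(shape)))) {
      stop(sprintf("mode '%s': dims (%s) do not match coords (%s)", m,
                   paste(dim(a), collapse = " x "),
                   paste(shape, collapse = " x ")), call. = FALSE)
    }
    arr[slice.index(arr, 1L) == which(modes == m)] <- as.numeric(a)
  }
  if (!all(is.finite(arr))) {
    stop("non-finite activity values", call. = FALSE)
  }
  if (!is.null(causes)) {
    causes <- as.numeric(causes)
    if (!length(causes) %in% c(1L, length(coords$time))) {
      stop("`causes` must be a scalar or one value per time step",
           call. = FALSE)
    }
    if (any(!is.finite(causes)) || any(causes < 0 | causes > 1)) {
      stop("`causes` values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(activity = arr, modes = modes,
         mode_roles = stats::setNames(unname(mode_roles), modes),
         coords = lapply(coords, as.numeric), causes = causes,
         metadata = metadata),
    class = "nd_result")
}

#' @export
print.nd_result <- function(x, ...) {
  ax <- paste(sprintf("%s[%d]", c("mode", names(x$coords)),
                      dim(x$activity)), collapse = " x ")
  cat("<nd_result> ", ax, "\n", sep = "")
  roles <- paste(sprintf("%s(%s)", x$modes, substr(x$mode_roles, 1, 3)),
                 collapse = ", ")
  cat("  modes : ", roles, "\n", sep = "")
  cat("  time  : ", length(x$coords$time), " steps [",
      min(x$coords$time), ", ", max(x$coords$time), "] ms\n", sep = "")
  if (!is.null(x$causes)) {
    cat("  causes: ", if (length(x$causes) == 1L)
      sprintf("scalar %.4f", x$causes) else
        sprintf("series, final %.4f", x$causes[length(x$causes)]), "\n",
      sep = "")
  }
  if (!is.null(x$metadata$model)) {
    cat("  model : ", x$metadata$model, "\n", sep = "")
  }
  invisible(x)
}

#' Extract one mode's activity
#'
#' @param result an [nd_result()].
#' @param label a mode label present in `result$modes`.
#' @return The activity array over the remaining axes `(time, x, y, z)`,
#'   with axis dimnames preserved (singleton axes are not dropped).
#' @export
get_mode <- function(result, label) {
  stopifnot(inherits(result, "nd_result"))
  if (!label %in% result$modes) {
    stop(sprintf("unknown mode '%s'; available: %s", label,
                 paste(result$modes, collapse = ", ")), call. = FALSE)
  }
  d <- dim(result$activity)
  dn <- dimnames(result$activity)
  idx <- which(result$modes == label)
  n_rest <- prod(d[-1L])
  out <- array(result$activity[slice.index(result$activity, 1L) == idx],
               dim = d[-1L], dimnames = dn[-1L])
  stopifnot(length(out) == n_rest)
  out
}

#' Collection of homogeneous results along a sweep axis
#'
#' Aggregates results that share identical axes and coordinate tables, e.g.
#' one result per value of a swept parameter or per stimulus disparity. The
#' shared coordinate tables are stored once (the collection is "compressed").
#'
#' @param results list of [nd_result()] objects with identical axis names and
#'   coordinate tables.
#' @param sweep_axis name of the varied quantity (a parameter name or
#'   `"disparity"`).
#' @param sweep_values vector with one entry per member of `results`
#'   (repeats expanded), in member order.
#' @return An object of class `nd_collection`.
#' @export
stack_collection <- function(results, sweep_axis, sweep_values) {
  if (length(results) == 0L) stop("empty result sequence", call. = FALSE)
  if (!all(vapply(results, inherits, logical(1), "nd_result"))) {
    stop("all members must be nd_result objects", call. = FALSE)
  }
  if (length(results) != length(sweep_values)) {
    stop(sprintf("%d results but %d sweep values", length(results),
                 length(sweep_values)), call. = FALSE)
  }
  ref <- results[[1L]]
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!identical(names(r$coords), names(ref$coords)) ||
        !identical(r$modes, ref$modes)) {
      stop(sprintf("member %d has heterogeneous axes", i), call. = FALSE)
    }
    if (!isTRUE(all.equal(r$coords, ref$coords, tolerance = 0))) {
      stop(sprintf("member %d has different coordinate tables", i),
           call. = FALSE)
    }
  }
  structure(
    list(results = results, sweep_axis = sweep_axis,
         sweep_values = sweep_values, coords = ref$coords, modes = ref$modes,
         mode_roles = ref$mode_roles, compressed = TRUE),
    class = "nd_collection")
}

#' @export
print.nd_collection <- function(x, ...) {
  cat("<nd_collection> ", length(x$results), " results over ", x$sweep_axis,
      "\n", sep = "")
  cat("  values: ", paste(utils::head(x$sweep_values, 8), collapse = ", "),
      if (length(x$sweep_values) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.nd_collection <- function(x) length(x$results)

#' Apply a scalar metric across a collection
#'
#' @param coll an [stack_collection()] result.
#' @param metric function mapping an [nd_result()] to a single number.
#' @param name column name for the metric values.
#' @return A data.frame with columns `sweep_value` and `name`, one row per
#'   member, in member order.
#' @export
collection_metric <- function(coll, metric, name = "metric") {
  stopifnot(inherits(coll, "nd_collection"), is.function(metric))
  vals <- vapply(seq_along(coll$results), function(i) {
    v <- tryCatch(metric(coll$results[[i]]), error = function(e) {
      stop(sprintf("metric failed at %s = %s: %s", coll$sweep_axis,
                   format(coll$sweep_values[i]), conditionMessage(e)),
           call. = FALSE)
    })
    as.numeric(v)[1L]
  }, numeric(1))
  out <- data.frame(sweep_value = coll$sweep_values, metric = vals)
  names(out)[2L] <- name
  out
}
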