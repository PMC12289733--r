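#' Describe one modality's physical stimulus
#'
#' A stimulus is the physical description of what one modality receives:
#' where (degrees), when (onset and duration in ms), how strong
#' (dimensionless intensity) and how unreliable (noise, the standard
#' deviation of the stimulus perturbation; its exact meaning is
#' model-specific, see the model pages).
#'
#' @param modality modality label, e.g. `"auditory"`, `"visual"`, `"tactile"`.
#' @param position stimulus position in degrees.
#' @param onset stimulus onset in ms (>= 0).
#' @param duration stimulus duration in ms (> 0).
#' @param intensity dimensionless amplitude (>= 0), scaling the model's
#'   per-modality input gain.
#' @param noise standard deviation of the stimulus perturbation (>= 0).
#'   For the closed-form models this maps to the likelihood sigma only when
#'   the model's own sigma parameter is unset; for the networks it sets the
#'   fractional per-neuron input perturbation.
#' @return An object of class `msi_stimulus`.
#' @export
stimulus <- function(modality, position = 0, onset = 0, duration = 50,
                     intensity = 1, noise = 0) {
  stopifnot(is.character(modality), length(modality) == 1L, nzchar(modality))
  if (!is.finite(position)) stop("non-finite position", call. = FALSE)
  if (onset < 0) stop("onset must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (intensity < 0) stop("intensity must be >= 0", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(modality = modality, position = as.numeric(position),
                 onset = as.numeric(onset), duration = as.numeric(duration),
                 intensity = as.numeric(intensity), noise = as.numeric(noise)),
            class = "msi_stimulus")
}

#' @export
print.msi_stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> %s @ %g deg, onset %g ms, duration %g ms, I=%g, noise=%g\n",
              x$modality, x$position, x$onset, x$duration, x$intensity,
              x$noise))
  invisible(x)
}

#' Resolve modality placeholders in parameter names
#'
#' Model parameter schemas are written against modality slots
#' (`{mod1}`, `{mod2}`, ...) so the same model core can serve an
#' audio-visual setup (yielding e.g. `auditory_position`) or a
#' visual-tactile one (yielding `tactile_position`) without touching the
#' model logic.
#'
#' @param template_params character vector of names possibly containing
#'   `{modN}` placeholders.
#' @param modalities modality labels filling the slots, in slot order.
#' @return The names with placeholders substituted.
#' @examples
#' resolve_parameter_names(c("{mod1}_position", "{mod2}_position"),
#'                         c("auditory", "visual"))
#' @export
resolve_parameter_names <- function(template_params, modalities) {
  slots <- regmatches(template_params,
                      gregexpr("\\{mod([0-9]+)\\}", template_params))
  idx <- as.integer(sub("\\{mod([0-9]+)\\}", "\\1", unlist(slots)))
  n_slots <- if (length(idx)) max(idx) else 0L
  if (n_slots > 0L && length(modalities) != n_slots) {
    stop(sprintf("model has %d modality slots but %d modalities supplied",
                 n_slots, length(modalities)), call. = FALSE)
  }
  out <- template_params
  for (i in seq_along(modalities)) {
    out <- gsub(sprintf("\\{mod%d\\}", i), modalities[i], out)
  }
  out
}

#' Define a model contract
#'
#' A contract is the uniform interface every model obeys: named modality
#' slots, a parameter schema (names, defaults, bounds) written against those
#' slots, and a run entry point that always returns a valid [nd_result()].
#' Any analysis function in the package can therefore consume any model's
#' output.
#'
#' @param name model name (registry key).
#' @param modalities ordered unisensory modality labels (>= 2).
#' @param param_schema data.frame with columns `name` (may contain `{modN}`
#'   placeholders), `default`, `lower`, `upper`.
#' @param run function `(stimuli, params, seed, ...)` returning an
#'   [nd_result()]. `params` arrive as a named list with placeholder slots
#'   resolved to the contract's modalities.
#' @param n_spatial_dims number of spatial axes the model emits (1-3).
#' @param dimensions character vector of the stimulus dimensions the model
#'   can operate on: `"space"`, `"time"`, or both.
#' @param multi_label label of the derived multisensory mode.
#' @return An object of class `msi_contract`.
#' @export
model_contract <- function(name, modalities = c("auditory", "visual"),
                           param_schema, run, n_spatial_dims = 1L,
                           dimensions = "space", multi_label = "multi") {
  stopifnot(length(modalities) >= 2L, is.function(run),
            n_spatial_dims >= 1L, n_spatial_dims <= 3L,
            all(dimensions %in% c("space", "time")))
  stopifnot(is.data.frame(param_schema),
            all(c("name", "default", "lower", "upper") %in%
                  names(param_schema)))
  schema <- param_schema
  schema$name <- resolve_parameter_names(schema$name, modalities)
  structure(list(name = name, modalities = modalities,
                 multi_label = multi_label,
                 mode_labels = c(modalities, multi_label),
                 n_spatial_dims = as.integer(n_spatial_dims),
                 dimensions = dimensions,
                 param_schema = schema, run = run),
            class = "msi_contract")
}

# package-level model registry
.msi_registry <- new.env(parent = emptyenv())

#' Register / look up model contracts
#'
#' Built-in models register themselves at load time; user models can be
#' added with `register_model()`.
#'
#' @param contract an [model_contract()] object.
#' @return `register_model` returns the contract invisibly; `get_contract`
#'   the contract registered under `name`; `list_models` the registered
#'   names.
#' @export
register_model <- function(contract) {
  stopifnot(inherits(contract, "msi_contract"))
  assign(contract$name, contract, envir = .msi_registry)
  invisible(contract)
}

#' @rdname register_model
#' @param name registered model name.
#' @export
get_contract <- function(name) {
  if (inherits(name, "msi_contract")) return(name)
  if (!exists(name, envir = .msi_registry, inherits = FALSE)) {
    stop(sprintf("unknown model '%s'; registered models: %s", name,
                 paste(list_models(), collapse = ", ")), call. = FALSE)
  }
  get(name, envir = .msi_registry, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() sort(ls(.msi_registry))

#' Validate a stimulus set against a contract
#'
#' Checks that exactly one stimulus is supplied per declared unisensory
#' modality and returns them as a named list in modality-slot order.
#'
#' @param stimuli list of [stimulus()] objects (a single stimulus is
#'   promoted to a list).
#' @param contract an [model_contract()] or registered model name.
#' @return Named list of stimuli, one per modality, in slot order.
#' @export
validate_stimuli <- function(stimuli, contract) {
  contract <- get_contract(contract)
  if (inherits(stimuli, "msi_stimulus")) stimuli <- list(stimuli)
  stopifnot(all(vapply(stimuli, inherits, logical(1), "msi_stimulus")))
  labs <- vapply(stimuli, `[[`, character(1), "modality")
  for (m in contract$modalities) {
    n <- sum(labs == m)
    if (n == 0L) stop(sprintf("missing modality: %s", m), call. = FALSE)
    if (n > 1L) stop(sprintf("duplicate modality: %s", m), call. = FALSE)
  }
  extra <- setdiff(labs, contract$modalities)
  if (length(extra)) {
    stop(sprintf("modalities not in contract: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(stimuli[match(contract$modalities, labs)],
                  contract$modalities)
}

# evaluate code with a temporary RNG seed, restoring global state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a deterministic 31-bit child seed from a base seed and indices
child_seed <- function(base_seed, i, r = 1L) {
  h <- (as.double(base_seed) %% 2147483647) * 2654435761 +
    as.double(i) * 40503 + as.double(r) * 69621 + 97
  as.integer(h %% 2147483647)
}

#' Run a model through its contract
#'
#' The single entry point used by tasks, sweeps and the CLI: validates the
#' stimuli and parameters against the contract, seeds the run, executes the
#' model and checks that the output honours the result invariants (finite
#' activity, the contract's modes). Identical seed and inputs give identical
#' output.
#'
#' @param model an [model_contract()] or registered model name.
#' @param stimuli list of [stimulus()] objects, one per contract modality.
#' @param params named list overriding schema defaults (may be empty).
#' @param seed integer seed for all randomness of the run, or `NULL` for a
#'   noiseless/deterministic run.
#' @param ... passed through to the model's run function (e.g. `grid`,
#'   `duration`, `dimension`).
#' @return A validated [nd_result()].
#' @export
run_model <- function(model, stimuli, params = list(), seed = NULL, ...) {
  contract <- get_contract(model)
  stim <- validate_stimuli(stimuli, contract)
  schema <- contract$param_schema
  full <- stats::setNames(as.list(schema$default), schema$name)
  if (length(params)) {
    bad <- setdiff(names(params), schema$name)
    if (length(bad)) {
      stop(sprintf("unknown parameter(s) for model '%s': %s", contract$name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    full[names(params)] <- params
  }
  for (i in seq_len(nrow(schema))) {
    v <- full[[schema$name[i]]]
    if (is.null(v) || is.na(v)) next  # NA default = model resolves at run time
    if (v < schema$lower[i] || v > schema$upper[i]) {
      stop(sprintf("parameter '%s' = %g outside bounds [%g, %g]",
                   schema$name[i], v, schema$lower[i], schema$upper[i]),
           call. = FALSE)
    }
  }
  res <- with_seed(seed, contract$run(stim, full, seed = seed, ...))
  if (!inherits(res, "nd_result")) {
    stop(sprintf("model '%s' did not return an nd_result", contract$name),
         call. = FALSE)
  }
  if (!all(is.finite(res$activity))) {
    stop(sprintf("model '%s' produced non-finite activity (diverged)",
                 contract$name), call. = FALSE)
  }
  res$metadata$model <- contract$name
  res$metadata$seed <- seed
  res$metadata$params <- full
  res
}
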