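#' Load and validate a run configuration
#'
#' A configuration is one JSON file describing one reproducible run: a
#' model name, stimulus blocks, an optional parameter block, exactly one of
#' a task block or a sweep block (or neither, for a single run), a seed and
#' an output path. Unknown keys are rejected rather than silently ignored.
#'
#' @param path path to a JSON config file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("model", "stimuli", "params", "task", "sweep", "seed",
               "output", "format")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$model)) stop("config requires a model name", call. = FALSE)
  if (!is.null(cfg$task) && !is.null(cfg$sweep)) {
    stop("ambiguous mode: config has both task and sweep blocks",
         call. = FALSE)
  }
  contract <- get_contract(cfg$model)
  if (!is.null(cfg$params)) {
    bad <- setdiff(names(cfg$params), contract$param_schema$name)
    if (length(bad)) {
      stop(sprintf("unknown parameter key(s) for model '%s': %s", cfg$model,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(cfg$stimuli)) {
    stim_fields <- c("modality", "position", "onset", "duration",
                     "intensity", "noise")
    blocks <- if (is.data.frame(cfg$stimuli)) {
      lapply(seq_len(nrow(cfg$stimuli)), function(i)
        as.list(cfg$stimuli[i, , drop = FALSE]))
    } else {
      cfg$stimuli
    }
    cfg$stimuli <- lapply(blocks, function(b) {
      b <- b[!vapply(b, function(v) all(is.na(v)), logical(1))]
      bad <- setdiff(names(b), stim_fields)
      if (length(bad)) {
        stop(sprintf("unknown stimulus key(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      do.call(stimulus, b)
    })
  }
  cfg$mode <- if (!is.null(cfg$task)) "task"
    else if (!is.null(cfg$sweep)) "sweep" else "run"
  structure(cfg, class = "run_config")
}

# provenance block embedded next to every CLI output
provenance_record <- function(cfg_path, cfg, seed) {
  list(config = normalizePath(cfg_path, mustWork = FALSE),
       config_sha = unname(tools::md5sum(cfg_path)),
       seed = seed,
       package = "multisense",
       version = as.character(utils::packageVersion("multisense")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Command-line entry point
#'
#' Subcommands: `run` (single model run), `task` (one of the three
#' causal-inference protocols), `sweep` (parameter sweep) and `fit` (model
#' fitting from a CSV of observed responses). Every invocation takes
#' `--config <file>` and writes its result plus a JSON provenance record
#' (config path and checksum, seed, package version) next to it. Returns a
#' nonzero exit code with a one-line diagnostic on failure.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success, 2 on usage errors).
#' @export
cli_run <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: multisense <run|task|sweep|fit> --config <file>",
    "[--out <path>] [--seed <int>] [--quiet]", sep = " ")
  quiet <- FALSE
  say <- function(...) if (!quiet) message(...)
  tryCatch({
    if (length(argv) < 1L) stop(usage, call. = FALSE)
    cmd <- argv[1L]
    args <- argv[-1L]
    opt <- function(flag, default = NULL) {
      i <- which(args == flag)
      if (length(i)) args[i[1L] + 1L] else default
    }
    quiet <- "--quiet" %in% args
    if (!cmd %in% c("run", "task", "sweep", "fit")) {
      stop(sprintf("unknown subcommand '%s'; registered models: %s\n%s",
                   cmd, paste(list_models(), collapse = ", "), usage),
           call. = FALSE)
    }
    cfg_path <- opt("--config")
    if (is.null(cfg_path)) stop(usage, call. = FALSE)
    cfg <- load_config(cfg_path)
    seed <- as.integer(opt("--seed", cfg$seed))
    if (length(seed) == 0L || is.na(seed)) seed <- NULL
    out <- opt("--out", cfg$output)
    if (is.null(out)) out <- paste0("multisense_", cmd, "_output")
    params <- as.list(cfg$params)
    if (cmd == "run") {
      res <- run_model(cfg$model, cfg$stimuli, params, seed = seed)
      export_result(res, paste0(out, ".h5"))
      say("wrote ", out, ".h5")
    } else if (cmd == "task") {
      kind <- cfg$task$kind
      if (is.null(kind)) stop("task block requires a kind", call. = FALSE)
      tab <- run_task(cfg$model, default_task(kind), params = params)
      export_result(tab, paste0(out, ".csv"))
      say("wrote ", out, ".csv (", nrow(tab), " conditions)")
    } else if (cmd == "sweep") {
      sw <- cfg$sweep
      config <- sweep_config(sw$parameter, unlist(sw$values),
                             repeats = if (is.null(sw$repeats)) 1L
                               else sw$repeats,
                             base_seed = if (is.null(seed)) 1L else seed)
      coll <- run_sweep(cfg$model, cfg$stimuli, params, config)
      export_result(coll, paste0(out, ".h5"))
      m <- collection_metric(coll, function(r) max(get_mode(
        r, r$modes[r$mode_roles == "multisensory"])))
      names(m)[2L] <- "max_multi_activity"
      export_result(m, paste0(out, "_summary.csv"))
      say("wrote ", out, ".h5 and ", out, "_summary.csv")
    } else {
      fit_cfg <- cfg$task
      if (is.null(fit_cfg$kind) || is.null(fit_cfg$observed)) {
        stop("fit requires task.kind and task.observed (CSV path)",
             call. = FALSE)
      }
      obs <- utils::read.csv(fit_cfg$observed)
      fp <- lapply(fit_cfg$free_params, unlist)
      fit <- fit_model(cfg$model, default_task(fit_cfg$kind), obs, fp,
                       params = params,
                       budget = if (is.null(fit_cfg$budget)) 2000
                         else fit_cfg$budget,
                       seed = if (is.null(seed)) 1L else seed)
      jsonlite::write_json(
        list(par = as.list(fit$par), loss = fit$loss, evals = fit$evals),
        paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
      say("wrote ", out, ".json (loss ", format(fit$loss), ")")
    }
    jsonlite::write_json(provenance_record(cfg_path, cfg, seed),
                         paste0(out, "_provenance.json"),
                         auto_unbox = TRUE, null = "null")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
}
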