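fmt_num <- function(x) sprintf("%.10g", x)

#' Write a dataset to disk in the plain-text exchange format
#'
#' One CSV per trial (`time_s,length_mm,force_N`), one plain-text spike
#' file per trial (one spike time per line), and a JSON manifest listing
#' every trial with its metadata and, for synthetic data, the ground
#' truth. Numeric formatting is fixed, so writing the same dataset twice
#' produces byte-identical files.
#'
#' @param dataset a `spindle_dataset` (from [make_dataset()] or
#'   [read_dataset()]).
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spindle_dataset"))
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE)
  manifest <- list(seed = dataset$seed, afferents = list())
  for (af in dataset$afferents) {
    trs <- list()
    for (tr in af$trials) {
      tfile <- file.path("trials", paste0(tr$trial_id, ".csv"))
      sfile <- file.path("spikes", paste0(tr$trial_id, ".txt"))
      lines <- c(
        "time_s,length_mm,force_N",
        paste(fmt_num(tr$t), fmt_num(tr$length_mm), fmt_num(tr$force_n),
              sep = ",")
      )
      writeLines(lines, file.path(dir, tfile))
      writeLines(fmt_num(tr$spike_times), file.path(dir, sfile))
      trs[[length(trs) + 1L]] <- list(
        trial_id = tr$trial_id,
        trial_file = tfile,
        spike_file = sfile,
        fs = tr$fs,
        stretch_type = tr$stretch_type,
        peak_length_mm = tr$peak_length_mm,
        peak_velocity_mm_s = tr$peak_velocity_mm_s,
        peak_accel_mm_s2 = tr$peak_accel_mm_s2,
        ramp_end_time_s = tr$ramp_end_time_s,
        exclude_flag = tr$exclude_flag
      )
    }
    entry <- list(afferent_id = af$afferent_id, trials = trs)
    if (!is.null(af$truth)) {
      tt <- af$truth
      entry$truth <- list(
        model_id = tt$model_id,
        k = tt$params$k, b = tt$params$b,
        lambda_ms = tt$params$lambda_ms,
        a = if (is.na(tt$params$a)) NULL else tt$params$a,
        spike_mode = tt$spike_mode, rate_floor = tt$rate_floor,
        isi_shape = tt$isi_shape,
        competing = isTRUE(tt$competing)
      )
    }
    manifest$afferents[[length(manifest$afferents) + 1L]] <- entry
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a dataset from its JSON manifest
#'
#' Validates every trial on load (column names, monotone time base,
#' spikes within the trial span) and reports schema violations with the
#' offending file.
#'
#' @param manifest_path path to `manifest.json` (or its directory).
#' @param config a [spindle_config()] used to derive predictor channels.
#' @param derive also compute [derive_channels()] per trial (default TRUE).
#' @return A `spindle_dataset`.
#' @export
read_dataset <- function(manifest_path, config = spindle_config(),
                         derive = TRUE) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.json")
  }
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  root <- dirname(manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  afferents <- lapply(m$afferents, function(entry) {
    trials <- lapply(entry$trials, function(ti) {
      tf <- file.path(root, ti$trial_file)
      sf <- file.path(root, ti$spike_file)
      if (!file.exists(tf)) stop("missing trial file: ", tf)
      if (!file.exists(sf)) stop("missing spike file: ", sf)
      dat <- utils::read.csv(tf)
      need <- c("time_s", "length_mm", "force_N")
      if (!all(need %in% names(dat))) {
        stop(sprintf("%s: expected columns %s", tf,
                     paste(need, collapse = ", ")))
      }
      spk_lines <- readLines(sf)
      spikes <- as.numeric(spk_lines[nzchar(spk_lines)])
      tryCatch(
        trial_record(
          trial_id = ti$trial_id, afferent_id = entry$afferent_id,
          t = dat$time_s, length_mm = dat$length_mm, force_n = dat$force_N,
          spike_times = spikes, fs = ti$fs,
          stretch_type = ti$stretch_type,
          peak_length_mm = ti$peak_length_mm,
          peak_velocity_mm_s = ti$peak_velocity_mm_s,
          peak_accel_mm_s2 = ti$peak_accel_mm_s2,
          ramp_end_time_s = if (is.null(ti$ramp_end_time_s)) NA_real_ else ti$ramp_end_time_s,
          exclude_flag = isTRUE(ti$exclude_flag)
        ),
        error = function(e) stop(sprintf("%s: %s", tf, conditionMessage(e)),
                                 call. = FALSE)
      )
    })
    channels <- if (derive) {
      lapply(trials, derive_channels, config = config)
    } else {
      vector("list", length(trials))
    }
    truth <- NULL
    if (!is.null(entry$truth)) {
      tt <- entry$truth
      truth <- spindle_truth(
        model_id = tt$model_id, k = unlist(tt$k), b = unlist(tt$b),
        lambda_ms = tt$lambda_ms,
        spike_mode = tt$spike_mode, rate_floor = tt$rate_floor,
        isi_shape = tt$isi_shape,
        a = if (is.null(tt$a) || !is.numeric(tt$a) || is.na(tt$a)) NA_real_ else tt$a,
        competing = isTRUE(tt$competing)
      )
    }
    list(afferent_id = entry$afferent_id, truth = truth, trials = trials,
         channels = channels)
  })
  names(afferents) <- vapply(afferents, `[[`, character(1), "afferent_id")
  structure(
    list(afferents = afferents, seed = m$seed, config = config,
         force_params = NULL),
    class = "spindle_dataset"
  )
}

#' Human-readable selection report
#'
#' Prints per-afferent and population tables in the fixed candidate order
#' (selection frequency, Akaike weight, mean +/- SD R-squared per model)
#' and optionally writes the same content as JSON.
#'
#' @param summaries list of per-afferent `selection_summary` objects.
#' @param metrics optional [spindle_metrics()] data frame to append.
#' @param out_json optional path for a machine-readable copy.
#' @return Invisibly, a list with `afferents`, `population`, `metrics`.
#' @export
run_report <- function(summaries, metrics = NULL, out_json = NULL) {
  if (inherits(summaries, "selection_summary")) summaries <- list(summaries)
  pop <- if (length(summaries) > 1L) population_summary(summaries) else NULL
  for (s in summaries) {
    cat(sprintf("== Afferent %s (%d CV iterations; force variant: %s)\n",
                paste(s$afferent_ids, collapse = ","), s$n_iter,
                if (!is.null(s$details)) s$details$force_variant else "plain"))
    print(s)
    cat("\n")
  }
  if (!is.null(pop)) {
    cat("== Population\n")
    print(pop)
    cat("\n")
  }
  if (!is.null(metrics)) {
    cat(sprintf("== Spindle metrics: %d trials, %d with dynamic index\n",
                nrow(metrics), sum(!is.na(metrics$di))))
  }
  out <- list(
    afferents = lapply(summaries, function(s) {
      list(afferent_id = paste(s$afferent_ids, collapse = ","),
           n_iter = s$n_iter, table = s$table)
    }),
    population = if (!is.null(pop)) {
      list(n_iter = pop$n_iter, table = pop$table)
    },
    metrics = metrics
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(out)
}
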