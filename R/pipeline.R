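# End-to-end orchestration: epoching -> connectivity -> topography ->
# modelling table -> statistics/selection/fits, with per-stage outputs and a
# manifest recording seeds, configuration and per-participant exclusions.

#' Read a continuous recording from a delimited matrix with a JSON sidecar
#'
#' The matrix file holds one channel per row (whitespace-, tab- or
#' comma-delimited); the sidecar is JSON with fields `fs` and
#' `channel_order`.
#'
#' @param path Matrix file path.
#' @param sidecar JSON sidecar path; defaults to `path` with extension
#'   `.json`.
#' @param participant_id,stimulus Identifiers attached to the recording.
#' @return A `continuous_recording`.
#' @export
read_recording <- function(path, sidecar = paste0(path, ".json"),
                           participant_id = NA_character_,
                           stimulus = NA_character_) {
  abort_if(!file.exists(path), "recording file not found: ", path)
  abort_if(!file.exists(sidecar), "sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  abort_if(is.null(meta$fs) || is.null(meta$channel_order),
           "sidecar must provide fs and channel_order")
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  abort_if(nrow(m) != length(meta$channel_order),
           "channel_order length does not match the matrix rows")
  continuous_recording(unname(m), meta$fs, meta$channel_order,
                       participant_id = participant_id, stimulus = stimulus)
}

#' Read attention masks from CSV
#'
#' @param path CSV with columns `participant`, `condition`, `start_s`,
#'   `end_s`.
#' @return Data frame of mask rows; extract one recording's mask with
#'   [mask_for()].
#' @export
read_masks <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("participant", "condition", "start_s", "end_s") %in% names(m)),
           "mask CSV needs columns participant, condition, start_s, end_s")
  m
}

#' @rdname read_masks
#' @param masks Data frame from [read_masks()].
#' @param participant,condition Which recording.
#' @export
mask_for <- function(masks, participant, condition) {
  d <- masks[masks$participant == participant & masks$condition == condition, ]
  attention_mask(d$start_s, d$end_s)
}

#' Run the full connectivity analysis pipeline
#'
#' Sequences the stages on a synthetic cohort (recordings regenerated
#' lazily) or on file-based inputs: epoch segmentation under the attention
#' masks, the minimum-epoch participant gate, per-band dbWPLI topographies,
#' normalization/flipping, the 12-variable modelling table, and optionally
#' the variable-selection and model-fitting stage.
#'
#' @param cohort A `synthetic_cohort`, or `NULL` when `recordings` is given.
#' @param recordings For file-based input: data frame with columns
#'   `participant`, `stimulus`, `path` (+ optional `sidecar`), plus `masks`
#'   (data frame as from [read_masks()]), `montage`, `selected_ids` and
#'   `covariates`.
#' @param masks,montage,selected_ids,covariates See `recordings`.
#' @param bands Band specs. Default [default_bands()].
#' @param epoch_s,overlap,max_bad_fraction Epoching parameters.
#' @param min_epochs Participant gate. Default 90.
#' @param run_models Fit the selection/association stage. Default TRUE.
#' @param selection_args List of overrides for [cv_subset_selection()]
#'   (e.g. `list(repeats = 3)`).
#' @param seed Seed for the modelling stage.
#' @param out_dir Optional output directory for per-stage artifacts.
#' @return List with `counts`, `gate`, `topographies` (long data frame, all
#'   three forms), `table`, `selection`, `fit_main`, `fit_moderation`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, recordings = NULL, masks = NULL,
                         montage = NULL, selected_ids = NULL,
                         covariates = NULL,
                         bands = default_bands(),
                         epoch_s = 1.0, overlap = 0.5, max_bad_fraction = 0.5,
                         min_epochs = 90L, run_models = TRUE,
                         selection_args = list(), seed = 1L,
                         out_dir = NULL) {
  abort_if(is.null(cohort) && is.null(recordings),
           "provide either a synthetic cohort or file-based recordings")
  synthetic <- !is.null(cohort)
  if (synthetic) {
    lay <- load_layout(default_montage(), default_selected_ids())
    plist <- cohort$participants$participant
    stimuli <- c("social", "nonsocial")
    covariates <- cohort$truth[, intersect(c("participant", "sex", "likelihood",
                                             "age_5mo", "group",
                                             "ados_css_total", "gmls"),
                                           names(cohort$truth))]
  } else {
    abort_if(is.null(montage) || is.null(selected_ids),
             "file-based input needs `montage` and `selected_ids`")
    lay <- load_layout(montage, selected_ids)
    plist <- unique(recordings$participant)
    stimuli <- unique(recordings$stimulus)
  }
  aoi <- assign_aois(lay)
  band_freqs <- sort(unique(unlist(lapply(bands, function(b)
    seq(ceiling(b$lo_hz), floor(b$hi_hz))))))
  counts <- list(); raw_topos <- list()
  for (p in plist) {
    for (st in stimuli) {
      if (synthetic) {
        sim <- simulate_recording(cohort, p, st)
        rec <- sim$recording; msk <- sim$mask
      } else {
        row <- recordings[recordings$participant == p & recordings$stimulus == st, ]
        if (nrow(row) == 0) next
        rec <- read_recording(row$path[1],
                              sidecar = row$sidecar[1] %||% paste0(row$path[1], ".json"),
                              participant_id = p, stimulus = st)
        msk <- if (!is.null(masks)) mask_for(masks, p, st) else NULL
      }
      starts <- segment_epochs(rec, msk, epoch_s = epoch_s, overlap = overlap,
                               max_bad_fraction = max_bad_fraction)
      counts[[length(counts) + 1]] <-
        data.frame(participant = p, condition = st, n_epochs = length(starts),
                   stringsAsFactors = FALSE)
      if (length(starts) < max(min_epochs, 2L)) next
      spec <- compute_spectra(rec, starts, epoch_s = epoch_s,
                              freqs = band_freqs)
      for (b in bands) {
        raw_topos[[length(raw_topos) + 1]] <- seed_topography(spec, aoi, b)
      }
    }
  }
  counts <- do.call(rbind, counts)
  gate <- min_epoch_gate(counts, min_epochs = min_epochs,
                         require_conditions = stimuli)
  retained <- gate$participant[gate$retained]
  raw_topos <- Filter(function(t) t$participant_id %in% retained, raw_topos)
  topo_long <- rbind(
    write_topographies(raw_topos),
    write_topographies(lapply(raw_topos, normalize_topography)),
    write_topographies(lapply(raw_topos, function(t)
      flip_topography(normalize_topography(t))))
  )
  table <- if (length(raw_topos))
    build_modeling_table(raw_topos, covariates = covariates) else NULL
  selection <- fit_main <- fit_moderation <- NULL
  if (run_models && !is.null(table) && "ados_css_total" %in% names(table)) {
    sel_args <- utils::modifyList(list(table = table, seed = seed), selection_args)
    selection <- do.call(cv_subset_selection, sel_args)
    fit_main <- fit_main_model(table, predictors = selection$selected)
    fit_moderation <- fit_moderation_model(table, predictors = selection$selected)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("infantfc")),
    synthetic = synthetic,
    seed = seed,
    parameters = list(epoch_s = epoch_s, overlap = overlap,
                      max_bad_fraction = max_bad_fraction,
                      min_epochs = min_epochs,
                      bands = lapply(bands, function(b) c(b$lo_hz, b$hi_hz))),
    n_participants = length(plist),
    n_retained = length(retained),
    exclusions = gate[!gate$retained, , drop = FALSE]
  )
  out <- list(counts = counts, gate = gate, topographies = topo_long,
              table = table, selection = selection, fit_main = fit_main,
              fit_moderation = fit_moderation, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(topo_long, file.path(out_dir, "topographies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(table))
      write_modeling_table(table, file.path(out_dir, "modeling_table.csv"))
    utils::write.csv(counts, file.path(out_dir, "epoch_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(gate, file.path(out_dir, "gate.csv"), row.names = FALSE)
    if (!is.null(selection))
      jsonlite::write_json(list(selected = selection$selected,
                                variable_frequency = as.list(selection$variable_frequency),
                                top_models = selection$top_models),
                           file.path(out_dir, "selection.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
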