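# Topographic pattern processing: vector normalization, flipping the pattern
# so every participant's maximum lies on the (arbitrarily chosen) right side,
# extraction of the Near-/Far-Connectivity modelling variables, and assembly
# of the participant-level modelling table.

#' Vector-normalize a raw topography
#'
#' Divides the 6 AoI scores by their Euclidean norm, so the pattern (not its
#' overall magnitude) is retained. An all-zero vector passes through
#' unchanged with a warning.
#'
#' @param topo A `condition_topography` with `form = "raw"` (any form is
#'   accepted; normalization is idempotent).
#' @param norm `"l2"` (default) or `"l1"`.
#' @return A `condition_topography` with `form = "normalized"`.
#' @export
normalize_topography <- function(topo, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  abort_if(!inherits(topo, "condition_topography"), "`topo` must be a condition_topography")
  v <- topo$values
  abort_if(!all(is.finite(v)), "non-finite topography values")
  nrm <- if (norm == "l2") sqrt(sum(v^2)) else sum(abs(v))
  if (nrm == 0) {
    warning("all-zero topography; normalization left it unchanged")
  } else {
    v <- v / nrm
  }
  out <- topo
  out$values <- v
  out$form <- "normalized"
  out
}

#' Flip a normalized topography so its maximum lies on the right
#'
#' If the global maximum of the normalized pattern lies in a left AoI, the
#' pattern is mirrored around the midline (left/right labels swapped at equal
#' steps). An exact tie between the left and right maxima leaves the pattern
#' unchanged. Applying the flip twice changes nothing.
#'
#' @param topo A `condition_topography` with `form = "normalized"` (or
#'   `"flipped"`, on which this is a no-op beyond re-checking).
#' @return A `condition_topography` with `form = "flipped"` and a logical
#'   `flipped` field recording whether mirroring occurred.
#' @export
flip_topography <- function(topo) {
  abort_if(!inherits(topo, "condition_topography"), "`topo` must be a condition_topography")
  abort_if(topo$form == "raw",
           "flip operates on normalized topographies; call normalize_topography() first")
  v <- topo$values
  half <- length(v) %/% 2
  do_flip <- max(v[seq_len(half)]) > max(v[half + seq_len(half)])
  out <- topo
  if (do_flip) {
    out$values <- stats::setNames(rev(v), names(v))
  }
  out$form <- "flipped"
  out$flipped <- do_flip
  out
}

#' Extract the Near- and Far-Connectivity scores from a flipped topography
#'
#' After flipping, the maxima side is the right side: Near-Connectivity is the
#' step-1 right AoI score and Far-Connectivity the step-3 right AoI score. The
#' step-2 AoI is deliberately skipped to minimize crosstalk between
#' neighbouring scalp regions.
#'
#' @param topo A `condition_topography` with `form = "flipped"`.
#' @return Named numeric vector `c(near = ..., far = ...)`.
#' @export
extract_near_far <- function(topo) {
  abort_if(!inherits(topo, "condition_topography"), "`topo` must be a condition_topography")
  abort_if(topo$form != "flipped", "Near/Far are read from the flipped form, got '",
           topo$form, "'")
  c(near = unname(topo$values["step1R"]),
    far = unname(topo$values[paste0("step", length(topo$values) %/% 2, "R")]))
}

#' Right-minus-left asymmetry of an unflipped normalized topography
#'
#' @param topo A `condition_topography` with `form = "normalized"` (unflipped,
#'   so hemispheric information is intact).
#' @param step Which step's asymmetry; default 3 (far-lateral).
#' @return `value(step R) - value(step L)`.
#' @export
asymmetry <- function(topo, step = 3L) {
  abort_if(!inherits(topo, "condition_topography"), "`topo` must be a condition_topography")
  abort_if(topo$form != "normalized",
           "asymmetry is defined on the unflipped normalized form, got '", topo$form, "'")
  r <- paste0("step", step, "R"); l <- paste0("step", step, "L")
  abort_if(!all(c(r, l) %in% names(topo$values)), "invalid step: ", step)
  unname(topo$values[r] - topo$values[l])
}

# Row-wise matrix versions of normalize/flip for whole-cohort batches
# (equivalent to the per-topography operations; used by the simulator and
# large property suites).
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

flip_rows <- function(m) {
  half <- ncol(m) %/% 2
  lmax <- do.call(pmax, as.data.frame(m[, seq_len(half), drop = FALSE]))
  rmax <- do.call(pmax, as.data.frame(m[, half + seq_len(half), drop = FALSE]))
  fl <- lmax > rmax
  m[fl, ] <- m[fl, rev(seq_len(ncol(m))), drop = FALSE]
  attr(m, "flipped") <- fl
  m
}

#' Modelling variable names
#'
#' The 12 connectivity variables: 3 bands x 2 stimuli x {near, far}, named
#' e.g. `theta_nonsocial_far`.
#'
#' @param bands,stimuli,positions Factors of the cross.
#' @return Character vector of variable names.
#' @export
modeling_variable_names <- function(bands = c("theta", "alpha", "gamma"),
                                    stimuli = c("social", "nonsocial"),
                                    positions = c("near", "far")) {
  as.vector(vapply(bands, function(b)
    vapply(stimuli, function(s) paste(b, s, positions, sep = "_"),
           character(length(positions))),
    character(length(stimuli) * length(positions))))
}

#' Assemble the participant-level modelling table
#'
#' Normalizes and flips each participant's raw topographies, extracts the 12
#' Near/Far variables, and joins the covariates/outcome columns.
#'
#' @param topos List of raw `condition_topography` objects (one per
#'   participant x band x stimulus).
#' @param covariates Data frame with column `participant` plus covariates
#'   (`sex` coded M=1/F=0, `likelihood` coded EL=1/LL=0, `age_5mo`, `group`,
#'   `ados_css_total`, optionally `gmls`).
#' @param use_normalized Use normalized-flipped scores (default) rather than
#'   raw-flipped.
#' @return Data frame, one row per participant with the 12 connectivity
#'   variables plus covariates.
#' @export
build_modeling_table <- function(topos, covariates = NULL, use_normalized = TRUE) {
  rows <- lapply(topos, function(t) {
    abort_if(t$form != "raw", "`topos` must contain raw topographies")
    fl <- flip_topography(normalize_topography(t))
    if (!use_normalized) {
      # same flip decision, applied to the raw scores
      v <- if (fl$flipped) stats::setNames(rev(t$values), names(t$values)) else t$values
      fl$values <- v
    }
    nf <- extract_near_far(fl)
    data.frame(participant = t$participant_id,
               variable = paste(t$band, t$stimulus, c("near", "far"), sep = "_"),
               value = unname(nf), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  wide <- stats::reshape(long, idvar = "participant", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  vars <- intersect(modeling_variable_names(), names(wide))
  wide <- wide[, c("participant", vars)]
  rownames(wide) <- NULL
  if (!is.null(covariates)) {
    abort_if(!"participant" %in% names(covariates),
             "`covariates` needs a participant column")
    wide <- merge(wide, covariates, by = "participant", sort = TRUE)
  }
  wide
}

#' Write a modelling table as CSV with a JSON schema sidecar
#'
#' @param table Modelling table from [build_modeling_table()].
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.schema.json`.
#' @return `path`, invisibly.
#' @export
write_modeling_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  schema <- list(
    columns = lapply(names(table), function(nm)
      list(name = nm, type = class(table[[nm]])[1])),
    connectivity_variables = intersect(modeling_variable_names(), names(table)),
    coding = list(sex = "M=1, F=0", likelihood = "EL=1, LL=0")
  )
  jsonlite::write_json(schema, sub("\\.[^.]*$", ".schema.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
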