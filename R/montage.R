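# Electrode montage handling and seed-anchored area-of-interest (AoI)
# construction. The occipital "visual cortex" electrode set is anchored on two
# midline seed electrodes (Oz, POz); every other selected electrode is binned,
# per hemisphere, into step-1/2/3 AoIs by Euclidean distance from the seed
# centroid.

#' Load an electrode layout from a coordinate file
#'
#' Reads a montage of labelled 3-D electrode positions (the common `.sfp`
#' dialect: whitespace-delimited `label x y z`, also accepted with commas) and
#' restricts it to the requested electrodes plus the seed electrodes.
#' Hemisphere is derived from the sign of the lateral coordinate
#' (negative = left, positive = right, |coord| < `lateral_tol` = midline).
#'
#' @param montage_file Path to the coordinate file.
#' @param selected_ids Character vector of electrode labels to retain
#'   (the lateral "visual cortex" electrodes).
#' @param seed_ids The two midline seed electrodes. Default `c("Oz", "POz")`.
#' @param lateral_axis Which coordinate column codes left/right. Default "x".
#' @param lateral_tol Absolute tolerance below which an electrode is midline.
#' @return An `electrode_layout` data frame with columns `electrode_id`, `x`,
#'   `y`, `z`, `hemisphere`, `is_seed`, and attribute `seed_ids`.
#' @examples
#' lay <- load_layout(default_montage(), default_selected_ids())
#' table(lay$hemisphere)
#' @export
load_layout <- function(montage_file, selected_ids,
                        seed_ids = c("Oz", "POz"),
                        lateral_axis = c("x", "y", "z"),
                        lateral_tol = 1e-9) {
  lateral_axis <- match.arg(lateral_axis)
  abort_if(!file.exists(montage_file), "montage file not found: ", montage_file)
  lines <- readLines(montage_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  # tolerate a header row ("label x y z" or similar)
  if (ncol(tab) >= 4 && !is.numeric(tab[[2]])) {
    tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, strip.white = TRUE)
  }
  abort_if(ncol(tab) < 4, "montage file must have columns label, x, y, z")
  tab <- tab[, 1:4]
  names(tab) <- c("electrode_id", "x", "y", "z")
  tab$electrode_id <- as.character(tab$electrode_id)
  dup <- unique(tab$electrode_id[duplicated(tab$electrode_id)])
  abort_if(length(dup) > 0, "duplicate electrode id(s) in montage: ",
           paste(dup, collapse = ", "))
  wanted <- unique(c(selected_ids, seed_ids))
  missing <- setdiff(wanted, tab$electrode_id)
  abort_if(length(missing) > 0, "electrode id(s) not found in montage: ",
           paste(missing, collapse = ", "))
  lay <- tab[match(wanted, tab$electrode_id), , drop = FALSE]
  abort_if(!all(is.finite(as.matrix(lay[, c("x", "y", "z")]))),
           "non-finite electrode coordinates")
  lat <- lay[[lateral_axis]]
  lay$hemisphere <- ifelse(abs(lat) < lateral_tol, "midline",
                           ifelse(lat < 0, "left", "right"))
  lay$is_seed <- lay$electrode_id %in% seed_ids
  abort_if(!all(lay$hemisphere[lay$is_seed] == "midline"),
           "seed electrodes must lie on the midline")
  rownames(lay) <- NULL
  structure(lay, seed_ids = seed_ids, class = c("electrode_layout", "data.frame"))
}

#' Assign non-seed electrodes to step-1..n areas of interest per hemisphere
#'
#' Per hemisphere, non-seed electrodes are ranked by Euclidean distance to the
#' centroid of the two seed electrodes and partitioned into `n_steps`
#' contiguous rank bins of as-equal-as-possible size, any remainder going to
#' the nearer bins (e.g. 11 electrodes, 3 steps -> sizes 4, 4, 3). Ties in
#' distance are broken by electrode id so the assignment is deterministic.
#'
#' @param layout An `electrode_layout` from [load_layout()].
#' @param seed_ids The two seed electrode labels; defaults to the layout's.
#' @param n_steps Number of distance bins per side. Default 3.
#' @return An `aoi_map`: list with `seed_ids`, `seed_centroid`, `n_steps`,
#'   `assignments` (data frame `electrode_id`, `side`, `step`, `distance`,
#'   `aoi`) and `aoi_levels` (the canonical ordering `step3L` ... `step3R`).
#' @examples
#' lay <- load_layout(default_montage(), default_selected_ids())
#' aoi <- assign_aois(lay)
#' table(aoi$assignments$aoi)
#' @export
assign_aois <- function(layout, seed_ids = attr(layout, "seed_ids"), n_steps = 3L) {
  abort_if(!inherits(layout, "electrode_layout"), "`layout` must be an electrode_layout")
  abort_if(length(seed_ids) != 2L, "exactly 2 seed electrodes are required")
  abort_if(n_steps < 1L, "`n_steps` must be >= 1")
  abort_if(!all(seed_ids %in% layout$electrode_id),
           "seed id(s) absent from layout: ",
           paste(setdiff(seed_ids, layout$electrode_id), collapse = ", "))
  seeds <- layout[layout$electrode_id %in% seed_ids, c("x", "y", "z")]
  centroid <- colMeans(seeds)
  nonseed <- layout[!layout$electrode_id %in% seed_ids, , drop = FALSE]
  mid <- nonseed$hemisphere == "midline"
  abort_if(any(mid),
           "non-seed midline electrode(s) cannot be assigned a side: ",
           paste(nonseed$electrode_id[mid], collapse = ", "))
  out <- list()
  for (side in c("left", "right")) {
    el <- nonseed[nonseed$hemisphere == side, , drop = FALSE]
    abort_if(nrow(el) < n_steps,
             "need at least ", n_steps, " non-seed electrodes on the ", side,
             " side, found ", nrow(el))
    d <- sqrt((el$x - centroid["x"])^2 + (el$y - centroid["y"])^2 +
                (el$z - centroid["z"])^2)
    ord <- order(d, el$electrode_id)  # id breaks exact distance ties
    sizes <- bin_sizes(nrow(el), n_steps)
    step <- rep(seq_len(n_steps), times = sizes)
    out[[side]] <- data.frame(
      electrode_id = el$electrode_id[ord],
      side = ifelse(side == "left", "L", "R"),
      step = step,
      distance = d[ord],
      stringsAsFactors = FALSE
    )
  }
  assignments <- rbind(out$left, out$right)
  assignments$aoi <- paste0("step", assignments$step, assignments$side)
  rownames(assignments) <- NULL
  structure(list(
    seed_ids = seed_ids,
    seed_centroid = centroid,
    n_steps = as.integer(n_steps),
    assignments = assignments,
    aoi_levels = aoi_levels(n_steps)
  ), class = "aoi_map")
}

# Bin m items into n contiguous bins, remainders to the first (nearer) bins.
bin_sizes <- function(m, n) {
  base <- m %/% n
  rem <- m %% n
  base + as.integer(seq_len(n) <= rem)
}

#' Canonical AoI ordering, far-left to far-right
#'
#' @param n_steps Number of steps per side.
#' @return Character vector, e.g. `c("step3L","step2L","step1L","step1R","step2R","step3R")`.
#' @export
aoi_levels <- function(n_steps = 3L) {
  c(paste0("step", rev(seq_len(n_steps)), "L"),
    paste0("step", seq_len(n_steps), "R"))
}

#' Export an AoI map as JSON
#'
#' @param aoi An `aoi_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aoi_map <- function(aoi, path) {
  abort_if(!inherits(aoi, "aoi_map"), "`aoi` must be an aoi_map")
  obj <- list(
    seed_ids = aoi$seed_ids,
    seed_centroid = as.list(aoi$seed_centroid),
    n_steps = aoi$n_steps,
    assignments = aoi$assignments[, c("electrode_id", "side", "step")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Path to the package's synthetic occipital montage
#'
#' A mirror-symmetric 26-electrode synthetic montage (24 lateral electrodes in
#' three distance rings per side plus midline seeds Oz and POz) shipped for
#' examples, tests and simulation. Coordinates are in centimetres on an
#' idealized head; this is a constructed stand-in layout, not a digitized net.
#'
#' @return File path to the `.sfp` montage.
#' @export
default_montage <- function() {
  system.file("extdata", "synthetic_occipital_montage.sfp",
              package = "infantfc", mustWork = TRUE)
}

#' Lateral electrode ids of the synthetic occipital montage
#'
#' @return Character vector of the 24 lateral electrode labels (`L01`..`L12`,
#'   `R01`..`R12`).
#' @export
default_selected_ids <- function() {
  c(sprintf("L%02d", 1:12), sprintf("R%02d", 1:12))
}

#' @export
print.aoi_map <- function(x, ...) {
  cat("AoI map:", nrow(x$assignments), "electrodes around seeds",
      paste(x$seed_ids, collapse = "/"), "\n")
  print(table(x$assignments$aoi)[x$aoi_levels])
  invisible(x)
}
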