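SPOT_COLUMNS <- c("spot_id", "slice_id", "x_um", "y_um", "depth_mm", "gs",
                  "ca", "fe", "ti", "si", "i372", "i373", "sn372", "sn373")

#' Construct a laser-spot table
#'
#' A spot table is the atomic input of the pipeline: one row per laser spot
#' of a mass-spectrometry-imaging (MSI) raster over a sediment thin section,
#' carrying position, depth below slice top, greyscale (GS, 0 = black,
#' 255 = white), elemental intensities (Ca, Fe, Ti, Si) and the intensities
#' and signal-to-noise ratios of the di- and tri-unsaturated C37 alkenones
#' used by the U37K' palaeothermometer.
#'
#' @param spots data frame with columns `spot_id`, `slice_id`, `x_um`,
#'   `y_um`, `depth_mm`, `gs`, `ca`, `fe`, `ti`, `si`, `i372`, `i373`,
#'   `sn372`, `sn373`.  Optional columns `delta_gs` and `background` are
#'   filled by [compute_delta_gs()].
#' @param slices data frame with one row per 5-cm slice: `slice_id`,
#'   `offset_cm_bsf` (composite depth of the slice top, cm below seafloor),
#'   `length_mm`, `width_mm`.
#' @return an object of class `spot_table`: a list with elements `spots`
#'   and `slices`.
#' @export
spot_table <- function(spots, slices) {
  spots <- as.data.frame(spots)
  slices <- as.data.frame(slices)
  missing_cols <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing_cols) > 0L) {
    stop("spot table format error: column(s) ", paste(missing_cols, collapse = ", "),
         " missing", call. = FALSE)
  }
  need_meta <- c("slice_id", "offset_cm_bsf", "length_mm", "width_mm")
  if (!all(need_meta %in% names(slices))) {
    stop("slice metadata must have columns ", paste(need_meta, collapse = ", "),
         call. = FALSE)
  }
  undeclared <- setdiff(unique(spots$slice_id), slices$slice_id)
  if (length(undeclared) > 0L) {
    stop("spots reference undeclared slice(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  for (col in c("ca", "fe", "ti", "si", "i372", "i373", "sn372", "sn373")) {
    bad <- which(spots[[col]] < 0)
    if (length(bad) > 0L) {
      stop("validation error: negative ", col, " for spot_id ",
           spots$spot_id[bad[1L]], call. = FALSE)
    }
  }
  if (any(spots$gs < 0 | spots$gs > 255)) {
    stop("validation error: gs outside [0, 255]", call. = FALSE)
  }
  len <- slices$length_mm[match(spots$slice_id, slices$slice_id)]
  if (any(spots$depth_mm < 0 | spots$depth_mm > len)) {
    stop("validation error: depth_mm outside [0, slice length]", call. = FALSE)
  }
  structure(list(spots = spots, slices = slices), class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat("spot_table:", nrow(x$spots), "spots in", nrow(x$slices), "slice(s)\n")
  if ("background" %in% names(x$spots)) {
    cat("  background-flagged spots:", sum(x$spots$background), "\n")
  }
  invisible(x)
}

#' Read or write a spot table
#'
#' Spot tables are stored as tab-separated text with a header line and the
#' slice metadata embedded as structured comment lines
#' (`# slice <id> <offset_cm_bsf> <length_mm> <width_mm>`), so that one
#' file round-trips the complete object.
#'
#' @param path file path.
#' @param table a [spot_table()] (write only).
#' @return `read_spot_table` returns a `spot_table`;
#'   `write_spot_table` returns `path` invisibly.
#' @export
read_spot_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# slice\\b", lines, value = TRUE)
  if (length(meta_lines) == 0L) {
    stop("spot table format error: no '# slice' metadata lines", call. = FALSE)
  }
  meta <- do.call(rbind, lapply(strsplit(sub("^# slice\\s+", "", meta_lines),
                                         "\t"), function(f) {
    data.frame(slice_id = f[1L], offset_cm_bsf = as.numeric(f[2L]),
               length_mm = as.numeric(f[3L]), width_mm = as.numeric(f[4L]),
               stringsAsFactors = FALSE)
  }))
  body <- lines[!grepl("^#", lines)]
  spots <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing_cols) > 0L) {
    stop("spot table format error: ", paste(missing_cols, collapse = ", "),
         " missing", call. = FALSE)
  }
  spot_table(spots[, union(SPOT_COLUMNS, names(spots))], meta)
}

#' @rdname read_spot_table
#' @export
write_spot_table <- function(table, path) {
  stopifnot(inherits(table, "spot_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(table$slices))) {
    s <- table$slices[i, ]
    writeLines(sprintf("# slice\t%s\t%.15g\t%.15g\t%.15g", s$slice_id,
                       s$offset_cm_bsf, s$length_mm, s$width_mm), con)
  }
  cols <- union(SPOT_COLUMNS, names(table$spots))
  utils::write.table(table$spots[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Correct spot depths for lamina tilt
#'
#' Laminae in sediment sub-cores can be tilted relative to the slice axis.
#' Tie points digitised on individual laminae (a minimum of four per lamina,
#' spanning the slice width) define, by linear interpolation across the
#' lateral coordinate, a lamina-surface depth offset at every x; each spot's
#' depth is shifted by the negative of the offset of the nearest lamina
#' surface above it (falling back to the nearest surface overall near the
#' slice ends), flattening the laminae to iso-depth.
#'
#' @param table a [spot_table()].
#' @param tiepoints data frame with columns `lamina_id`, `slice_id`, `x_um`,
#'   `depth_mm`; at least four points per lamina, x strictly increasing.
#' @return the corrected `spot_table` (column `depth_mm` updated; original
#'   stored as `depth_mm_raw` if not yet present).
#' @export
correct_tilt <- function(table, tiepoints) {
  stopifnot(inherits(table, "spot_table"))
  tiepoints <- as.data.frame(tiepoints)
  need <- c("lamina_id", "slice_id", "x_um", "depth_mm")
  stopifnot(all(need %in% names(tiepoints)))
  counts <- table(tiepoints$lamina_id)
  if (any(counts < 4L)) {
    stop("validation error: a minimum of four tie points per lamina is ",
         "required (lamina ", names(counts)[which(counts < 4L)[1L]],
         " has ", min(counts), ")", call. = FALSE)
  }
  spots <- table$spots
  if (!"depth_mm_raw" %in% names(spots)) spots$depth_mm_raw <- spots$depth_mm
  for (sid in unique(spots$slice_id)) {
    tp_s <- tiepoints[tiepoints$slice_id == sid, , drop = FALSE]
    if (nrow(tp_s) == 0L) next
    idx <- which(spots$slice_id == sid)
    laminae <- split(tp_s, tp_s$lamina_id)
    # per lamina: reference depth (mean of tie points) and interpolated
    # surface depth at each spot x; rule = 2 holds the end offsets constant
    ref <- vapply(laminae, function(l) mean(l$depth_mm), numeric(1L))
    surf <- vapply(laminae, function(l) {
      ord <- order(l$x_um)
      if (any(diff(l$x_um[ord]) <= 0)) {
        stop("validation error: tie-point x must be strictly increasing ",
             "within a lamina", call. = FALSE)
      }
      stats::approx(l$x_um[ord], l$depth_mm[ord], xout = spots$x_um[idx],
                    rule = 2)$y
    }, numeric(length(idx)))
    surf <- matrix(surf, nrow = length(idx))
    # nearest lamina surface above the spot (smaller depth); if none, nearest
    d <- spots$depth_mm[idx]
    gap <- d - surf                       # >= 0 where the surface is above
    pick <- apply(gap, 1L, function(g) {
      above <- which(g >= 0)
      if (length(above) > 0L) above[which.min(g[above])] else which.min(abs(g))
    })
    offset <- surf[cbind(seq_along(idx), pick)] - ref[pick]
    spots$depth_mm[idx] <- d - offset
  }
  table$spots <- spots
  table
}

#' Age-depth model from control points
#'
#' @param depth_cm_bsf numeric, composite depth (cm below seafloor),
#'   strictly increasing.
#' @param age_kyr_b2k numeric, age in kyr before 2000 AD, strictly
#'   increasing with depth (deeper is older).
#' @return object of class `age_depth_model`.
#' @export
age_depth_model <- function(depth_cm_bsf, age_kyr_b2k) {
  stopifnot(length(depth_cm_bsf) == length(age_kyr_b2k),
            length(depth_cm_bsf) >= 2L)
  if (any(diff(depth_cm_bsf) <= 0)) {
    stop("age model control depths must be strictly increasing", call. = FALSE)
  }
  if (any(diff(age_kyr_b2k) <= 0)) {
    stop("age must increase strictly with depth (deeper = older)",
         call. = FALSE)
  }
  structure(list(depth_cm_bsf = as.numeric(depth_cm_bsf),
                 age_kyr_b2k = as.numeric(age_kyr_b2k)),
            class = "age_depth_model")
}

#' Convert composite depth to age
#'
#' Piecewise-linear interpolation through the age-model control points.
#' Queries outside the control range are refused: no extrapolation.
#'
#' @param model an [age_depth_model()].
#' @param depth_cm_bsf numeric vector of composite depths.
#' @return ages in kyr b2k.
#' @export
depth_to_age <- function(model, depth_cm_bsf) {
  stopifnot(inherits(model, "age_depth_model"))
  rng <- range(model$depth_cm_bsf)
  out <- which(depth_cm_bsf < rng[1L] | depth_cm_bsf > rng[2L])
  if (length(out) > 0L) {
    stop(sprintf("range error: depth %.4g cm outside age model [%.4g, %.4g]",
                 depth_cm_bsf[out[1L]], rng[1L], rng[2L]), call. = FALSE)
  }
  stats::approx(model$depth_cm_bsf, model$age_kyr_b2k,
                xout = depth_cm_bsf)$y
}

#' Composite depth of each spot
#'
#' Slice offset (cm bsf) plus within-slice (tilt-corrected) depth.
#'
#' @param table a [spot_table()].
#' @return numeric vector, cm below seafloor, one per spot.
#' @export
spot_composite_depth <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  i <- match(table$spots$slice_id, table$slices$slice_id)
  table$slices$offset_cm_bsf[i] + table$spots$depth_mm / 10
}

#' Greyscale normalisation and background exclusion
#'
#' Flags spots with very low greyscale (areas devoid of sediment imaged as
#' black background) and computes `delta_gs`, the difference between a
#' spot's greyscale and the median greyscale of the non-background spots of
#' its slice.  Negative `delta_gs` marks darker-than-typical sediment,
#' positive lighter.
#'
#' @param table a [spot_table()].
#' @param background_gs_max greyscale at or below which a spot is flagged as
#'   background and excluded from all downstream statistics (default 30).
#' @return the `spot_table` with columns `background` and `delta_gs` filled
#'   (`delta_gs` is `NA` for background spots).
#' @export
compute_delta_gs <- function(table, background_gs_max = 30) {
  stopifnot(inherits(table, "spot_table"))
  spots <- table$spots
  spots$background <- spots$gs <= background_gs_max
  spots$delta_gs <- NA_real_
  for (sid in unique(spots$slice_id)) {
    in_slice <- spots$slice_id == sid
    keep <- in_slice & !spots$background
    if (!any(keep)) {
      stop("validation error: slice ", sid, " has no non-background spots",
           call. = FALSE)
    }
    med <- stats::median(spots$gs[keep])
    spots$delta_gs[keep] <- spots$gs[keep] - med
  }
  table$spots <- spots
  table
}
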