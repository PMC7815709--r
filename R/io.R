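#' Read an ICP trace from CSV
#'
#' Expects a header `time_min,icp_mmhg`. Time must be strictly
#' increasing; the first offending row is named in the error. Decimal
#' commas are rejected explicitly: the file must use `.` as the decimal
#' separator.
#'
#' @param path CSV file path.
#' @param infusion_start Infusion start time (min).
#' @param infusion_rate Infusion rate (uL/min).
#' @return An [icp_trace()].
#' @export
read_icp_trace <- function(path, infusion_start, infusion_rate) {
  d <- utils::read.csv(path, colClasses = "character",
                       stringsAsFactors = FALSE)
  need <- c("time_min", "icp_mmhg")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  for (col in need) {
    if (any(grepl(",", d[[col]], fixed = TRUE)))
      stop("column ", col, " contains ',': decimal commas are not ",
           "supported, use '.' as the decimal separator")
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column ", col, " at row ",
           which(is.na(v))[1L])
    d[[col]] <- v
  }
  bad <- which(diff(d$time_min) <= 0)
  if (length(bad))
    stop("time_min not strictly increasing at row ", bad[1L] + 1L)
  icp_trace(d$time_min, d$icp_mmhg, infusion_start, infusion_rate)
}

#' Write an ICP trace to CSV
#'
#' Full double precision, lossless round trip with [read_icp_trace()].
#'
#' @param trace An [icp_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_icp_trace <- function(trace, path) {
  stopifnot(inherits(trace, "icp_trace"))
  d <- data.frame(time_min = format(trace$time, digits = 17,
                                    scientific = FALSE, trim = TRUE),
                  icp_mmhg = format(trace$pressure, digits = 17,
                                    scientific = FALSE, trim = TRUE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traced cell geometry and organelles from JSON
#'
#' Schema: `cells: [{id, apical: [[x,y],...], basal: [[x,y],...],
#' region: [[x,y],...]}]` and `mitochondria: [{cell_id, centroid: [x,y],
#' area}]`. All invariants are validated: polyline lengths, referential
#' integrity of `cell_id`, and centroid containment in the parent cell
#' region.
#'
#' @param path JSON file path.
#' @return A list with `cells` (named list of [cell_outline()]) and
#'   `mitos` (data frame: `cell_id`, `x`, `y`, `area`).
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  if (is.null(g$cells)) stop("geometry file has no 'cells' entry")
  to_mat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    matrix(as.numeric(x), ncol = 2L)
  }
  cl <- g$cells
  cells <- list()
  for (k in seq_along(cl$id)) {
    cells[[cl$id[k]]] <- cell_outline(
      to_mat(cl$apical[[k]]), to_mat(cl$basal[[k]]),
      to_mat(cl$region[[k]]), id = cl$id[k])
  }
  mt <- g$mitochondria
  if (is.null(mt) || !length(mt)) {
    mitos <- data.frame(cell_id = character(0), x = numeric(0),
                        y = numeric(0), area = numeric(0))
  } else {
    cen <- to_mat(mt$centroid)
    mitos <- data.frame(cell_id = mt$cell_id, x = cen[, 1L],
                        y = cen[, 2L], area = as.numeric(mt$area),
                        stringsAsFactors = FALSE)
    orphan <- setdiff(mitos$cell_id, names(cells))
    if (length(orphan))
      stop("organelles reference unknown cells: ",
           paste(orphan, collapse = ", "))
    if (any(mitos$area <= 0)) stop("organelle areas must be > 0")
    for (k in seq_len(nrow(mitos))) {
      if (!point_in_polygon(c(mitos$x[k], mitos$y[k]),
                            cells[[mitos$cell_id[k]]]$region))
        stop("organelle ", k, " lies outside its cell region (",
             mitos$cell_id[k], ")")
    }
  }
  list(cells = cells, mitos = mitos)
}

#' Write cell geometry and organelles to JSON
#'
#' Inverse of [read_geometry()]; full double precision.
#'
#' @param cells Named list of [cell_outline()] objects.
#' @param mitos Data frame with `cell_id`, `x`, `y`, `area` (may be
#'   empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(cells, mitos, path) {
  obj <- list(
    cells = lapply(unname(cells), function(cl)
      list(id = cl$id, apical = cl$apical, basal = cl$basal,
           region = cl$region)),
    mitochondria = if (nrow(mitos)) lapply(seq_len(nrow(mitos)),
      function(k) list(cell_id = mitos$cell_id[k],
                       centroid = c(mitos$x[k], mitos$y[k]),
                       area = mitos$area[k]))
      else list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a swelling timecourse table from CSV
#'
#' Header `animal_id,cell_id,time_min,volume`; volumes must be positive.
#'
#' @param path CSV file path.
#' @return Data frame for [per_animal_swelling()].
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "cell_id", "time_min", "volume")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!is.numeric(d$time_min) || !is.numeric(d$volume))
    stop("time_min and volume must be numeric")
  if (any(d$volume <= 0)) stop("volumes must be > 0")
  d
}

#' Read a group-volume table from CSV
#'
#' Header `group,animal_id,volume_mm3`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `group`, `volume` for
#'   [group_volume_summary()].
#' @export
read_group_volumes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "volume_mm3")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!is.numeric(d$volume_mm3) || any(d$volume_mm3 <= 0))
    stop("volume_mm3 must be positive numeric")
  data.frame(group = d$group, volume = d$volume_mm3,
             stringsAsFactors = FALSE)
}

#' Convert infusion rates between uL/min and mL/min
#'
#' The model itself works in uL/min throughout; conversion is offered at
#' the I/O boundary only.
#'
#' @param x Rate value(s).
#' @param from,to `"uL/min"` or `"mL/min"`.
#' @return Converted value(s).
#' @export
convert_rate <- function(x, from = c("uL/min", "mL/min"),
                         to = c("uL/min", "mL/min")) {
  from <- match.arg(from); to <- match.arg(to)
  fac <- c("uL/min" = 1, "mL/min" = 1000)
  x * fac[[from]] / fac[[to]]
}
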