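soil_properties <- function() {
  c("pH", "TOC", "TON", "CN", "MBC", "MBN", "AP",
    "ExchK", "ExchCa", "ExchMg", "ExchNa")
}

#' Assign chronosequence age groups
#'
#' Bins stand ages into the four co-occurrence network groups: adjacent
#' forest (`F`), young stands (`Y3_20`), middle-aged stands (`Y40_50`) and
#' old stands (`Y90`). The default bin edges place stands of age <=
#' `breaks[1]` in `Y3_20`, ages in `(breaks[1], breaks[2]]` in `Y40_50`,
#' and older stands in `Y90`; forest samples are always `F` regardless of
#' age. Edges are configurable because the group membership of
#' intermediate ages (e.g. a 21-year stand) is a study design choice.
#'
#' @param stand_age numeric years since conversion (NA allowed for forest).
#' @param land_use `"tea"` or `"forest"`.
#' @param breaks two increasing bin edges, default `c(21, 69)`.
#' @return factor with levels `F`, `Y3_20`, `Y40_50`, `Y90`.
#' @export
assign_age_group <- function(stand_age, land_use, breaks = c(21, 69)) {
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2])
  land_use <- as.character(land_use)
  if (!all(land_use %in% c("tea", "forest"))) {
    stop("land_use must be 'tea' or 'forest'")
  }
  grp <- ifelse(land_use == "forest", "F",
         ifelse(stand_age <= breaks[1], "Y3_20",
         ifelse(stand_age <= breaks[2], "Y40_50", "Y90")))
  if (anyNA(grp)) stop("tea samples must have a stand_age")
  factor(grp, levels = age_group_levels())
}

age_group_levels <- function() c("F", "Y3_20", "Y40_50", "Y90")

#' Construct a per-sample metadata frame
#'
#' Joins design metadata (site, stand age, land use, plot) with soil
#' physicochemical properties and derives the age group.
#'
#' @param sample_id unique sample identifiers.
#' @param site site code, e.g. `TRI`, `HZ`, `JL`.
#' @param stand_age years since conversion; `NA` or 0 only for forest.
#' @param land_use `"tea"` or `"forest"`.
#' @param plot plot label within the stand.
#' @param soil data.frame (one row per sample) with any of the columns
#'   `pH, TOC, TON, CN, MBC, MBN, AP, ExchK, ExchCa, ExchMg, ExchNa`
#'   (units: pH unitless; TOC/TON g kg-1; MBC/MBN/AP/Exch* mg kg-1).
#' @param age_group_breaks passed to [assign_age_group()].
#' @return data.frame of class `sample_frame`.
#' @export
sample_frame <- function(sample_id, site, stand_age, land_use, plot,
                         soil = NULL, age_group_breaks = c(21, 69)) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample id: ", sample_id[duplicated(sample_id)][1L])
  }
  land_use <- as.character(land_use)
  stand_age <- as.numeric(stand_age)
  if (any(land_use == "forest" & !is.na(stand_age) & stand_age > 0)) {
    stop("forest samples cannot have a positive stand_age")
  }
  if (any(land_use == "tea" & (is.na(stand_age) | stand_age <= 0))) {
    stop("tea samples must have a positive stand_age")
  }
  out <- data.frame(
    sample_id = sample_id, site = as.character(site),
    stand_age = ifelse(land_use == "forest", 0, stand_age),
    land_use = land_use, plot = as.character(plot),
    age_group = assign_age_group(stand_age, land_use, age_group_breaks),
    stringsAsFactors = FALSE)
  if (!is.null(soil)) {
    soil <- as.data.frame(soil)
    known <- intersect(names(soil), soil_properties())
    for (p in known) {
      v <- as.numeric(soil[[p]])
      if (p == "pH") {
        if (any(!is.na(v) & (v <= 0 | v >= 14))) {
          stop("pH outside (0, 14) for sample ",
               sample_id[which(v <= 0 | v >= 14)[1L]])
        }
      } else if (any(!is.na(v) & v < 0)) {
        stop(p, " negative for sample ", sample_id[which(v < 0)[1L]])
      }
      out[[p]] <- v
    }
  }
  class(out) <- c("sample_frame", "data.frame")
  out
}

#' Read sample metadata and soil properties from TSV files
#'
#' @param metadata_path TSV with columns `sample_id, site, stand_age,
#'   land_use, plot` (stand_age may be empty for forest).
#' @param soil_path optional TSV with `sample_id` plus soil property
#'   columns; must cover exactly the metadata samples.
#' @param age_group_breaks passed to [assign_age_group()].
#' @return a [sample_frame()].
#' @export
read_sample_frame <- function(metadata_path, soil_path = NULL,
                              age_group_breaks = c(21, 69)) {
  md <- utils::read.delim(metadata_path, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "site", "stand_age", "land_use", "plot")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  soil <- NULL
  if (!is.null(soil_path)) {
    soil <- utils::read.delim(soil_path, sep = "\t",
                              stringsAsFactors = FALSE)
    off <- union(setdiff(soil$sample_id, md$sample_id),
                 setdiff(md$sample_id, soil$sample_id))
    if (length(off)) {
      stop("unmatched sample id(s) between metadata and soil table: ",
           paste(off, collapse = ", "))
    }
    soil <- soil[match(md$sample_id, soil$sample_id), , drop = FALSE]
  }
  sample_frame(md$sample_id, md$site, md$stand_age, md$land_use, md$plot,
               soil = soil, age_group_breaks = age_group_breaks)
}

#' @rdname read_sample_frame
#' @param x a [sample_frame()].
#' @param path output TSV path (metadata and soil columns together).
#' @export
write_sample_frame <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
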