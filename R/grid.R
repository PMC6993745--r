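## The specification grid: every theoretically defensible analytical path.

ctrl_abbrev <- c("demographics" = "dem",
                 "demographics+child" = "dem_child",
                 "demographics+mother" = "dem_mother",
                 "demographics+family" = "dem_family",
                 "all" = "all")

#' Enumerate all specifications
#'
#' Full Cartesian product of the four analytical decisions: day type (2),
#' sleep measure (3), technology measure (4) and control set (5) --- 120
#' specifications, 60 per day type. A "no controls" option is deliberately
#' absent: simple controls are routinely included in epidemiological work, so
#' an uncontrolled model is not considered a defensible path. The ordering is
#' stable and `spec_id` is a deterministic label.
#'
#' @return Data frame of class `sca_grid` with columns `spec_id`, `day_type`,
#'   `sleep_measure`, `tech_measure`, `control_set`.
#' @examples
#' nrow(build_grid())  # 120
#' @export
build_grid <- function() {
  g <- expand.grid(control_set = control_sets,
                   tech_measure = tech_measures,
                   sleep_measure = sleep_measures,
                   day_type = day_types,
                   stringsAsFactors = FALSE)
  g <- g[, c("day_type", "sleep_measure", "tech_measure", "control_set")]
  g$spec_id <- paste(g$day_type, g$sleep_measure, g$tech_measure,
                     ctrl_abbrev[g$control_set], sep = ".")
  g <- g[, c("spec_id", "day_type", "sleep_measure", "tech_measure",
             "control_set")]
  rownames(g) <- NULL
  class(g) <- c("sca_grid", "data.frame")
  g
}

#' Filter a specification grid
#'
#' Order-preserving subset by field values or an arbitrary predicate.
#'
#' @param grid An `sca_grid` (or compatible data frame).
#' @param ... Named filters, e.g. `day_type = "weekday"`,
#'   `tech_measure = c("participation", "bedtime_use")`. Unknown field names
#'   are an error.
#' @param predicate Optional function taking the grid data frame and
#'   returning a logical vector.
#' @return The filtered grid (class preserved).
#' @export
subset_grid <- function(grid, ..., predicate = NULL) {
  filters <- list(...)
  fields <- c("spec_id", "day_type", "sleep_measure", "tech_measure",
              "control_set")
  unknown <- setdiff(names(filters), fields)
  if (length(unknown) > 0)
    validation_error(paste("unknown grid field(s):",
                           paste(unknown, collapse = ", ")))
  keep <- rep(TRUE, nrow(grid))
  for (f in names(filters)) keep <- keep & grid[[f]] %in% filters[[f]]
  if (!is.null(predicate)) keep <- keep & predicate(as.data.frame(grid))
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
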