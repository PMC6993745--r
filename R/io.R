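## Plain-text interchange: cohort / diary / derived-measure CSVs and the flat
## key = value configuration dialect used by the command line.

#' Write and read cohort tables
#'
#' Cohort CSVs use an empty field for missing values; the column dictionary
#' is the cohort layout documented in [generate_cohort()]. Diaries travel in
#' long form (`person_id`, `day_type`, `slot` 1--144, `code`).
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_*` return the path invisibly; `read_*` return the object.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(person_id = "character"))
}

#' @rdname write_cohort_csv
#' @param diaries List of diary matrices (as in `sca_cohort$diaries`).
#' @export
diaries_to_long <- function(diaries) {
  parts <- list()
  for (d in names(diaries)) {
    mat <- diaries[[d]]
    if (is.null(mat) || nrow(mat) == 0) next
    parts[[d]] <- data.frame(
      person_id = rep(rownames(mat), times = n_slots),
      day_type = d,
      slot = rep(seq_len(n_slots), each = nrow(mat)),
      code = as.vector(mat),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$person_id, out$day_type, out$slot), ]
  rownames(out) <- NULL
  out
}

#' @rdname write_cohort_csv
#' @param long Long diary data frame from [diaries_to_long()].
#' @export
diaries_from_long <- function(long) {
  out <- list()
  for (d in unique(long$day_type)) {
    sub <- long[long$day_type == d, ]
    ids <- sort(unique(sub$person_id))
    mat <- matrix(NA_character_, length(ids), n_slots,
                  dimnames = list(ids, NULL))
    mat[cbind(match(sub$person_id, ids), sub$slot)] <- sub$code
    if (anyNA(mat)) validation_error("diary long table has missing slots")
    out[[d]] <- mat
  }
  out
}

#' @rdname write_cohort_csv
#' @export
write_diaries_csv <- function(diaries, path) {
  write.csv(diaries_to_long(diaries), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_diaries_csv <- function(path) {
  diaries_from_long(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(person_id = "character")))
}

## Flat configuration dialect ---------------------------------------------
##
## One `key = value` pair per line; `#` starts a comment; dots nest keys
## (`true_effects.weekday.time_spent_diary = -0.1`); values are parsed as
## logical, numeric, or string. Unknown keys are an error so typos cannot
## silently fall back to defaults.

parse_flat_value <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "TRUE", "yes")) return(TRUE)
  if (s %in% c("false", "FALSE", "no")) return(FALSE)
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  gsub('^"|"$', "", s)
}

#' Read a flat key = value configuration file
#'
#' @param path File path.
#' @return Nested named list.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) config_error(paste("malformed config line:", ln))
    key <- trimws(kv[1])
    val <- parse_flat_value(paste(kv[-1], collapse = "="))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_nested(out, parts, val)
  }
  out
}

assign_nested <- function(lst, parts, val) {
  if (length(parts) == 1) {
    lst[[parts]] <- val
    return(lst)
  }
  head <- parts[1]
  if (is.null(lst[[head]])) lst[[head]] <- list()
  lst[[head]] <- assign_nested(lst[[head]], parts[-1], val)
  lst
}

#' Build a generator configuration from a flat config list
#'
#' Keys mirror the arguments of [generator_config()]; nested keys address
#' day types and pathways (e.g. `participation_prob.weekday`,
#' `true_effects.weekend.time_spent_retro`). Unknown top-level keys raise a
#' configuration error naming the key.
#'
#' @param overrides Nested list, typically from [read_flat_config()].
#' @return An `sca_config`.
#' @export
config_from_list <- function(overrides = list()) {
  defaults <- formals(generator_config)
  known <- names(defaults)
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0)
    config_error(paste("unknown configuration key(s):",
                       paste(unknown, collapse = ", ")))
  args <- list()
  for (k in names(overrides)) {
    v <- overrides[[k]]
    if (k %in% c("participation_prob", "bedtime_use_prob")) {
      base <- eval(defaults[[k]])
      for (d in names(v)) base[[d]] <- v[[d]]
      args[[k]] <- base
    } else if (k %in% c("digital_hours", "sleep_onset", "wake_diary")) {
      base <- eval(defaults[[k]])
      for (d in names(v)) for (f in names(v[[d]]))
        base[[d]][[f]] <- v[[d]][[f]]
      args[[k]] <- base
    } else if (k == "true_effects") {
      base <- zero_effects()
      for (d in names(v)) for (m in names(v[[d]]))
        base[[d]][[m]] <- v[[d]][[m]]
      args[[k]] <- base
    } else if (k == "missingness_rates") {
      base <- default_missingness()
      for (b in names(v)) base[[b]] <- v[[b]]
      args[[k]] <- base
    } else {
      args[[k]] <- v
    }
  }
  do.call(generator_config, args)
}
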