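.map_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png", csv = "csv", rds = "rds",
         stop("cannot guess map format from extension: ", path))
}

#' Read a sensation drawing from disk
#'
#' Supported formats: single-channel 8-bit PNG (values scaled to
#' \[0, 1\] by 1/255), CSV matrices (values taken verbatim), and RDS — a
#' compressed binary matrix container with a bit-exact round trip.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"png"`, `"csv"` or `"rds"`.
#' @return numeric matrix of non-negative intensities.
#' @export
read_map <- function(path, format = c("auto", "png", "csv", "rds")) {
  format <- .map_format(path, match.arg(format))
  if (!file.exists(path)) stop("map file not found: ", path)
  m <- switch(format,
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L)
        stop("multi-channel PNG not supported; drawings must be single-channel")
      img
    },
    csv = as.matrix(read.table(path, sep = ",", header = FALSE)),
    rds = readRDS(path))
  if (!is.numeric(m) || !is.matrix(m)) stop("map file did not parse to a numeric matrix: ", path)
  dimnames(m) <- NULL
  if (anyNA(m)) stop("map contains missing values: ", path)
  if (any(m < 0)) stop("negative intensity in map: ", path)
  m
}

#' Write a sensation drawing to disk
#'
#' CSV and RDS round trips are bit-exact (CSV values are written with 17
#' significant digits); PNG is quantized to 8 bits, so a read-back agrees
#' within 1/255 and requires values in \[0, 1\].
#'
#' @param m non-negative numeric matrix.
#' @inheritParams read_map
#' @return `path`, invisibly.
#' @export
write_map <- function(m, path, format = c("auto", "png", "csv", "rds")) {
  format <- .map_format(path, match.arg(format))
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (anyNA(m)) stop("map contains NA/NaN values")
  if (any(m < 0)) stop("negative intensity")
  switch(format,
    png = {
      if (max(m) > 1) stop("PNG maps require values in [0, 1]")
      png::writePNG(m, path)
    },
    csv = {
      txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
      write.table(txt, path, sep = ",", row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
    },
    rds = saveRDS(m, path))
  invisible(path)
}

.session_key <- function(session_kind, stimulus_type, stimulus_location) {
  if (identical(session_kind, "baseline")) "baseline"
  else paste(stimulus_type, stimulus_location, sep = ":")
}

#' Construct a single-session sensation map
#'
#' One subject's drawing for one session, plus session metadata. Values
#' are non-negative intensities on the template canvas; pixels outside the
#' template mask are zeroed when a template is supplied. A stimulation
#' session must name its stimulus type and location; a baseline session
#' carries neither.
#'
#' @param values non-negative numeric matrix.
#' @param subject_id subject identifier.
#' @param session_kind `"baseline"` or `"stimulation"`.
#' @param stimulus_type e.g. `"acupuncture"` or `"tactile"` (stimulation only).
#' @param stimulus_location e.g. `"HT7"`, `"PC6"`, `"ST36"`, `"SP10"`.
#' @param normalized whether values have been unit-range normalized.
#' @param template optional [body_template()] used to mask and shape-check.
#' @return object of class `bsm_map`.
#' @export
sensation_map <- function(values, subject_id, session_kind = c("baseline", "stimulation"),
                          stimulus_type = NULL, stimulus_location = NULL,
                          normalized = FALSE, template = NULL) {
  session_kind <- match.arg(session_kind)
  if (!is.matrix(values) || !is.numeric(values)) stop("values must be a numeric matrix")
  if (anyNA(values)) stop("values contain NA")
  if (any(values < 0)) stop("negative intensity")
  if (session_kind == "stimulation") {
    if (is.null(stimulus_type) || is.null(stimulus_location))
      stop("stimulation session requires stimulus_type and stimulus_location")
  } else if (!is.null(stimulus_type) || !is.null(stimulus_location)) {
    stop("baseline session must not carry stimulus_type/stimulus_location")
  }
  if (!is.null(template)) {
    if (!identical(dim(values), dim(template$mask)))
      stop("map shape does not match template")
    values[!template$mask] <- 0
  }
  structure(list(values = values, subject_id = as.character(subject_id),
                 session_kind = session_kind,
                 stimulus_type = stimulus_type,
                 stimulus_location = stimulus_location,
                 normalized = isTRUE(normalized)),
            class = "bsm_map")
}

#' @export
print.bsm_map <- function(x, ...) {
  cat(sprintf("<bsm_map> subject %s, %s%s, %dx%d, max %.3g%s\n",
              x$subject_id, x$session_kind,
              if (x$session_kind == "stimulation")
                sprintf(" (%s at %s)", x$stimulus_type, x$stimulus_location) else "",
              nrow(x$values), ncol(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

map_key <- function(map) {
  .session_key(map$session_kind, map$stimulus_type, map$stimulus_location)
}

#' Assemble a study dataset
#'
#' @param template a [body_template()].
#' @param maps list of [sensation_map()] objects (all sharing the template
#'   shape; at most one baseline per subject; subject x session keys unique).
#' @param questionnaire optional long-format data.frame with columns
#'   `subject_id`, `stimulus_type`, `stimulus_location`, `item` (1..13),
#'   `score` (0..3).
#' @param provenance free-text description of where the data came from.
#' @return object of class `bsm_study`. Maps are stored in a named list
#'   keyed `subject|session`, sorted by key, so assembly is independent of
#'   input order.
#' @export
study_dataset <- function(template, maps, questionnaire = NULL,
                          provenance = "unspecified") {
  stopifnot(inherits(template, "bsm_template"))
  keys <- character(length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    stopifnot(inherits(m, "bsm_map"))
    if (!identical(dim(m$values), dim(template$mask)))
      stop("map shape does not match template (subject ", m$subject_id, ")")
    m$values[!template$mask] <- 0
    maps[[i]] <- m
    keys[i] <- paste(m$subject_id, map_key(m), sep = "|")
  }
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys)][1]
    if (grepl("\\|baseline$", d)) stop("two baseline maps for subject ", sub("\\|.*", "", d))
    stop("duplicate session key: ", d)
  }
  names(maps) <- keys
  maps <- maps[order(keys)]
  if (!is.null(questionnaire)) questionnaire <- .check_questionnaire(questionnaire)
  structure(list(template = template, maps = maps,
                 questionnaire = questionnaire, provenance = provenance),
            class = "bsm_study")
}

.check_questionnaire <- function(q) {
  need <- c("subject_id", "stimulus_type", "stimulus_location", "item", "score")
  if (!all(need %in% names(q))) stop("questionnaire must have columns: ",
                                     paste(need, collapse = ", "))
  if (any(q$score < 0 | q$score > 3)) stop("questionnaire scores must be in 0..3")
  if (any(q$score != round(q$score)))
    warning("non-integer questionnaire scores accepted (scale is ordinal 0..3)")
  if (any(q$item < 1 | q$item > 13 | q$item != round(q$item)))
    stop("questionnaire item ids must be integers 1..13")
  q
}

#' @export
print.bsm_study <- function(x, ...) {
  cat(sprintf("<bsm_study> %d maps, %d subjects, %s questionnaire rows (%s)\n",
              length(x$maps), length(study_subjects(x)),
              if (is.null(x$questionnaire)) "no" else nrow(x$questionnaire),
              x$provenance))
  invisible(x)
}

#' @rdname study_dataset
#' @param dataset a `bsm_study`.
#' @export
study_subjects <- function(dataset) {
  unique(vapply(dataset$maps, function(m) m$subject_id, character(1)))
}

#' Fetch one subject's map for a session
#'
#' @param dataset a `bsm_study`.
#' @param subject_id subject identifier.
#' @param key session key: `"baseline"` or `"<stimulus_type>:<location>"`.
#' @return a [sensation_map()], or `NULL` if absent.
#' @export
get_map <- function(dataset, subject_id, key = "baseline") {
  dataset$maps[[paste(subject_id, key, sep = "|")]]
}

#' Load a study dataset from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `session_kind`
#' (`baseline`/`stimulation`), `stimulus_type`, `stimulus_location` (empty
#' for baseline rows) and `map_path` (relative to the manifest). A
#' questionnaire CSV (long format, one row per item score) may accompany
#' it. All dataset invariants are enforced; maps are masked to the
#' template on load (idempotently).
#'
#' @param manifest path to the manifest CSV.
#' @param template a [body_template()], builtin template name, or PNG path.
#' @param questionnaire optional path to the questionnaire CSV.
#' @return a [study_dataset()].
#' @export
load_dataset <- function(manifest, template, questionnaire = NULL) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_kind", "map_path")
  if (!all(need %in% names(man))) stop("manifest must have columns: ",
                                       paste(need, collapse = ", "))
  if (!inherits(template, "bsm_template")) template <- load_template(template)
  base <- dirname(manifest)
  blank <- function(x) is.null(x) || is.na(x) || !nzchar(x)
  maps <- lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    ty <- if ("stimulus_type" %in% names(row) && !blank(row$stimulus_type)) row$stimulus_type
    loc <- if ("stimulus_location" %in% names(row) && !blank(row$stimulus_location)) row$stimulus_location
    sensation_map(read_map(file.path(base, row$map_path)),
                  subject_id = row$subject_id,
                  session_kind = row$session_kind,
                  stimulus_type = ty, stimulus_location = loc,
                  template = template)
  })
  qdf <- if (!is.null(questionnaire)) utils::read.csv(questionnaire, stringsAsFactors = FALSE)
  study_dataset(template, maps, qdf, provenance = paste("manifest:", manifest))
}

#' Write a study dataset to a directory
#'
#' Inverse of [load_dataset()]: writes one map file per session plus
#' `manifest.csv` (and `questionnaire.csv` when present).
#'
#' @param dataset a [study_dataset()].
#' @param dir output directory (created if needed).
#' @param format map file format (see [write_map()]).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("rds", "csv", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  rows <- lapply(dataset$maps, function(m) {
    fn <- file.path("maps", paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                        paste(m$subject_id, map_key(m), sep = "_")),
                                   ".", format))
    write_map(m$values, file.path(dir, fn), format)
    data.frame(subject_id = m$subject_id, session_kind = m$session_kind,
               stimulus_type = m$stimulus_type %||% "",
               stimulus_location = m$stimulus_location %||% "",
               map_path = fn, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  if (!is.null(dataset$questionnaire))
    utils::write.csv(dataset$questionnaire, file.path(dir, "questionnaire.csv"),
                     row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
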