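#' Read MIMIC-style CSV tables into per-stay episodes
#'
#' Reads the four-table CSV dialect written by [write_cohort()]
#' (chartevents-, noteevents-, diagnoses- and labels-like tables merged by
#' stay id) and assembles one episode per stay: temporal events restricted
#' to the 17 recognised features, notes, age, chronic status (from ICD-9
#' codes against `chronic_list`) and the mortality label when present
#' (absent at predict time). Unknown-feature rows and unparseable numeric
#' values are dropped with logged counts; categorical Glasgow Coma Scale
#' entries are mapped to ordinal scores via [gcs_lookup()].
#'
#' @param paths Either a directory containing `chartevents.csv`,
#'   `noteevents.csv`, `diagnoses.csv`, `labels.csv`, or a named list/vector
#'   with those four elements.
#' @param chronic_list Chronic ICD-9 code set (default the shipped synthetic
#'   list, [chronic_code_list()]).
#' @param quiet Suppress the drop-count messages.
#' @return List of episodes (class `"mortnet_episodes"`); each episode has
#'   `stay_id`, `age`, `chronic`, `icd9_codes`, `events`, `notes`, `label`
#'   (NA when the labels table has no `MORTALITY` column). Attributes
#'   `dropped_unknown_feature` and `dropped_unparseable` carry the filter
#'   counts.
#' @export
read_cohort <- function(paths, chronic_list = chronic_code_list(),
                        quiet = FALSE) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- file.path(paths, c(chartevents = "chartevents.csv",
                                noteevents = "noteevents.csv",
                                diagnoses = "diagnoses.csv",
                                labels = "labels.csv"))
    names(paths) <- c("chartevents", "noteevents", "diagnoses", "labels")
  }
  paths <- as.list(paths)
  for (nm in c("chartevents", "noteevents", "diagnoses", "labels")) {
    if (is.null(paths[[nm]])) stop("read_cohort: missing table path: ", nm)
    if (!file.exists(paths[[nm]])) {
      stop("read_cohort: file not found: ", paths[[nm]])
    }
  }
  read_tab <- function(path, required) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    miss <- setdiff(required, names(tab))
    if (length(miss) > 0L) {
      stop("read_cohort: ", basename(path), " lacks required column(s): ",
           paste(miss, collapse = ", "))
    }
    tab
  }
  chart <- read_tab(paths$chartevents,
                    c("STAY_ID", "FEATURE", "CHARTTIME_H", "VALUENUM"))
  notes <- read_tab(paths$noteevents,
                    c("STAY_ID", "CHARTTIME_H", "CATEGORY", "TEXT"))
  diag <- read_tab(paths$diagnoses, c("STAY_ID", "ICD9_CODE"))
  labels <- read_tab(paths$labels, c("STAY_ID", "AGE"))
  has_label <- "MORTALITY" %in% names(labels)

  feats <- feature_names()
  unknown <- !(chart$FEATURE %in% feats)
  n_unknown <- sum(unknown)
  chart <- chart[!unknown, , drop = FALSE]
  val <- suppressWarnings(as.numeric(chart$VALUENUM))
  gcs <- gcs_lookup()
  bad <- which(is.na(val))
  for (i in bad) {
    lk <- gcs[[chart$FEATURE[i]]]
    if (!is.null(lk)) {
      v <- lk[tolower(trimws(chart$VALUENUM[i]))]
      if (!is.na(v)) val[i] <- v
    }
  }
  n_unparseable <- sum(is.na(val))
  keep <- !is.na(val)
  chart <- chart[keep, , drop = FALSE]
  val <- val[keep]
  if (!quiet && (n_unknown > 0L || n_unparseable > 0L)) {
    message("read_cohort: dropped ", n_unknown, " unknown-feature and ",
            n_unparseable, " unparseable event row(s)")
  }
  time_h <- as.numeric(chart$CHARTTIME_H)

  # merge features measured in several source tables: duplicates at identical
  # timestamps are averaged
  if (nrow(chart) > 0L) {
    key <- paste(chart$STAY_ID, chart$FEATURE, time_h, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(cbind(val, 1), key)
      first <- !duplicated(key)
      ord <- match(key[first], rownames(agg))
      chart <- chart[first, , drop = FALSE]
      time_h <- time_h[first]
      val <- (agg[, 1] / agg[, 2])[ord]
    }
  }

  stay_ids <- labels$STAY_ID
  if (length(stay_ids) == 0L) {
    stay_ids <- unique(chart$STAY_ID)
  }
  chart_split <- split(seq_len(nrow(chart)), chart$STAY_ID)
  notes_split <- split(seq_len(nrow(notes)), notes$STAY_ID)
  diag_split <- split(diag$ICD9_CODE, diag$STAY_ID)
  lab_idx <- match(stay_ids, labels$STAY_ID)

  episodes <- vector("list", length(stay_ids))
  for (i in seq_along(stay_ids)) {
    sid <- stay_ids[i]
    ci <- chart_split[[sid]]
    events <- if (is.null(ci)) {
      data.frame(feature = character(0), time = numeric(0),
                 value = numeric(0), stringsAsFactors = FALSE)
    } else {
      data.frame(feature = chart$FEATURE[ci], time = time_h[ci],
                 value = val[ci], stringsAsFactors = FALSE)
    }
    ni <- notes_split[[sid]]
    nlist <- if (is.null(ni)) list() else lapply(ni, function(j) {
      list(chart_time = as.numeric(notes$CHARTTIME_H[j]),
           category = notes$CATEGORY[j], text = notes$TEXT[j])
    })
    nlist <- Filter(function(x) nzchar(trimws(x$text)), nlist)
    codes <- diag_split[[sid]]
    if (is.null(codes)) codes <- character(0)
    li <- lab_idx[i]
    episodes[[i]] <- list(
      stay_id = sid,
      age = if (is.na(li)) NA_real_ else as.numeric(labels$AGE[li]),
      chronic = classify_chronic(codes, chronic_list),
      icd9_codes = codes,
      events = events,
      notes = nlist,
      label = if (has_label && !is.na(li)) {
        as.integer(labels$MORTALITY[li])
      } else NA_integer_)
  }
  structure(episodes, class = "mortnet_episodes",
            dropped_unknown_feature = n_unknown,
            dropped_unparseable = n_unparseable)
}

#' Apply the cohort inclusion filters
#'
#' Retains episodes with age at least 16 years (physiology standards for
#' minors differ) and an ICU stay of at least 48 hours (maximum event time
#' >= 48 h), preserving order. Idempotent.
#'
#' @param episodes List of episodes from [read_cohort()].
#' @param min_age Minimum age in years (inclusive, default 16).
#' @param min_stay_h Minimum stay length in hours (default 48).
#' @param quiet Suppress the before/after count message.
#' @return Filtered episode list (class preserved).
#' @export
filter_cohort <- function(episodes, min_age = 16, min_stay_h = 48,
                          quiet = FALSE) {
  keep <- vapply(episodes, function(e) {
    max_t <- if (nrow(e$events) > 0L) max(e$events$time) else -Inf
    !is.na(e$age) && e$age >= min_age && max_t >= min_stay_h
  }, logical(1))
  if (!quiet) {
    message("filter_cohort: ", sum(keep), " of ", length(episodes),
            " episode(s) retained (age >= ", min_age, ", stay >= ",
            min_stay_h, " h)")
  }
  structure(episodes[keep], class = class(episodes))
}

#' Classify chronic status from ICD-9 codes
#'
#' A patient is chronic iff any diagnosis code, after normalization
#' (uppercase, decimal points and whitespace stripped), is in the chronic
#' code set.
#'
#' @param icd9_codes Character vector of ICD-9 codes (possibly dotted).
#' @param chronic_list Chronic code set (default [chronic_code_list()]).
#' @return Logical scalar; `FALSE` for an empty code list.
#' @export
#' @examples
#' classify_chronic(c("401.9"), chronic_list = c("4019"))
classify_chronic <- function(icd9_codes, chronic_list = chronic_code_list()) {
  if (length(icd9_codes) == 0L) return(FALSE)
  any(normalize_icd9(icd9_codes) %in% normalize_icd9(chronic_list))
}

#' Select the notes feeding the text branch
#'
#' Notes charted inside the observation window (`0 <= t <= window_h`, hours
#' from ICU admission) are always included. Notes outside the window —
#' pre-admission history records in particular — are included as history
#' notes only for chronic patients, ordered before the window notes when the
#' text is assembled. `K` counts the history notes.
#'
#' @param episode An episode from [read_cohort()].
#' @param window_h Observation window length in hours (default 48).
#' @param chronic Whether the history pathway is active (default the
#'   episode's chronic flag).
#' @return A note bundle: list with `stay_id`, `notes` (each note carrying a
#'   logical `history` flag) and `K`.
#' @export
select_notes <- function(episode, window_h = 48, chronic = episode$chronic) {
  stopifnot(window_h > 0)
  out <- list()
  for (nt in episode$notes) {
    in_window <- nt$chart_time >= 0 && nt$chart_time <= window_h
    if (in_window) {
      nt$history <- FALSE
      out[[length(out) + 1L]] <- nt
    } else if (isTRUE(chronic)) {
      nt$history <- TRUE
      out[[length(out) + 1L]] <- nt
    }
  }
  list(stay_id = episode$stay_id, notes = out,
       K = sum(vapply(out, `[[`, logical(1), "history")))
}

#' Convert generated patients to episodes without a disk round trip
#'
#' Convenience used by the fitting pipeline and tests: gives generated
#' synthetic patients the episode interface of [read_cohort()] (chronic
#' status re-derived from their ICD-9 codes).
#'
#' @param patients A cohort from [generate_cohort()].
#' @param chronic_list Chronic code set.
#' @return List of episodes (class `"mortnet_episodes"`).
#' @export
as_episodes <- function(patients, chronic_list = chronic_code_list()) {
  eps <- lapply(patients, function(p) {
    list(stay_id = p$stay_id, age = p$age,
         chronic = classify_chronic(p$icd9_codes, chronic_list),
         icd9_codes = p$icd9_codes, events = p$events, notes = p$notes,
         label = p$label)
  })
  structure(eps, class = "mortnet_episodes")
}

#' @export
print.mortnet_episodes <- function(x, ...) {
  labs <- vapply(x, `[[`, integer(1), "label")
  cat("<mortnet_episodes>", length(x), "episode(s) |",
      sum(labs == 1L, na.rm = TRUE), "positive |",
      sum(vapply(x, `[[`, logical(1), "chronic")), "chronic\n")
  invisible(x)
}
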