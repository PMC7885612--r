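#' Specification of a synthetic EMR cohort
#'
#' Declares the statistical structure of a synthetic ICU cohort: size, label
#' prevalence, chronic-disease fraction, the tokens planted as textual
#' mortality signal, and measurement missingness. The generator plants
#' recoverable signal in both modalities for positive-label patients: the
#' `signal_tokens` appear in note sections with probability
#' `signal_strength`, and three temporal features (heart rate, respiratory
#' rate, systolic blood pressure) have their means shifted by `effect_size`
#' times a feature-scale step.
#'
#' @param n_patients Number of patients (positive integer).
#' @param prevalence Probability of mortality label 1 (real cohorts are
#'   imbalanced; the default 0.13 is a configurable placeholder).
#' @param chronic_fraction Probability a patient carries a chronic ICD-9
#'   code (chronic patients dominate real ICU cohorts).
#' @param signal_tokens Tokens planted preferentially in positive-label
#'   notes.
#' @param signal_strength Probability a signal token is planted per positive
#'   note.
#' @param noise_vocab_size Size of the background token vocabulary.
#' @param missing_rate Per-cell probability that an hourly measurement is
#'   missing (missing completely at random).
#' @param seed Integer seed; a fixed seed yields byte-identical cohorts.
#' @param effect_size Temporal mean-shift multiplier for positive patients
#'   (0 disables the temporal signal).
#' @param signal_section Canonical section name into which text signal is
#'   planted.
#' @param signal_location Where text signal may be planted: `"any"` note,
#'   `"window"` notes only, or pre-window `"history"` notes only (the last
#'   isolates the chronic-history pathway).
#' @param text_signal Logical; plant token signal at all.
#' @param background_rate Probability a negative-label note also carries a
#'   signal token (label noise in the text channel).
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients, prevalence = 0.13, chronic_fraction = 0.7,
                        signal_tokens = c("sepsis", "hypotension", "anuric",
                                          "pressors"),
                        signal_strength = 0.8, noise_vocab_size = 200L,
                        missing_rate = 0.3, seed = 1L, effect_size = 1,
                        signal_section = "HISTORY_OF_PRESENT_ILLNESS",
                        signal_location = c("any", "window", "history"),
                        text_signal = TRUE, background_rate = 0.02) {
  signal_location <- match.arg(signal_location)
  spec <- list(n_patients = n_patients, prevalence = prevalence,
               chronic_fraction = chronic_fraction,
               signal_tokens = signal_tokens,
               signal_strength = signal_strength,
               noise_vocab_size = as.integer(noise_vocab_size),
               missing_rate = missing_rate, seed = as.integer(seed),
               effect_size = effect_size, signal_section = signal_section,
               signal_location = signal_location, text_signal = text_signal,
               background_rate = background_rate)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("cohort_spec: ", msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(spec$n_patients) && spec$n_patients >= 1, "n_patients must be >= 1")
  chk(num1(spec$prevalence) && spec$prevalence >= 0 && spec$prevalence <= 1,
      "prevalence must be in [0, 1]")
  chk(num1(spec$chronic_fraction) && spec$chronic_fraction >= 0 &&
        spec$chronic_fraction <= 1, "chronic_fraction must be in [0, 1]")
  chk(num1(spec$signal_strength) && spec$signal_strength >= 0 &&
        spec$signal_strength <= 1, "signal_strength must be in [0, 1]")
  chk(num1(spec$missing_rate) && spec$missing_rate >= 0 &&
        spec$missing_rate < 1, "missing_rate must be in [0, 1)")
  chk(num1(spec$noise_vocab_size) && spec$noise_vocab_size >= 10,
      "noise_vocab_size must be >= 10")
  chk(num1(spec$effect_size) && spec$effect_size >= 0,
      "effect_size must be >= 0")
  chk(num1(spec$background_rate) && spec$background_rate >= 0 &&
        spec$background_rate <= 1, "background_rate must be in [0, 1]")
  chk(num1(spec$seed), "seed must be a finite number")
  chk(is.character(spec$signal_tokens) && length(spec$signal_tokens) >= 1,
      "signal_tokens must be a non-empty character vector")
  invisible(spec)
}

# acute (non-chronic) filler codes for diagnosis lists
.acute_codes <- c("486", "5070", "8020", "9592", "56081", "4239")

#' Generate a synthetic ICU cohort
#'
#' Simulates `n_patients` ICU stays with the structure the model assumes:
#' irregular hourly measurements of the 17 temporal features over at least
#' 48 h (stationary AR(1) fluctuation around clinically plausible baselines,
#' with label-shifted means for positive patients), sectioned clinical notes
#' built from the canonical header lexicon with label-informative tokens,
#' ICD-9-coded chronic status (chronic patients get at least one pre-window
#' history note), and Bernoulli mortality labels.
#'
#' @param spec A [cohort_spec()].
#' @return List of patients (class `"mortnet_cohort"`); each patient is a
#'   list with `stay_id`, `age`, `icd9_codes`, `label`, `chronic`, `events`
#'   (data.frame `feature`, `time`, `value`) and `notes` (list of
#'   `chart_time`, `category`, `text`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(5, prevalence = 0.4, seed = 1))
#' length(cohort)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  ref <- feature_reference()
  feats <- names(ref)
  noise_vocab <- sprintf("w%03d", seq_len(spec$noise_vocab_size))
  filler_stop <- c("the", "and", "of", "with", "was", "on", "to", "in")
  rho <- 0.9

  patients <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    stay_id <- sprintf("S%05d", p)
    age <- round(stats::runif(1, 18, 95), 1)
    label <- stats::rbinom(1, 1, spec$prevalence)
    chronic <- stats::runif(1) < spec$chronic_fraction
    icd9 <- if (chronic) {
      c(sample(chronic_code_list(), sample(1:3, 1)),
        sample(.acute_codes, sample(0:1, 1)))
    } else {
      sample(.acute_codes, sample(1:2, 1))
    }
    max_h <- 48 + stats::runif(1, 1, 24)
    H <- floor(max_h)
    shift <- stats::setNames(numeric(length(feats)), feats)
    if (label == 1L && spec$effect_size > 0) {
      shift["heart_rate"] <- 10 * spec$effect_size
      shift["respiratory_rate"] <- 4 * spec$effect_size
      shift["systolic_blood_pressure"] <- -12 * spec$effect_size
    }
    ev_feat <- character(0); ev_time <- numeric(0); ev_val <- numeric(0)
    for (f in feats) {
      r <- ref[[f]]
      if (r$step_sd == 0) {
        ev_feat <- c(ev_feat, f)
        ev_time <- c(ev_time, 0.1)
        ev_val <- c(ev_val, r$baseline + stats::rnorm(1, 0, 2))
        next
      }
      innov <- stats::rnorm(H, 0, r$step_sd)
      dev <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      vals <- r$baseline + shift[[f]] + dev
      times <- (seq_len(H) - 1L) + stats::runif(H)
      keep <- stats::runif(H) > spec$missing_rate
      ev_feat <- c(ev_feat, rep(f, sum(keep)))
      ev_time <- c(ev_time, times[keep])
      ev_val <- c(ev_val, vals[keep])
    }
    # anchor the stay length: one final measurement past the 48 h mark
    ev_feat <- c(ev_feat, "heart_rate")
    ev_time <- c(ev_time, max_h)
    ev_val <- c(ev_val, ref$heart_rate$baseline + shift[["heart_rate"]] +
                  stats::rnorm(1, 0, ref$heart_rate$step_sd))
    events <- data.frame(feature = ev_feat, time = ev_time, value = ev_val,
                         stringsAsFactors = FALSE)

    plant_window <- spec$text_signal && label == 1L &&
      spec$signal_location %in% c("any", "window")
    plant_history <- spec$text_signal && label == 1L &&
      spec$signal_location %in% c("any", "history")
    notes <- list()
    for (k in seq_len(sample(1:3, 1))) {
      plant <- if (plant_window) {
        stats::runif(1) < spec$signal_strength
      } else {
        stats::runif(1) < spec$background_rate
      }
      notes[[length(notes) + 1L]] <- list(
        chart_time = stats::runif(1, 0, 48),
        category = sample(c("Nursing", "Physician", "Nursing/other"), 1),
        text = make_note_text(spec, noise_vocab, filler_stop, plant,
                              history = FALSE))
    }
    if (chronic) {
      for (k in seq_len(sample(1:2, 1))) {
        plant <- if (plant_history) {
          stats::runif(1) < spec$signal_strength
        } else {
          stats::runif(1) < spec$background_rate
        }
        notes[[length(notes) + 1L]] <- list(
          chart_time = stats::runif(1, -240, -24),
          category = "Physician",
          text = make_note_text(spec, noise_vocab, filler_stop, plant,
                                history = TRUE))
      }
    }
    patients[[p]] <- list(stay_id = stay_id, age = age, icd9_codes = icd9,
                          label = label, chronic = chronic, events = events,
                          notes = notes)
  }
  structure(patients, class = "mortnet_cohort")
}

# one note: 3-5 sections with headers from the canonical lexicon; signal
# tokens (if planted) go into spec$signal_section
make_note_text <- function(spec, noise_vocab, filler_stop, plant, history) {
  pool <- if (history) {
    c("CLINICAL_HISTORY", "PAST_MEDICAL_HISTORY", "FAMILY_HISTORY",
      "SOCIAL_HISTORY", "HISTORY_OF_PRESENT_ILLNESS", "ALLERGIES")
  } else {
    c("CHIEF_COMPLAINT", "HISTORY_OF_PRESENT_ILLNESS", "PAST_MEDICAL_HISTORY",
      "ALLERGIES", "FAMILY_HISTORY", "MAJOR_SURGICAL_OR_INVASIVE_PROCEDURE",
      "SOCIAL_HISTORY")
  }
  secs <- sample(pool, sample(3:5, 1))
  if (plant && !(spec$signal_section %in% secs)) {
    secs <- c(secs, spec$signal_section)
  }
  parts <- character(length(secs))
  for (j in seq_along(secs)) {
    n_tok <- sample(6:14, 1)
    toks <- sample(noise_vocab, n_tok, replace = TRUE)
    sw <- stats::runif(n_tok) < 0.25
    toks[sw] <- sample(filler_stop, sum(sw), replace = TRUE)
    if (plant && secs[j] == spec$signal_section) {
      ins <- sample(spec$signal_tokens, sample(1:2, 1), replace = TRUE)
      at <- sample(seq_len(n_tok), length(ins))
      toks[at] <- ins
    }
    parts[j] <- paste0(gsub("_", " ", secs[j]), ": ",
                       paste(toks, collapse = " "), ".")
  }
  paste(parts, collapse = " ")
}

#' Write a cohort to MIMIC-style CSV tables
#'
#' Emits four CSV files in the dialect [read_cohort()] reads:
#' `chartevents.csv` (`STAY_ID, FEATURE, CHARTTIME_H, VALUENUM`),
#' `noteevents.csv` (`STAY_ID, CHARTTIME_H, CATEGORY, TEXT`),
#' `diagnoses.csv` (`STAY_ID, ICD9_CODE`) and `labels.csv`
#' (`STAY_ID, AGE, MORTALITY`). Times are fractional hours from ICU
#' admission (negative for pre-admission history notes). An empty cohort
#' yields headers-only files.
#'
#' @param patients A cohort from [generate_cohort()] (or a compatible list).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(patients, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_cohort: cannot create directory ", out_dir)
  }
  grab <- function(fun) do.call(rbind, lapply(patients, fun))
  chart <- grab(function(p) {
    if (nrow(p$events) == 0L) return(NULL)
    data.frame(STAY_ID = p$stay_id, FEATURE = p$events$feature,
               CHARTTIME_H = p$events$time, VALUENUM = p$events$value,
               stringsAsFactors = FALSE)
  })
  notes <- grab(function(p) {
    if (length(p$notes) == 0L) return(NULL)
    data.frame(STAY_ID = p$stay_id,
               CHARTTIME_H = vapply(p$notes, `[[`, numeric(1), "chart_time"),
               CATEGORY = vapply(p$notes, `[[`, character(1), "category"),
               TEXT = vapply(p$notes, `[[`, character(1), "text"),
               stringsAsFactors = FALSE)
  })
  diag <- grab(function(p) {
    data.frame(STAY_ID = p$stay_id, ICD9_CODE = p$icd9_codes,
               stringsAsFactors = FALSE)
  })
  labels <- grab(function(p) {
    data.frame(STAY_ID = p$stay_id, AGE = p$age, MORTALITY = p$label,
               stringsAsFactors = FALSE)
  })
  empty <- list(
    chartevents = data.frame(STAY_ID = character(0), FEATURE = character(0),
                             CHARTTIME_H = numeric(0), VALUENUM = numeric(0)),
    noteevents = data.frame(STAY_ID = character(0), CHARTTIME_H = numeric(0),
                            CATEGORY = character(0), TEXT = character(0)),
    diagnoses = data.frame(STAY_ID = character(0), ICD9_CODE = character(0)),
    labels = data.frame(STAY_ID = character(0), AGE = numeric(0),
                        MORTALITY = integer(0)))
  tabs <- list(chartevents = chart, noteevents = notes, diagnoses = diag,
               labels = labels)
  paths <- character(0)
  for (nm in names(tabs)) {
    tab <- if (is.null(tabs[[nm]])) empty[[nm]] else tabs[[nm]]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    ok <- tryCatch({
      utils::write.csv(tab, path, row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("write_cohort: failed writing ", path, ": ", conditionMessage(ok))
    }
    paths[nm] <- path
  }
  invisible(paths)
}

#' @export
print.mortnet_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, numeric(1), "label")
  chr <- vapply(x, `[[`, logical(1), "chronic")
  cat("<mortnet_cohort>", length(x), "patients |",
      sum(labs), "positive |", sum(chr), "chronic\n")
  invisible(x)
}
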