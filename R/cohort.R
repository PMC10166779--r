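# Cohort container, CSV input, validation and event scoring.
#
# A cohort is a pair of data frames:
#   carriers: carrier_id, gene, sex, age_inclusion, age_last_obs, vital_status
#   events:   carrier_id, organ, age_dx, timing
# Ages are continuous years; inputs in whole years are accepted unchanged.
# Carriers enter at their first prospectively planned surveillance contact at
# age >= 25; vital status is categorised at last observation.

#' Construct a Lynch-syndrome surveillance cohort
#'
#' Assembles carrier and cancer-event records into a `lynch_cohort`.
#' Vocabulary columns are canonicalised (genes/sex upper case, organs, event
#' timing and vital status lower case); label and invariant checks are
#' deferred to [validate_cohort()].
#'
#' @param carriers Data frame with columns `carrier_id`, `gene`, `sex`,
#'   `age_inclusion`, `age_last_obs`, `vital_status`.
#' @param events Data frame with columns `carrier_id`, `organ`, `age_dx`,
#'   `timing` (`previous`, `prevalent` or `prospective`), or `NULL` for an
#'   event-free cohort.
#' @return An object of class `lynch_cohort`: a list with elements
#'   `carriers` and `events`.
#' @seealso [read_cohort()], [validate_cohort()], [score_prospective_events()]
#' @export
as_lynch_cohort <- function(carriers, events = NULL) {
  need <- c("carrier_id", "gene", "sex", "age_inclusion", "age_last_obs",
            "vital_status")
  miss <- setdiff(need, names(carriers))
  if (length(miss)) {
    stop("carriers is missing column(s): ", paste(miss, collapse = ", "))
  }
  ca <- as.data.frame(carriers)[need]
  ca$carrier_id <- as.character(ca$carrier_id)
  ca$gene <- toupper(trimws(as.character(ca$gene)))
  ca$sex <- toupper(trimws(as.character(ca$sex)))
  ca$age_inclusion <- as.numeric(ca$age_inclusion)
  ca$age_last_obs <- as.numeric(ca$age_last_obs)
  ca$vital_status <- tolower(trimws(as.character(ca$vital_status)))
  if (anyDuplicated(ca$carrier_id)) {
    stop("duplicated carrier_id in carriers: ",
         paste(unique(ca$carrier_id[duplicated(ca$carrier_id)]),
               collapse = ", "))
  }
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    ev <- data.frame(carrier_id = character(), organ = character(),
                     age_dx = numeric(), timing = character(),
                     stringsAsFactors = FALSE)
  } else {
    neede <- c("carrier_id", "organ", "age_dx", "timing")
    misse <- setdiff(neede, names(events))
    if (length(misse)) {
      stop("events is missing column(s): ", paste(misse, collapse = ", "))
    }
    ev <- as.data.frame(events)[neede]
    ev$carrier_id <- as.character(ev$carrier_id)
    ev$organ <- tolower(trimws(as.character(ev$organ)))
    ev$age_dx <- as.numeric(ev$age_dx)
    ev$timing <- tolower(trimws(as.character(ev$timing)))
  }
  structure(list(carriers = ca, events = ev),
            class = "lynch_cohort",
            validated = FALSE, scored = FALSE)
}

#' Read a cohort from CSV files
#'
#' Reads `carriers.csv` (columns `carrier_id, gene, sex, age_inclusion,
#' age_last_obs, vital_status`) and optionally `events.csv` (columns
#' `carrier_id, organ, age_dx, timing`).  Files must have a header, be UTF-8
#' and use `.` as the decimal separator.  Vocabulary columns are read
#' case-insensitively.
#'
#' @param carriers_csv,events_csv File paths; `events_csv` may be `NULL`.
#' @return A `lynch_cohort` (not yet validated).
#' @export
read_cohort <- function(carriers_csv, events_csv = NULL) {
  # read everything as character: "F" in the sex column must not become a
  # logical; as_lynch_cohort() converts the numeric columns
  ca <- read.csv(carriers_csv, stringsAsFactors = FALSE,
                 colClasses = "character")
  ev <- if (!is.null(events_csv)) {
    read.csv(events_csv, stringsAsFactors = FALSE, colClasses = "character")
  }
  as_lynch_cohort(ca, ev)
}

#' Write a cohort to CSV files
#'
#' Writes `carriers.csv` and `events.csv` into `dir` with canonical
#' lower-case vocabulary (genes upper case).
#'
#' @param cohort A `lynch_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- file.path(dir, "carriers.csv")
  pe <- file.path(dir, "events.csv")
  write.csv(cohort$carriers, pc, row.names = FALSE)
  write.csv(cohort$events, pe, row.names = FALSE)
  invisible(c(carriers = pc, events = pe))
}

#' Validate a cohort against the design invariants
#'
#' Checks every carrier and event record: known gene/sex/organ/timing/vital
#' labels, inclusion age at least 25, last observation not before inclusion,
#' events referencing existing carriers, sex-compatible organs, prospective
#' events strictly after inclusion and not after last observation,
#' previous/prevalent events not after inclusion.
#'
#' @param cohort A `lynch_cohort`.
#' @param on_invalid `"stop"` (default) aborts listing the offending
#'   carriers; `"skip"` drops offending carriers (and their events) and
#'   records them in the issue log.
#' @return The validated cohort, with attributes `issues` (data frame of
#'   carrier_id/message pairs) and `summary` (see [cohort_summary()]).
#' @export
validate_cohort <- function(cohort, on_invalid = c("stop", "skip")) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  on_invalid <- match.arg(on_invalid)
  ca <- cohort$carriers
  ev <- cohort$events
  issues <- list()
  flag <- function(ids, msg) {
    if (length(ids)) {
      issues[[length(issues) + 1L]] <<-
        data.frame(carrier_id = unique(as.character(ids)), message = msg,
                   stringsAsFactors = FALSE)
    }
  }

  flag(ca$carrier_id[!ca$gene %in% .GENES],
       "gene not one of MLH1/MSH2/MSH6/PMS2")
  flag(ca$carrier_id[!ca$sex %in% .SEXES], "sex not one of F/M")
  flag(ca$carrier_id[!ca$vital_status %in% .VITAL],
       "vital_status not one of alive/dead")
  flag(ca$carrier_id[is.na(ca$age_inclusion) | ca$age_inclusion < 25],
       "age_inclusion below 25 or missing")
  flag(ca$carrier_id[is.na(ca$age_last_obs) |
                       ca$age_last_obs < ca$age_inclusion],
       "age_last_obs before age_inclusion or missing")

  if (nrow(ev)) {
    flag(ev$carrier_id[!ev$carrier_id %in% ca$carrier_id],
         "event references unknown carrier")
    flag(ev$carrier_id[!ev$organ %in% .ORGANS], "unknown organ code")
    flag(ev$carrier_id[!ev$timing %in% .TIMINGS], "unknown event timing")
    flag(ev$carrier_id[is.na(ev$age_dx)], "missing age_dx")
    sex <- ca$sex[match(ev$carrier_id, ca$carrier_id)]
    bad_sex <- !is.na(sex) & ev$organ %in% .ORGANS &
      !organ_sex_ok(ev$organ, sex)
    flag(ev$carrier_id[bad_sex], "organ incompatible with carrier sex")
    incl <- ca$age_inclusion[match(ev$carrier_id, ca$carrier_id)]
    last <- ca$age_last_obs[match(ev$carrier_id, ca$carrier_id)]
    pro <- ev$timing == "prospective" & !is.na(ev$age_dx) & !is.na(incl)
    flag(ev$carrier_id[pro & ev$age_dx <= incl],
         "prospective event dated at or before inclusion")
    flag(ev$carrier_id[pro & !is.na(last) & ev$age_dx > last],
         "prospective event dated after last observation")
    pre <- ev$timing %in% c("previous", "prevalent") & !is.na(ev$age_dx) &
      !is.na(incl)
    flag(ev$carrier_id[pre & ev$age_dx > incl],
         "previous/prevalent event dated after inclusion")
  }

  log <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(carrier_id = character(), message = character(),
               stringsAsFactors = FALSE)
  }

  if (nrow(log)) {
    if (on_invalid == "stop") {
      stop("cohort validation failed for carrier(s): ",
           paste(unique(log$carrier_id), collapse = ", "), "\n  ",
           paste(unique(paste0(log$carrier_id, ": ", log$message)),
                 collapse = "\n  "))
    }
    drop <- unique(log$carrier_id)
    ca <- ca[!ca$carrier_id %in% drop, , drop = FALSE]
    ev <- ev[!ev$carrier_id %in% drop, , drop = FALSE]
    message("validate_cohort: skipped ", length(drop),
            " carrier(s) with validation issues")
  }

  out <- structure(list(carriers = ca, events = ev),
                   class = "lynch_cohort",
                   validated = TRUE,
                   scored = isTRUE(attr(cohort, "scored")),
                   issues = log)
  attr(out, "summary") <- cohort_summary(out)
  out
}

#' Summarise a cohort
#'
#' Counts and person-time the registry reports for sanity checking: number of
#' carriers by gene and sex, total observation years
#' (`sum(age_last_obs - age_inclusion)`), mean follow-up, and counts of
#' scored prospective first cancers with the share occurring in core
#' Lynch-syndrome organs.
#'
#' @param cohort A `lynch_cohort`.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  ca <- cohort$carriers
  obs <- ca$age_last_obs - ca$age_inclusion
  sc <- score_prospective_events(cohort)
  pro <- sc$events[sc$events$timing == "prospective", , drop = FALSE]
  structure(list(
    n_carriers = nrow(ca),
    n_by_gene = table(factor(ca$gene, levels = .GENES)),
    n_by_sex = table(factor(ca$sex, levels = .SEXES)),
    observation_years = sum(obs),
    mean_follow_up = if (nrow(ca)) mean(obs) else NA_real_,
    n_prospective_cancers = nrow(pro),
    n_ls_cancers = sum(pro$organ %in% .LS_ORGANS),
    ls_cancer_share = if (nrow(pro)) {
      100 * sum(pro$organ %in% .LS_ORGANS) / nrow(pro)
    } else {
      NA_real_
    }
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n_carriers, "carriers\n")
  cat("  by gene:", paste(names(x$n_by_gene), as.integer(x$n_by_gene),
                          sep = "=", collapse = ", "), "\n")
  cat("  by sex: ", paste(names(x$n_by_sex), as.integer(x$n_by_sex),
                          sep = "=", collapse = ", "), "\n")
  cat(sprintf("  observation years: %.1f (mean follow-up %.1f)\n",
              x$observation_years, x$mean_follow_up))
  if (!is.na(x$ls_cancer_share)) {
    cat(sprintf("  prospective first cancers: %d (%d, %.1f%% in LS organs)\n",
                x$n_prospective_cancers, x$n_ls_cancers, x$ls_cancer_share))
  }
  invisible(x)
}

#' @export
print.lynch_cohort <- function(x, ...) {
  cat("<lynch_cohort> ", nrow(x$carriers), " carriers, ",
      nrow(x$events), " events",
      if (isTRUE(attr(x, "scored"))) " (scored)", "\n", sep = "")
  invisible(x)
}

#' Score prospective cancer events
#'
#' Applies the registry event-scoring rules organ by organ: a carrier with a
#' previous or prevalent cancer in an organ is ineligible for that organ and
#' contributes no risk time to it; otherwise the earliest prospective cancer
#' in the organ is the scored event and any synchronous or subsequent cancer
#' in the same organ is discarded.  Prospective cancers in other organs do
#' not affect eligibility.  Scoring is idempotent.
#'
#' @param cohort A `lynch_cohort`.
#' @return The cohort with `events` reduced to previous/prevalent records
#'   plus at most one scored prospective event per carrier and organ;
#'   attribute `scored` is set.
#' @export
#' @examples
#' ca <- data.frame(carrier_id = "a", gene = "MLH1", sex = "F",
#'                  age_inclusion = 40, age_last_obs = 60,
#'                  vital_status = "alive")
#' ev <- data.frame(carrier_id = "a", organ = c("colon", "colon"),
#'                  age_dx = c(55, 47), timing = "prospective")
#' score_prospective_events(as_lynch_cohort(ca, ev))$events
score_prospective_events <- function(cohort) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  if (isTRUE(attr(cohort, "scored"))) return(cohort)
  ev <- cohort$events
  ca <- cohort$carriers
  if (nrow(ev)) {
    incl <- ca$age_inclusion[match(ev$carrier_id, ca$carrier_id)]
    bad <- ev$timing == "prospective" & !is.na(incl) & ev$age_dx <= incl
    if (any(bad)) {
      stop("prospective event dated at or before inclusion for carrier(s): ",
           paste(unique(ev$carrier_id[bad]), collapse = ", "))
    }
    pre <- ev[ev$timing %in% c("previous", "prevalent"), , drop = FALSE]
    pro <- ev[ev$timing == "prospective", , drop = FALSE]
    blocked <- paste(pre$carrier_id, pre$organ)
    pro <- pro[!paste(pro$carrier_id, pro$organ) %in% blocked, , drop = FALSE]
    if (nrow(pro)) {
      pro <- pro[order(pro$carrier_id, pro$organ, pro$age_dx), , drop = FALSE]
      first <- !duplicated(paste(pro$carrier_id, pro$organ))
      pro <- pro[first, , drop = FALSE]
    }
    ev <- rbind(pre, pro)
    rownames(ev) <- NULL
  }
  out <- cohort
  out$events <- ev
  attr(out, "scored") <- TRUE
  out
}

#' Carriers eligible for an organ set
#'
#' A carrier is eligible for an organ set when they have no previous or
#' prevalent cancer in any member organ and at least one member organ is
#' compatible with their sex.
#'
#' @param cohort A `lynch_cohort`.
#' @param organ_set An [organ_group()] or character vector of organ codes.
#' @return Character vector of eligible `carrier_id`s.
#' @export
eligible_carriers <- function(cohort, organ_set) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  os <- as_organ_group(organ_set)
  ca <- cohort$carriers
  ev <- cohort$events
  compatible <- rep(FALSE, nrow(ca))
  for (o in os$members) compatible <- compatible | organ_sex_ok(o, ca$sex)
  pre <- ev[ev$timing %in% c("previous", "prevalent") &
              ev$organ %in% os$members, , drop = FALSE]
  ca$carrier_id[compatible & !ca$carrier_id %in% pre$carrier_id]
}
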