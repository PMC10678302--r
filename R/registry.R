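# Registry data model: one table of diseases, one table of trials.
# Trials are grouped into development programs (a sponsor x disease set of
# trials, the unit of success simulation) via the program_id column.

.CATEGORIES <- c("cancer", "rare", "general")
.THERAPEUTIC_AREAS <- c(
  "Autoimmune/Inflammation", "Cardiovascular", "CNS",
  "Metabolic/Endocrinology", "Oncology", "Ophthalmology"
)
.DISEASE_COLS <- c(
  "disease_id", "name", "category", "therapeutic_area", "incidence_i",
  "prevalence_j", "survival_p", "survival_k", "age_minor", "age_adult",
  "age_elderly", "delta_qaly", "prior_approval", "parent_disease_id",
  "eligible_fraction"
)
.TRIAL_COLS <- c("trial_id", "disease_id", "program_id", "phase",
                 "start_date", "end_date")

#' Construct a validated disease/trial registry
#'
#' @param diseases data frame with the columns documented in
#'   [read_registry()]: identifiers, category (`cancer`/`rare`/`general`),
#'   therapeutic area, incidence (persons/year) and/or prevalence (persons),
#'   k-year survival, an age mix over minor/adult/elderly, the expected
#'   incremental QALYs per treated patient, a prior-approval flag, an
#'   optional parent disease for overlap adjustment, and the eligible
#'   fraction of the patient population.
#' @param trials data frame of late-stage trials with disease and program
#'   identifiers, phase (`"2/3"` or `"3"`), start date and (possibly
#'   missing) end date.
#' @return an object of class `gt_registry`.
#' @export
new_registry <- function(diseases, trials) {
  diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  for (col in c("start_date", "end_date")) {
    if (!inherits(trials[[col]], "Date")) {
      trials[[col]] <- as.Date(as.character(trials[[col]]))
    }
  }
  reg <- structure(list(diseases = diseases, trials = trials),
                   class = "gt_registry")
  validate_registry(reg)
  reg
}

#' Validate registry invariants
#'
#' Checks referential integrity (every trial references a disease, every
#' disease has at least one trial), column presence, category and area
#' levels, date ordering, age-mix normalisation, epidemiological domain
#' constraints, and (before overlap adjustment) that nested child diseases
#' do not exceed their parents' patient counts.
#'
#' @param registry a `gt_registry`.
#' @return the registry, invisibly; stops with a descriptive error otherwise.
#' @export
validate_registry <- function(registry) {
  d <- registry$diseases
  t <- registry$trials
  missing_d <- setdiff(.DISEASE_COLS, names(d))
  if (length(missing_d)) {
    stop_arg("diseases table is missing columns: ",
             paste(missing_d, collapse = ", "))
  }
  missing_t <- setdiff(.TRIAL_COLS, names(t))
  if (length(missing_t)) {
    stop_arg("trials table is missing columns: ",
             paste(missing_t, collapse = ", "))
  }
  if (anyDuplicated(d$disease_id)) stop_arg("duplicated disease_id")
  if (anyDuplicated(t$trial_id)) stop_arg("duplicated trial_id")
  if (!all(d$category %in% .CATEGORIES)) {
    stop_arg("category must be one of ", paste(.CATEGORIES, collapse = ", "))
  }
  if (!all(d$therapeutic_area %in% .THERAPEUTIC_AREAS)) {
    stop_arg("unknown therapeutic_area: ",
             paste(setdiff(d$therapeutic_area, .THERAPEUTIC_AREAS),
                   collapse = ", "))
  }
  if (!all(t$phase %in% c("2/3", "3"))) stop_arg("phase must be '2/3' or '3'")

  orphan <- setdiff(t$disease_id, d$disease_id)
  if (length(orphan)) {
    stop_arg("trials reference unknown diseases: ",
             paste(orphan, collapse = ", "))
  }
  untrialed <- setdiff(d$disease_id, t$disease_id)
  if (length(untrialed)) {
    stop_arg("diseases without any trial: ",
             paste(untrialed, collapse = ", "))
  }
  has_end <- !is.na(t$end_date)
  if (any(t$end_date[has_end] < t$start_date[has_end])) {
    stop_arg("trial end_date precedes start_date")
  }

  no_epi <- is.na(d$incidence_i) & is.na(d$prevalence_j)
  if (any(no_epi)) {
    stop_arg("diseases with neither incidence nor prevalence: ",
             paste(d$disease_id[no_epi], collapse = ", "))
  }
  if (any(!is.na(d$incidence_i) & d$incidence_i < 0)) {
    stop_arg("negative incidence")
  }
  if (any(!is.na(d$prevalence_j) & d$prevalence_j < 0)) {
    stop_arg("negative prevalence")
  }
  needs_conv <- xor(is.na(d$incidence_i), is.na(d$prevalence_j))
  p_ok <- !is.na(d$survival_p) & d$survival_p >= 0 & d$survival_p < 1
  k_ok <- !is.na(d$survival_k) & d$survival_k > 0
  if (any(needs_conv & !(p_ok & k_ok))) {
    stop_arg("steady-state conversion needs survival_p in [0,1) and ",
             "survival_k > 0 for: ",
             paste(d$disease_id[needs_conv & !(p_ok & k_ok)], collapse = ", "))
  }
  mix <- as.matrix(d[, c("age_minor", "age_adult", "age_elderly")])
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-9)) {
    stop_arg("age mix must be nonnegative and sum to 1")
  }
  if (any(d$delta_qaly <= 0)) stop_arg("delta_qaly must be positive")
  ef <- d$eligible_fraction
  if (any(ef <= 0 | ef > 1)) stop_arg("eligible_fraction must be in (0, 1]")

  linked <- which(!is.na(d$parent_disease_id) & d$parent_disease_id != "")
  for (i in linked) {
    pid <- d$parent_disease_id[i]
    pi <- match(pid, d$disease_id)
    if (is.na(pi)) stop_arg("parent disease not found: ", pid)
    if (!isTRUE(attr(registry, "overlap_adjusted"))) {
      for (col in c("incidence_i", "prevalence_j")) {
        cv <- d[[col]][i]; pv <- d[[col]][pi]
        if (!is.na(cv) && !is.na(pv) && cv > pv) {
          stop_arg("child ", d$disease_id[i], " exceeds parent ", pid,
                   " in ", col)
        }
      }
    }
  }
  invisible(registry)
}

#' @export
print.gt_registry <- function(x, ...) {
  cat(sprintf(
    "<gt_registry> %d diseases (%s), %d trials in %d programs\n",
    nrow(x$diseases),
    paste(sprintf("%s: %d", .CATEGORIES,
                  tabulate(factor(x$diseases$category, .CATEGORIES),
                           length(.CATEGORIES))), collapse = ", "),
    nrow(x$trials), length(unique(x$trials$program_id))))
  invisible(x)
}

#' Read a registry from two CSV tables
#'
#' `diseases.csv` columns: `disease_id,name,category,therapeutic_area,`
#' `incidence_i,prevalence_j,survival_p,survival_k,age_minor,age_adult,`
#' `age_elderly,delta_qaly,prior_approval,parent_disease_id,eligible_fraction`.
#' `trials.csv` columns: `trial_id,disease_id,program_id,phase,start_date,`
#' `end_date` with ISO-8601 dates; an empty cell is a missing value.
#'
#' @param disease_path,trial_path paths to the two CSV files.
#' @return a validated `gt_registry`.
#' @export
read_registry <- function(disease_path, trial_path) {
  d <- utils::read.csv(disease_path, stringsAsFactors = FALSE,
                       colClasses = c(parent_disease_id = "character"))
  t <- utils::read.csv(trial_path, stringsAsFactors = FALSE)
  d$parent_disease_id[d$parent_disease_id == ""] <- NA_character_
  d$prior_approval <- as.logical(d$prior_approval)
  t$start_date <- as.Date(t$start_date)
  t$end_date <- as.Date(ifelse(t$end_date == "", NA, t$end_date))
  new_registry(d, t)
}

#' Write a registry to two CSV tables
#'
#' Inverse of [read_registry()]; dates are written ISO-8601 and missing
#' values as empty cells.
#'
#' @param registry a `gt_registry`.
#' @param disease_path,trial_path output CSV paths.
#' @return the two paths, invisibly.
#' @export
write_registry <- function(registry, disease_path, trial_path) {
  d <- registry$diseases[, .DISEASE_COLS]
  t <- registry$trials[, .TRIAL_COLS]
  t$start_date <- format(t$start_date, "%Y-%m-%d")
  t$end_date <- ifelse(is.na(t$end_date), "",
                       format(t$end_date, "%Y-%m-%d"))
  utils::write.csv(d, disease_path, row.names = FALSE, na = "")
  utils::write.csv(t, trial_path, row.names = FALSE, na = "")
  invisible(c(disease_path, trial_path))
}

#' Generate a synthetic disease/trial registry
#'
#' Emulates the structure of a late-stage gene-therapy pipeline: a category
#' mix dominated by oncology, 1-4 development programs per disease, a
#' fraction of trials with missing declared end dates, at least one nested
#' (parent/child) disease pair for overlap adjustment, and at least one
#' disease with a previously approved therapy.  Epidemiology is drawn on
#' log scales plausible per category (prevalent patients: rare 1e2-1e4,
#' general 1e5-1e7, cancer 1e3-1e6) with k-year survival, and incidence and
#' prevalence linked at steady state; one of the two is blanked for a
#' subset of diseases so the steady-state conversions are exercised.
#' Expected incremental QALYs are drawn per category (rare 5-25, other
#' 0.5-5).
#'
#' @param n_diseases number of diseases (>= 1).
#' @param n_trials number of trials (>= `n_diseases`).
#' @param category_weights named probabilities over
#'   `c("cancer", "rare", "general")`, summing to 1.
#' @param seed optional integer seed; the same arguments and seed always
#'   reproduce the same registry.
#' @param missing_end_fraction fraction of trials whose declared end date is
#'   blanked (default 0.2).
#' @return a validated `gt_registry`.
#' @export
generate_registry <- function(n_diseases = 57, n_trials = 109,
                              category_weights = c(cancer = 0.50,
                                                   rare = 0.35,
                                                   general = 0.15),
                              seed = NULL,
                              missing_end_fraction = 0.2) {
  if (n_diseases < 1) stop_arg("n_diseases must be >= 1")
  if (n_trials < n_diseases) stop_arg("n_trials must be >= n_diseases")
  if (is.null(names(category_weights)) ||
      !setequal(names(category_weights), .CATEGORIES)) {
    stop_arg("category_weights must be named over ",
             paste(.CATEGORIES, collapse = ", "))
  }
  if (abs(sum(category_weights) - 1) > 1e-9) {
    stop_arg("category_weights must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)

  category <- sample(.CATEGORIES, n_diseases, replace = TRUE,
                     prob = category_weights[.CATEGORIES])
  area <- ifelse(category == "cancer", "Oncology",
                 sample(setdiff(.THERAPEUTIC_AREAS, "Oncology"),
                        n_diseases, replace = TRUE))
  prev_range <- list(rare = c(2, 4), general = c(5, 7), cancer = c(3, 6))
  prevalence <- vapply(seq_len(n_diseases), function(i) {
    r <- prev_range[[category[i]]]
    10^stats::runif(1, r[1], r[2])
  }, numeric(1))
  survival_k <- sample(3:10, n_diseases, replace = TRUE)
  survival_p <- stats::runif(n_diseases, 0.3, 0.9)
  incidence <- prevalence * (1 - survival_p) / survival_k
  mix <- matrix(stats::rgamma(3 * n_diseases, shape = 2), ncol = 3)
  mix <- mix / rowSums(mix)
  delta_qaly <- ifelse(category == "rare",
                       stats::runif(n_diseases, 5, 25),
                       stats::runif(n_diseases, 0.5, 5))
  prior <- stats::runif(n_diseases) < 0.07
  prior[1] <- TRUE
  diseases <- data.frame(
    disease_id = sprintf("D%03d", seq_len(n_diseases)),
    name = sprintf("%s disease %d", category, seq_len(n_diseases)),
    category = category,
    therapeutic_area = area,
    incidence_i = incidence,
    prevalence_j = prevalence,
    survival_p = survival_p,
    survival_k = as.numeric(survival_k),
    age_minor = mix[, 1], age_adult = mix[, 2], age_elderly = mix[, 3],
    delta_qaly = delta_qaly,
    prior_approval = prior,
    parent_disease_id = NA_character_,
    eligible_fraction = 1.0,
    stringsAsFactors = FALSE
  )

  # Blank one epidemiological field for ~30% of diseases so the steady-state
  # conversions are exercised on read.
  drop <- sample(c("none", "incidence", "prevalence"), n_diseases,
                 replace = TRUE, prob = c(0.7, 0.15, 0.15))
  diseases$incidence_i[drop == "incidence"] <- NA
  diseases$prevalence_j[drop == "prevalence"] <- NA

  # Nested pair: make disease 2 a sub-population of disease 1 when possible.
  if (n_diseases >= 2) {
    frac <- stats::runif(1, 0.2, 0.5)
    diseases$parent_disease_id[2] <- diseases$disease_id[1]
    diseases$category[2] <- diseases$category[1]
    diseases$therapeutic_area[2] <- diseases$therapeutic_area[1]
    for (col in c("incidence_i", "prevalence_j")) {
      diseases[[col]][2] <- diseases[[col]][1] * frac
    }
    if (is.na(diseases$incidence_i[2]) && is.na(diseases$prevalence_j[2])) {
      diseases$prevalence_j[2] <- prevalence[1] * frac
    }
  }

  disease_of_trial <- c(seq_len(n_diseases),
                        sample(seq_len(n_diseases), n_trials - n_diseases,
                               replace = TRUE))
  disease_of_trial <- sort(disease_of_trial)
  start <- as.Date("2014-01-01") +
    sample.int(2007, n_trials, replace = TRUE) - 1  # through 2019-06-30
  duration <- sample(365:1825, n_trials, replace = TRUE)
  end <- start + duration
  end[stats::runif(n_trials) < missing_end_fraction] <- NA
  trials <- data.frame(
    trial_id = sprintf("T%04d", seq_len(n_trials)),
    disease_id = diseases$disease_id[disease_of_trial],
    program_id = NA_character_,
    phase = sample(c("3", "2/3"), n_trials, replace = TRUE,
                   prob = c(0.6, 0.4)),
    start_date = start,
    end_date = end,
    stringsAsFactors = FALSE
  )
  # Partition each disease's trials into 1-4 development programs
  # (sponsor x disease trial sets).
  for (i in seq_len(n_diseases)) {
    idx <- which(disease_of_trial == i)
    k <- sample.int(min(4L, length(idx)), 1L)
    prog <- sample.int(k, length(idx), replace = TRUE)
    prog[seq_len(k)] <- seq_len(k)  # every program nonempty
    trials$program_id[idx] <- sprintf("%s-P%d", diseases$disease_id[i], prog)
  }
  new_registry(diseases, trials)
}

#' Subtract nested sub-population counts from their parent diseases
#'
#' Where a disease is declared a sub-population of another (for example a
#' type-I form of a broader disease), the parent's incidence and prevalence
#' are replaced by parent minus child so that overlapping patient
#' populations are not double-counted.  Idempotent: a registry that has
#' already been adjusted is returned unchanged.
#'
#' @param registry a `gt_registry`.
#' @return the adjusted `gt_registry` (attribute `overlap_adjusted` set).
#' @export
adjust_overlaps <- function(registry) {
  if (isTRUE(attr(registry, "overlap_adjusted"))) return(registry)
  d <- registry$diseases
  linked <- which(!is.na(d$parent_disease_id))
  for (i in linked) {
    pi <- match(d$parent_disease_id[i], d$disease_id)
    for (col in c("incidence_i", "prevalence_j")) {
      cv <- d[[col]][i]; pv <- d[[col]][pi]
      if (!is.na(cv) && !is.na(pv)) {
        if (cv > pv) {
          stop_arg("child ", d$disease_id[i], " exceeds parent in ", col)
        }
        d[[col]][pi] <- pv - cv
      }
    }
  }
  registry$diseases <- d
  attr(registry, "overlap_adjusted") <- TRUE
  registry
}
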