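# Programmatic fixtures: small registries built in code.

make_disease <- function(disease_id = "D1", name = disease_id,
                         category = "rare", area = "CNS",
                         incidence = 100, prevalence = 1000,
                         survival_p = 0.5, survival_k = 5,
                         age_mix = c(1, 1, 1) / 3, delta_qaly = 10,
                         prior_approval = FALSE, parent = NA_character_,
                         eligible_fraction = 1) {
  data.frame(
    disease_id = disease_id, name = name, category = category,
    therapeutic_area = area, incidence_i = incidence,
    prevalence_j = prevalence, survival_p = survival_p,
    survival_k = survival_k,
    age_minor = age_mix[1], age_adult = age_mix[2],
    age_elderly = age_mix[3], delta_qaly = delta_qaly,
    prior_approval = prior_approval, parent_disease_id = parent,
    eligible_fraction = eligible_fraction, stringsAsFactors = FALSE)
}

make_trial <- function(trial_id, disease_id, program_id = NULL,
                       phase = "3", start = "2018-01-01",
                       end = "2021-01-01") {
  data.frame(
    trial_id = trial_id, disease_id = disease_id,
    program_id = program_id %||% paste0(disease_id, "-P1"), phase = phase,
    start_date = as.Date(start),
    end_date = as.Date(if (is.na(end)) NA else end),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n diseases, `programs_each` one-trial programs per disease, uniform
# parameters; trials end 2021-06-30 so approvals land mid-horizon.
toy_registry <- function(n = 4, programs_each = 1, area = "CNS",
                         category = "rare", prior = FALSE,
                         start = "2018-01-01", end = "2021-06-30", ...) {
  ids <- sprintf("D%02d", seq_len(n))
  diseases <- do.call(rbind, lapply(ids, function(id) {
    make_disease(id, category = category, area = area,
                 prior_approval = prior, ...)
  }))
  trials <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(seq_len(programs_each), function(p) {
      make_trial(sprintf("%s-T%d", id, p), id,
                 program_id = sprintf("%s-P%d", id, p), start = start,
                 end = end)
    }))
  }))
  new_registry(diseases, trials)
}

# One prior-approval rare disease with no uncertainty anywhere: the
# closed-form single-disease scenario (incidence 120/yr, no existing
# stock, delta-QALY 10).
plateau_registry <- function() {
  d <- make_disease("D1", category = "rare", incidence = 120,
                    prevalence = 0, delta_qaly = 10, prior_approval = TRUE)
  new_registry(d, make_trial("T1", "D1"))
}

plateau_config <- function(n_iterations = 1, ...) {
  simulation_config(n_iterations = n_iterations, dispersion = 0,
                    price_mod = price_model(rare = 1e5, other = 4e4),
                    seed = 1, ...)
}
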