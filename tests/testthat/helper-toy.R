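## small deterministic datasets used across tests

toy_dataset <- function() {
  subjects <- data.frame(
    subject_id = c("a", "b", "c"),
    time = c(2, 5, 7), event = c(1, 0, 1),
    z1 = c(0, 1, 1), z2 = c(0.5, -1, 2))
  visits <- do.call(rbind, lapply(seq_len(3), function(i) {
    tt <- seq(0, subjects$time[i], by = 1)
    tt <- tt[tt <= subjects$time[i]]
    data.frame(subject_id = subjects$subject_id[i], visit_time = tt,
               y1 = tt + i, y2 = 2 * tt - i)
  }))
  longitudinal_data(subjects, visits)
}

## one subject, explicit values
single_subject <- function(y1, times = seq_along(y1) - 1, T = max(times) + 1,
                           event = 1) {
  longitudinal_data(
    data.frame(subject_id = "s1", time = T, event = event, z1 = 1),
    data.frame(subject_id = "s1", visit_time = times, y1 = y1))
}

sim_pair <- function(scenario, n_train, n_eval, seed = 7) {
  tr <- simulate_scenario(scenario, n_subjects = n_train, seed = seed)
  ev <- simulate_scenario(scenario, n_subjects = n_eval, seed = seed + 1000)
  ev$data$subjects$subject_id <- paste0("e", ev$data$subjects$subject_id)
  ev$data$visits$subject_id <- paste0("e", ev$data$visits$subject_id)
  ev$truth$subject_id <- paste0("e", ev$truth$subject_id)
  list(train = tr$data, train_truth = tr$truth,
       eval = ev$data, truth = ev$truth)
}
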