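# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ref_anthro <- function() anthropometry("ref", body_mass = 79, body_height = 1.8)

# Small cohort x battery dataset (idealized features) for estimator and
# sweep tests: 3 participants x 8 tasks.
micro_dataset <- function() {
  memo("micro_dataset", function() {
    cohort <- sample_cohort(3, seed = 11)
    battery <- build_task_battery(masses = c(0, 10, 23), repetitions = 1,
                                  styles = c("squat", "stoop"),
                                  seed = 11)
    calibrate_insoles(simulate_dataset(cohort, battery[1:8, ], seed = 11))
  })
}

micro_cohort <- function() attr(micro_dataset(), "cohort")

# A single mid-size simulated trial reused across dynamics/feature tests.
ref_trial <- function() {
  memo("ref_trial", function() {
    suppressWarnings(simulate_trial(
      ref_anthro(), task_spec("tref", 10, "low", "mid", style = "squat"),
      seed = 42))
  })
}

moment_series_for_test <- function(ext_nm) {
  lumbarload:::moment_series(0, ext_nm, 0, 100, units = "Nm",
                             source = "lab_truth")
}

rel_rms <- function(a, b) {
  sqrt(mean((a - b)^2)) / max(sqrt(mean(b^2)), 1e-300)
}
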