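#' Simulate a full two-condition replication experiment
#'
#' Draws `n_observers` simulated observers from a population and runs each
#' through one control session (11 levels x `reps` matches = 110 trials by
#' default) and one adaptation session (6 levels x `reps` = 60 trials),
#' returning the pooled trial records. This is the study design behind the
#' packaged reference analysis: 2 observers x 170 trials = 340 records.
#'
#' @param pop A [population_params()]; defaults to the reference estimates.
#' @param n_observers Number of simulated observers.
#' @param reps Matches per contrast level per condition.
#' @param seed Seed governing observer draws and both sessions per observer.
#' @return A trial-record tibble (see [run_headless_session()]).
#' @export
simulate_replication_experiment <- function(pop = population_params(),
                                            n_observers = 2L,
                                            reps = 10L, seed = 1L) {
  stopifnot(inherits(pop, "population_params"), n_observers >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- lapply(seq_len(n_observers), function(i) {
    obs <- sample_observer(pop)
    id <- sprintf("obs%02d", i)
    seeds <- sample.int(.Machine$integer.max, 2L)
    rbind(
      run_headless_session(
        session_config("replication", "control", reps = reps,
                       seed = seeds[1]), obs, observer_id = id),
      run_headless_session(
        session_config("replication", "adaptation", reps = reps,
                       seed = seeds[2]), obs, observer_id = id))
  })
  tibble::as_tibble(do.call(rbind, out))
}
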