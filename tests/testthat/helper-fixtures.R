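# Shared fixtures: the hand-checkable worked example and a small helper
# to write its tables to a temporary directory as CSV inputs.

worked <- make_worked_example()

write_worked_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    roster = file.path(dir, "roster.csv"),
    consumption = file.path(dir, "consumption.csv"),
    fct = file.path(dir, "fct.csv"),
    groupmap = file.path(dir, "groupmap.csv"),
    footprint = file.path(dir, "footprint.csv"))
  write_results(worked$roster, paths$roster)
  write_results(worked$consumption, paths$consumption)
  write_results(worked$fct, paths$fct)
  write_results(worked$groupmap, paths$groupmap)
  write_results(worked$footprint, paths$footprint)
  paths
}

# per-AFE table of the worked example, computed once
worked_tab <- per_afe_table(worked$roster, worked$consumption, worked$fct,
                            worked$groupmap)

# small deterministic generator config for fast tests
small_gen <- function(n = 400, seed = 42, ...) {
  generator_config(n_households = n, seed = seed, ...)
}
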