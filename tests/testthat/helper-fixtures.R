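# Shared synthetic fixtures, built once per test run.  The small bundle
# backs the module tests; the large one backs the planted-event recovery
# and ORF-equivalence checks.

.fx <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fx$small)) {
    dir <- file.path(tempdir(), "stope-fx-small")
    .fx$small <- suppressMessages(suppressWarnings(
      generate_fixtures(dir, n_per_type = 3L, seed = 42L)))
  }
  .fx$small
}

small_run <- function() {
  if (is.null(.fx$small_run)) {
    b <- small_fixture()
    .fx$small_run <- suppressMessages(suppressWarnings(
      run_pipeline(b$paths, file.path(tempdir(), "stope-out-small"),
                   config = pipeline_config(seed = 42L))))
  }
  .fx$small_run
}

big_fixture <- function() {
  if (is.null(.fx$big)) {
    dir <- file.path(tempdir(), "stope-fx-big")
    .fx$big <- suppressMessages(suppressWarnings(
      generate_fixtures(dir, n_per_type = 20L, seed = 2024L)))
  }
  .fx$big
}

big_run <- function() {
  if (is.null(.fx$big_run)) {
    b <- big_fixture()
    .fx$big_run <- suppressMessages(suppressWarnings(
      run_pipeline(b$paths, file.path(tempdir(), "stope-out-big"),
                   config = pipeline_config(seed = 2024L))))
  }
  .fx$big_run
}

# match truth events to emitted event ids by (type, chrom, coords)
truth_event_ids <- function(bundle, events) {
  tkey <- vapply(bundle$truth$events, function(e)
    paste(e$event_type, e$chrom, e$start, e$end), "")
  ekey <- paste(events$event_type, events$chrom, events$start, events$end)
  setNames(events$event_id[match(tkey, ekey)], tkey)
}
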