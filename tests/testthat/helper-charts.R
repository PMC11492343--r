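# Shared synthetic-chart fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# a clean reference chart (volume 30 cm3, 145 Gy) rendered in both formats
clean_chart_dir <- function() {
  if (is.null(.fixtures$clean_dir)) {
    dir <- file.path(tempdir(), "psichart-clean")
    params <- chart_params("P001", prostate_volume = 30, dose = 145)
    generate_chart(params, dir, formats = c("docx", "pdf"))
    .fixtures$clean_dir <- dir
  }
  .fixtures$clean_dir
}

clean_chart <- function(prefer = "docx") {
  key <- paste0("clean_", prefer)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- load_chart(clean_chart_dir(), prefer = prefer)
  .fixtures[[key]]
}

# a fresh copy of the clean chart for mutation
mutable_chart_dir <- function() {
  dir <- tempfile("psichart-mut")
  params <- chart_params("P001", prostate_volume = 30, dose = 145)
  generate_chart(params, dir, formats = c("docx", "pdf"))
  dir
}

default_registry <- function() {
  if (is.null(.fixtures$registry)) .fixtures$registry <- load_schemas()
  .fixtures$registry
}
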