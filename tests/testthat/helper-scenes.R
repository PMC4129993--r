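# Suite scenes and detector runs are expensive; generate each at most once
# per test session and share across test files.

.fixtures <- new.env(parent = emptyenv())

suiteScene <- function(name) {
  key <- paste0("scene_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateScene(standardSuite()[[name]])
  .fixtures[[key]]
}

suiteDetection <- function(name) {
  key <- paste0("det_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- detectSequence(suiteScene(name))
  .fixtures[[key]]
}

suiteBaseline <- function(name) {
  key <- paste0("base_", name)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- gaussianBaselineDetect(suiteScene(name))
  .fixtures[[key]]
}
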