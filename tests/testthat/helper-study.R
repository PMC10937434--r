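# The end-to-end phantom experiment is expensive (~100 structure sets), so
# it runs once per test session and is shared by the tests that assert on
# its outcomes.

.studyCache <- new.env(parent = emptyenv())

getStudy <- function() {
  if (is.null(.studyCache$study))
    .studyCache$study <- suppressWarnings(suppressMessages(
      phantomStudy(seed = 1)))
  .studyCache$study
}
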