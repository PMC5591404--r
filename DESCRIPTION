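Package: etnt
Title: Eye Tracker Neglect Test Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for administering and analysing gaze-based cancellation
    tests used to assess visuospatial neglect after stroke. Generates
    stimulus boards of targets and distractors, scores timestamped gaze
    recordings with a dwell-based detection rule (a stimulus counts as
    found when gaze is held within its zone for a minimum duration),
    derives neglect indexes, search-strategy classifications and gaze
    heat maps, computes clinical summary scores (anosognosia index,
    training adherence, nonparametric effect sizes with exact small-sample
    tests), and simulates synthetic neglect-patient gaze so the whole
    pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
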