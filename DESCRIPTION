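Package: lickdistract
Title: Distraction During Licking: Behavioural Triggers, Fibre Photometry and
    Bin-Wise ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lick-triggered distraction experiments in
    rodents. Detects burst-triggered distractor events from lick trains,
    classifies trials as distracted from post-event pauses, builds
    modelled-distractor nulls, corrects dual-channel fibre-photometry signals
    (calcium-modulated 470 nm against the isosbestic 405 nm reference) into
    dF/F, extracts event-aligned z-scored snips, and compares trial classes
    with bin-wise ROC/AUC (Bonferroni corrected) and repeated-measures
    statistics. Ships a closed-loop synthetic-session generator with ground
    truth so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
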