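Package: lotengine
Title: Deterministic Enumeration of Lines of Therapy in Solid Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable rule engine for enumerating lines of
    therapy (LoT) from chronological treatment histories of patients with
    solid cancers. Ingests a standardized tabular dataset of therapy
    segments (clinical setting, treatment intent, date of most recent
    clinical progression, anti-cancer modality, start/stop dates, stop
    reason, structured agent lists), decides which segments qualify as
    systemic anti-cancer therapy (SACT), groups segments into lines under a
    set of draft consensus guidelines, dichotomizes each line into the
    curative or palliative track, and emits labels in the
    'N (CLoT + PLoT)' format together with a per-decision rule trace.
    Includes a seeded generator of synthetic patient histories with
    by-construction ground-truth labels, CSV/TSV readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
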