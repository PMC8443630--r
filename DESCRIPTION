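Package: leadsync
Title: Leadership Emergence in Group Synchronization Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize leadership emergence in groups
    performing a joint oscillatory task. Extracts per-player motion phases from
    position time series via the analytic-signal (Hilbert) method, ranks players
    by a phase leadership index, infers directed influence between players with
    causation entropy (including optimal causation entropy network discovery),
    classifies trials into three leadership patterns, and relates pattern
    emergence to group coordination measured by the Kuramoto order parameter.
    Includes a coupled phase-oscillator simulator with planted leaders for
    ground-truthed validation on the four visual-coupling topologies
    (complete, path, ring, star).
License: MIT + file LICENSE
Encoding: UTF-8
Imports: signal, jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
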