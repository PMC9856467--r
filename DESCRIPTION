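Package: mscdetect
Title: Multi-Site Seizure Detection from Coherence Maps and Cross-Correlation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizure onsets in multichannel local field
    potential (LFP) or intracranial EEG recordings by exploiting multi-site
    synchronization changes. Magnitude-squared-coherence (MSC) maps computed
    per channel pair are scanned with a Canny-style edge detector to select a
    subject-specific frequency band and the channel pairs with the strongest
    coherence increase at seizure onset. Detection then runs on sliding-window
    maximal cross-correlation curves: the mean (AVG) over selected pairs and
    the standard deviation (STD) over selected plus background pairs are
    thresholded with iteratively verified thresholds (Th = u + 3*sd).
    Includes a synthetic multichannel LFP generator with controllable
    band-limited coupling for end-to-end validation, comparison baselines
    (mean phase coherence and common single-channel features), and EDF/CSV
    input support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
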