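Package: affectbandit
Title: Affect-Adaptive Interaction Style Selection with Thompson Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for affect-adaptive human-agent interaction. Maps
    categorical facial-emotion labels to valence scores, computes a
    per-turn mean-valence reward and its turn-to-turn change, and runs
    a Beta-Bernoulli Thompson Sampling policy that selects between
    communicative styles (e.g. neutral vs enthusiastic) so as to
    reinforce the style that maintains or improves the user's affective
    valence. Includes a synthetic affective-user simulator, a session
    orchestrator producing replayable per-turn logs, and analysis
    helpers (posterior trajectories, Spearman trait correlations,
    cumulative regret) for evaluating adaptation dynamics at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
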