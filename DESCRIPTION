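Package: inteinscreen
Title: Split-Intein Orthogonality Screening and Assembly Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for split-intein characterization screens
    built on split fluorescent-protein reporters. Normalizes plate-reader
    fluorescence and OD600 measurements (blank, density and negative-control
    correction), builds N-half by C-half cross-reactivity matrices, applies a
    two-threshold orthogonality criterion and computes mutually orthogonal
    split-intein sets, estimates splicing efficiency from dual-antibody
    Western-blot band intensities, calls splicing activity and kinetic classes,
    aggregates reaction-condition screens, plans one-pot and recursive
    solid-phase intein-mediated assembly of repetitive proteins with
    incomplete-splicing ladder predictions, evaluates intein-split
    transcription-factor logic circuits, and generates fully synthetic
    datasets with ground-truth labels for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
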