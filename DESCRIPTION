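Package: isletsim
Title: Local-Concentration Modelling of Glucose-Stimulated Insulin Release
    in Perifused Pancreatic Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dynamic glucose-stimulated insulin release (GSIR) of
    avascular pancreatic islets in a perifusion chamber. Hill-type rate laws for
    oxygen and glucose consumption and for biphasic (first- and second-phase)
    insulin secretion, driven by the local glucose concentration and its time
    derivative and limited by local oxygen availability, are coupled to
    convection-diffusion transport of four species (oxygen, glucose, released and
    cell-local insulin) over a steady low-Reynolds flow field. Includes a
    one-dimensional spherically symmetric reduced solver, protocol drivers for
    glucose staircases, single steps, incoming-oxygen sweeps and free versus
    hydrogel-encapsulated islet comparisons, Hill-equation dose-response fitting,
    and a YAML configuration layer with unit-suffixed keys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    generics,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
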