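Package: TuringMimic
Title: Cellular-Automaton Turing Patterns and Inverse Parameter
    Estimation for Pattern Mimicry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates binary Turing-type patterns (spots and stripes)
    with a two-parameter cellular automaton that applies a paired disc
    filter -- short-range activation within radius s, long-range
    inhibition weighted by w within radius 2s -- on a toroidal grid, and
    estimates both parameters back from an observed binary pattern by
    scanning candidate radii with an edge-consistency index. Composing
    the two gives an observe-estimate-regenerate mimicry round trip,
    a model of rapid background matching by cephalopod skin. Also
    includes preprocessing of grayscale photographs into model grids,
    plain-text and bitmap grid formats, seeded pattern fixtures, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
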