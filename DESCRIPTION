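Package: andyn
Title: Fixed Points and Attractors of Multi-Valued Automata Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models discrete biological regulatory networks as automata
    networks: finite automata with multi-valued activity levels coupled by
    conditional local transitions.  Implements the non-deterministic
    asynchronous and synchronous update semantics, exhaustive enumeration of
    steady states (global states with no playable transition), and exhaustive
    enumeration of non-singleton attractors (minimal trap domains) as traces
    of length-n trap cycles, including complex "star" attractors whose
    shortest covering cycle is longer than their trace.  A brute-force
    state-transition-graph oracle based on terminal strongly connected
    components verifies every result, and a seeded random-network generator
    supports property-style testing.  Readers and writers are provided for a
    plain-text network format and for a logic-programming facts dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
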