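Package: semdecode
Title: Semantic Decoding of Visual Scenes from Intracranial High-Gamma Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to embed annotated visual scenes into a word-embedding
    semantic space, decode that space from high-gamma band power features of
    intracranial recordings with ridge regression under source-grouped nested
    cross-validation, simulate and evaluate a closed-loop semantic
    neurofeedback system, and quantify imagery-driven modulation of decoded
    semantic vectors. Includes a synthetic-data generator with the statistical
    structure the analysis assumes (linear encoding of semantic and low-level
    stimulus features, session gain drift, additive imagery gain), low-level
    motion-energy and auditory modulation-transfer stimulus features, all four
    accuracy measures (dimension-wise, projected, scene-wise correlations and
    scene identification), and permutation machinery (clip-shuffle and
    target-shuffle nulls) with standard multiple-testing corrections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
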