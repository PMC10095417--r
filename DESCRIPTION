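Package: lanthominer
Title: Genome Mining and Mass-Spectrometric Verification of Nisin-Family Lanthipeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for discovering and verifying nisin-family
    lanthipeptides. Mines genome sequences for precursor open reading frames by
    similarity to a panel of known mature cores, splits leader and core
    peptides, reconciles deduced against observed intact masses by counting
    post-translational dehydrations, generates in-silico tryptic digests with
    fixed and variable modifications and targeted-MS inclusion lists, matches
    theoretical targets against observed peak lists with sequence-coverage
    accounting, threads lanthionine ring topologies from a template structure,
    and compares candidate variants against known nisins by percent identity,
    substitution lists, p-distances and neighbor-joining trees. Includes a
    seeded synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
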