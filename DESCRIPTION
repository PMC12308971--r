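Package: litatlas
Title: Literature Co-Occurrence Atlas of Gene and Cell-Type Relations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a queryable atlas of gene to cell-type relations from
    per-article named-entity annotations of biomedical literature. Annotated
    articles (PubTator or line-delimited record formats) are filtered against
    offline gene and cell-type concept catalogs, aggregated into per-pair
    evidence counts (distinct supporting articles and total co-occurrences),
    and ranked with a log-normalised relevance score. Includes a Cell
    Ontology style OBO parser with a graph distance between cell-type terms,
    a marker-gene benchmark that compares the atlas against a curated marker
    database via top-1 hit distances, exportable co-occurrence graphs, fully
    seeded synthetic data generators for end-to-end testing, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
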