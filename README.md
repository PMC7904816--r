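# mdlink

Text-mining of microbe–disease associations from biomedical sentences.

A fast-growing literature reports which bacteria and viruses cause,
aggravate, or accompany which diseases, but curated association databases
cover only a sliver of it. mdlink implements a three-stage extraction
pipeline for this problem, aimed at bioinformaticians who want to mine
association tables and disease-similarity networks from sentence-level
text:

1. **Entity tagging** — longest-match dictionary NER over microbe and
   disease lexicons; mentions collapse into single tagged tokens
   (`BAC00Helicobacter_pylori`, `DIS00gastritis`).
2. **Relation detection** — a hierarchical bidirectional LSTM with
   entity-based attention decides, per candidate microbe–disease pair,
   whether the sentence asserts an association. The sentence is split into
   the phrases before/between/after the entities (Seq1–3) plus the
   shortest dependency path (SDP); four bottom bi-LSTMs encode these, and
   a top bi-LSTM consumes [Seq1, E1, Seq2, E2, Seq3, SDP] into a binary
   softmax. Attention weights each token by
   θᵢ = ½·(softmax(wᵢ·e₁) + softmax(wᵢ·e₂)). Implemented from scratch in
   RcppArmadillo (forward, backpropagation-through-time, Adam).
3. **Relation-word extraction** — an ensemble of two parse-tree methods:
   *TPE*, a tree-pattern-expression matcher over constituency parses
   (regex node labels, subtree wildcards `*`, sibling gaps `**`, capture
   groups `1#`/`2#`/`3#` for microbe/disease/relation), and *DBE*,
   dependency-tree rules (of/with chunking, a distance filter, preposition
   connectors, lowest-common-ancestor rules, coordination inheritance).
   Each triplet is scored with a Bayes confidence,
   conf(r) = maxᵢ Pr(pᵢ | r) with
   Pr(pᵢ|r) = Pr(r|pᵢ)Pr(pᵢ) / (Pr(r|pᵢ)Pr(pᵢ) + Pr(r|¬pᵢ)Pr(¬pᵢ)),
   where the prior Pr(pᵢ) is the pattern's precision; triplets below a
   confidence threshold (default 0.5) are dropped.

Downstream, triplets aggregate into a per-(microbe, disease) association
table (with exclusion of generic terms and a below-mean-count filter) and
a disease–disease network connecting diseases whose associated microbe
sets have Jaccard similarity ≥ 0.6.

A deterministic synthetic-corpus generator (`generate_corpus()`) emits
annotated sentences *with gold constituency and dependency trees* from
hand-written template schemas, so the whole pipeline is testable without
an external parser or any download.

## Worked example

```r
library(mdlink)

mic <- lexicon(c("Klebsiella pneumoniae"), "MICROBE")
dis <- lexicon(c("sepsis", "pneumonia"), "DISEASE")
s <- tag_entities(
  "Klebsiella pneumoniae, a common cause of sepsis, is associated with pneumonia.",
  mic, dis, sentence_id = "ex1")
s
#> <mdlink_sentence ex1: 13 tokens, 3 mentions>
#>   BAC00Klebsiella_pneumoniae , a common cause of DIS00sepsis , is associated with DIS00pneumonia .
```

With a constituency and a dependency tree for the tagged sentence (from a
fixture file or your parser; the synthetic generator makes gold ones), the
two shipped tree patterns extract both asserted triplets:

```r
ps <- provide(s, provider)          # attach the parse trees
extract_triplets(ps, mdlink_patterns())
#> # A tibble: 2 × 7
#>   sentence_id microbe               disease   relation  relation_surface extractor pattern_ids
#> 1 ex1         Klebsiella_pneumoniae pneumonia associate associated       TPE       passive_participle
#> 2 ex1         Klebsiella_pneumoniae sepsis    cause     cause            TPE       appositive_commas
```

The relation word is stemmed (`associated → associate`), and each row
carries the extracting pattern as provenance for the ensemble's
confidence model. The dependency extractor runs the same way
(`extract_dbe(ps)`), and `merge_extractions()` unions and scores the two
streams.

An end-to-end synthetic run:

```r
corpus <- generate_corpus(fixtures_config(n_sentences = 1000, seed = 7))
cp     <- corpus_pairs(corpus)
emb    <- random_embeddings(200, 42)
cv     <- cv_detector(cp$pairs, cp$labels, emb,
                      detector_config(epochs = 5, seed = 5),
                      folds = 10, seed = 11)
cv$mean
#> # A tibble: 1 × 3
#>   precision recall    f1
#> 1         1  0.997 0.999

compare_extractors(corpus, threshold = 0.5, seed = 3)$metrics
#> # A tibble: 3 × 4
#>   method   precision recall    f1
#> 1 TPE          0.324  0.307 0.312
#> 2 DBE          0.912  0.899 0.904
#> 3 ensemble     1      1     1
```

The detector's tenfold cross-validated pair-level F on the synthetic
corpus is ~0.999 (the planted relation words make the task nearly
separable; a 10% noise knob swaps relation words for unseen synonyms).
The extraction comparison shows the characteristic ensemble behavior: TPE
alone covers only the construction families its two shipped patterns
describe, DBE covers most constructions but mis-handles appositives, and
their confidence-weighted union dominates both.

A thin CLI for the file-level steps (tagging, fixture generation,
extraction, network building) ships as `inst/cli/mdlink.R` — locate it
with `system.file("cli/mdlink.R", package = "mdlink")` and run it with
`Rscript`; the usage block sits at the top of the file. Model training
and evaluation are R-session activities (see above).

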