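---
title: "Mining microbe-disease associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining microbe-disease associations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlink)
```

mdlink extracts *(microbe, disease, relation word)* triplets from biomedical
sentences in three stages — dictionary entity tagging, neural relation
detection, and parse-tree relation-word extraction — and aggregates the
triplets into association tables and a disease-similarity network. This
vignette describes each model, its assumptions, the tunable parameters, and
the design decisions taken where more than one reasonable reading existed.

## Entity tagging

Microbes and diseases are recognized by longest-match, leftmost-first
dictionary lookup over the token stream, one lexicon at a time. A matched
multi-word mention is collapsed into a single tagged token
(`BAC00Pseudomonas_aeruginosa`, `DIS00acute_lung_injury`), so downstream
parse trees carry one token per mention and entity alignment is positional.
Three choices matter:

* **Tokenization** splits on whitespace and separates `.,;:!?()[]{}"'` into
  their own tokens while keeping hyphens and underscores word-internal.
  Canonical names are sanitized to survive re-tokenization, which makes
  tagging idempotent.
* **Cross-class overlaps** are resolved microbe-first by default (strain
  vocabularies are more specific than disease vocabularies); the priority
  is a function argument.
* **Acronym safety**: single-token all-uppercase lexicon entries (e.g.
  `MRSA`) are matched case-sensitively, everything else case-insensitively.

The package does not attempt model-based disease NER or normalization to
ontology identifiers; the lexicon is the contract. Token positions are
1-based inclusive indices throughout, the natural R convention (CoNLL-U's
1-based `HEAD` with `0` for the root then needs no boundary conversion).

## Relation detection

For every co-mentioned microbe-disease pair the sentence is split into the
phrase before the first entity (Seq1), between the entities (Seq2), and
after the second entity (Seq3); the shortest dependency path (SDP) between
the entity tokens supplies the syntactic core. Each token is embedded as a
240-dim feature: a 200-dim word vector, 10-dim POS and dependency-tag
embeddings (trained jointly from random initialization), and a 20-dim
position feature — two 10-bin one-hots of the signed distance to each
entity, clipped to $[-4, +5]$.

Entity-based attention reweights the word vectors before the recurrent
layers: per entity $e_k$, token weights are the softmax of the dot products
$w_i \cdot e_k$ over the tokens of a segment, and the final weight is the
mean of the two entity-specific weight vectors,
$\theta_i = (\theta_i^1 + \theta_i^2)/2$. Each $\theta^k$ sums to one, so
the average does too and no renormalization is applied. The weights
multiply the word-vector block of the features; attention is computed per
segment because each bottom LSTM consumes one segment.

Four many-to-one bidirectional LSTMs (hidden size 100 per direction; 60
time steps per segment, 12 for the SDP) encode Seq1/Seq2/Seq3/SDP into a
$4 \times 200$ matrix. The "many-to-one" output is the concatenation of the
last forward and last backward hidden states — this is the reading that
produces the stated 200-width output. Interleaving the two entity
embeddings (the mean of the canonical name's word vectors) in sentence
order, $[\mathrm{Seq1}, E_1, \mathrm{Seq2}, E_2, \mathrm{Seq3},
\mathrm{SDP}]$, gives the $6 \times 200$ input of a top bi-LSTM, whose
200-dim output feeds a linear layer and a binary softmax. The constraint
$2 \cdot \mathrm{hidden} = \mathrm{word\ dim}$ is enforced at configuration
time because entity embeddings and bottom outputs share the top input
width.

Training uses cross-entropy with Adam (learning rate 0.001, 30 epochs by
default), gradients averaged over minibatches of 16, and inverted dropout
on the input features (keep 0.7) and the top output (keep 0.5). The
published dropout "rates" are ambiguous between keep- and drop-probability;
keep-probability is the default and `dropout_semantics = "drop"` flips the
reading. Sequences longer than their time-step budget are truncated at the
end farthest from the nearest entity (Seq1 keeps its tail, Seq3 its head,
Seq2 and the SDP keep both ends), since entity-adjacent context carries the
relation. Forward/backward propagation and the optimizer are implemented in
C++ (RcppArmadillo); correctness of the hand-written backpropagation is
pinned by a finite-difference gradient check in the test suite, and
inference is bit-deterministic. Ties at probability 0.5 predict the
negative class. Sentence-level evaluation reduces a sentence to "at least
one pair asserted / predicted" — a natural reading, since no finer
definition is standard.

## Tree-pattern extraction (TPE)

Tree pattern expressions are queries over constituency trees:
`{LABEL_RE child ...}` matches an internal node and its child sequence,
`<POS_RE WORD_RE>` a leaf, `*` exactly one arbitrary subtree, `**` a gap of
zero or more consecutive subtrees, and a `k#` prefix on a word regex marks
capture `k` (1 microbe, 2 disease, 3 relation word). Regexes are anchored
PCRE. Anchors are tried at every node; child sequences are matched left to
right with backtracking over gaps, and the matcher is validated against an
exhaustive embedding oracle on hundreds of random tree/pattern cases. The
`*`-vs-`**` distinction is declared, not inherited from any prior tool: one
subtree versus a sibling gap.

The package ships the two published example patterns in canonicalized form
(typesetting artifacts such as `.*+` and stray spaces normalized to `.+`):
an appositive-with-commas pattern whose noun head is the relation word, and
a passive/copular participle pattern whose `VBN` is the relation word. In
the participle pattern the published rendering collapses bracket types and
omits capture markers; the canonical form restores `{}` node syntax, adds
the three captures, and uses gaps where the printed single wildcards would
otherwise hard-code arity. The remaining pattern library is user data, not
code: patterns load from a TSV (`read_patterns()`), and every extraction
carries its pattern id as provenance.

## Dependency-based extraction (DBE)

Three preprocessing steps and three rules, applied in a fixed, observable
order (chunk, distance filter, preposition rule, LCA rules, inheritance):

1. **Chunking.** Where an entity hangs off a word through an `of`/`with`
   prepositional edge, that word absorbs its `amod`/`compound` modifiers
   (`common cause of DIS00sepsis` becomes a `common_cause` node). A
   non-entity word `compound`-linked to an entity merges into the entity
   node and is remembered as its `chunk_word`. Merges are edge
   contractions, innermost first, so the result remains a single-headed
   tree partitioning the original tokens.
2. **Distance filter.** Pairs farther than 4 steps apart in the chunked
   tree are dropped; `conj`, `conj:and`, `conj:or`, `compound` and `appos`
   edges are not counted, because they join co-mentioned entities rather
   than separate them. The boundary value 4 is retained and the cutoff is
   configurable. The edge list is treated as exact.
3. **Rules.** A direct entity-entity edge through a listed connector
   (`by`, `in`, `from`, `on`, `with`, `of`, `due to`, `induced`,
   `between`) emits the connector (`PREP_SIMPLE`). Otherwise the lowest
   common ancestor decides: a child of the LCA attached by a descriptive
   edge (`acl`, `acl:relcl`, `amod`, `xcomp`, `ccomp`, `appos`, `nmod:as`,
   `conj:and`, `conj:or`, `advcl`, `dep`) is the relation word
   (`LCA_CHILD`); with no qualifying child the LCA's own — possibly
   chunk-merged — word is used (`LCA_NODE`). When several children
   qualify, priority follows the order of the edge list (clausal before
   adjectival modifiers), then sentence position: in *"an emerging
   pathogen implicated in ..."* both `emerging` (amod) and `implicated`
   (acl) qualify, and the acl child is the relation word; pure
   left-to-right choice would pick the adjective. When one entity
   dominates the other, its `chunk_word` is the relation if one exists
   (`NO_LCA_CHUNK`); otherwise the label of the edge toward the other
   entity is emitted (`LCA_SELF_EDGE`) — the label rather than any word,
   an explicit reading of an ambiguous rule, and deliberately cheap: the
   ensemble learns how unreliable this rule is and discounts it.
4. **Inheritance.** Entities of the same class connected through
   coordination-type edges share relations: if (M, A, r) was extracted and
   B coordinates with A, (M, B, r) is added (`INHERIT`), transitively
   along the coordination component.

Both the preposition rule and an LCA rule may fire for one pair; both
triplets are emitted and the ensemble arbitrates. DBE triplets keep their
surface relation word; stemming to the shared key happens once, centrally.
The stemmer is the inflectional first step of Porter's algorithm (plurals,
`-ed`, `-ing` with e-restoration): the full Porter cascade would collapse
`cause` to `caus` and `associated` to `associ`, destroying the
correspondence between extracted relation words and their surface forms,
while the first step maps `causes`→`cause`, `associated`→`associate`,
`implicated`→`implicate` as required.

## Ensemble confidence

Every extraction pattern — TPE pattern ids and the five DBE rule ids alike
— is treated as a noisy annotator. From labelled extractions the package
estimates the pattern precision $\Pr(p_i)$ and the relation-word
likelihoods $\Pr(r_j \mid p_i)$ and $\Pr(r_j \mid \lnot p_i)$ with
add-$\alpha$ smoothing ($\alpha = 1$) over the observed relation-word
vocabulary plus one unseen slot; the estimator is ours, since only the
probability model itself is given. The posterior
$$\Pr(p_i \mid r_j) = \frac{\Pr(r_j \mid p_i)\Pr(p_i)}
{\Pr(r_j \mid p_i)\Pr(p_i) + \Pr(r_j \mid \lnot p_i)\Pr(\lnot p_i)}$$
scores each contributing pattern, and a triplet's confidence is the maximum
posterior over its patterns. TPE and DBE streams are unioned by
(sentence, microbe, disease, stemmed relation) with merged provenance, and
triplets below the confidence threshold (default 0.5, where the reference
evaluation peaks) are dropped. Correctness for fitting is exact tuple
match against gold; no partial credit. Extraction quality is reported as
macro-averaged precision/recall/F over the relation-word classes present
in the gold standard.

## Association table and disease network

Triplets aggregate into per-(microbe, disease) counts with their
relation-word bags. Two filters apply in a fixed order: generic disease
terms are excluded first (default `infection`, an outcome word rather than
a disease), then associations whose count falls strictly below the mean
count of the remaining records are dropped — the threshold is always the
computed mean, never a constant, since any printed value is specific to
one corpus. Disease-disease similarity is the Jaccard index of the
associated microbe sets; pairs sharing fewer than two microbes are
excluded (the "single common bacterium" reading is applied to pairs — the
alternative per-disease reading is exposed as `min_shared`), and the
network keeps edges at similarity $\ge 0.6$, with node size given by each
disease's microbe count.

## The synthetic corpus

`generate_corpus()` emulates the statistical shape of a manually annotated
evaluation corpus — on the order of a thousand sentences, about 60% of
candidate pairs positive — from five relation-asserting construction
families (active verb, adverb-fronted active, passive participle,
appositive-with-commas, copular of-chunk, plus a coordinated-disease
variant) and five non-asserting distractor families, three structural
(coordinated co-mention, screening context, two-clause contrast) and two
that reuse the positive constructions with non-asserting verbs so that the
relation word, not sentence shape, decides the label. Gold constituency
and dependency trees come from hand-written schemas per template, removing
any parser dependency and making gold trees exact. A noise knob (default
0.1 of positive sentences) swaps the relation word for a synonym drawn
from pools wide enough that corrupted words essentially never recur —
genuinely out-of-vocabulary for a detector trained on other folds. The
generator is byte-deterministic under its seed.

What the corpus does *not* emulate: paraphrase diversity, parser errors,
abbreviations and anaphora, multi-sentence context, and class imbalance
beyond the configured fraction. Green tests on this corpus certify the
machinery — segmentation, feature flow, optimization, rule logic, ensemble
arithmetic — not performance on real abstracts.

## Study sizes and numerical choices

The packaged experiments use 1000 sentences (~1100 candidate pairs),
tenfold cross-validation split at sentence level, and 5 training epochs
with minibatch 16 for the cross-validated runs — on the separable
synthetic corpus the loss plateaus within two epochs, so longer schedules
only add runtime; the 30-epoch default remains for real data. Weight
initialization is uniform $[-0.08, 0.08]$ with forget-gate biases at 1.
Softmax computations subtract the row maximum. Empty segments (entity at a
sentence edge) encode as the zero vector through their bi-LSTM. All
randomness — generator, fold assignment, initialization, dropout,
shuffling — flows from explicit seeds, and training is reproducible to the
bit on one platform.

## Known limitations

Dictionary NER cannot find unlexiconed surface forms or resolve
abbreviations. The TPE library contains the two published patterns only;
coverage on real text requires the user's pattern file. The
`LCA_SELF_EDGE` rule emits edge labels, which are never correct relation
words — by design it exists to be down-weighted by the ensemble rather
than to contribute. The detector's word vectors are hash-seeded random
unless a word2vec file is supplied, so semantic generalization across
synonyms is limited to what the trainable POS/dependency/position channels
carry. Enhanced dependency graphs with multiple heads are out of scope;
the reader accepts basic trees with subtyped labels.
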