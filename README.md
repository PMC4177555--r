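# ssapcluster

Semi-supervised affinity propagation clustering for full-text document
corpora, with the evaluation metrics and the directed journal
relationship-network analysis that accompany it.

## The problem

Full scientific texts carry far more signal than abstracts, but a corpus of
a few hundred full texts spans tens of thousands of unique terms. In the
classical vector space model every document becomes a huge, almost-empty
vector, and Euclidean methods such as k-means both slow down and lose
accuracy. This package is for text-mining practitioners who want to cluster
such corpora without ever materializing the global vocabulary:

* each document is stored as sparse term tuples ⟨term, count, normalized
  frequency⟩;
* every pairwise similarity is the **cosine coefficient computed in the
  sub-space of the two documents' own terms** — an exact shortcut, since
  terms outside the pair contribute nothing to the dot product:

  $$S(i,j) = \frac{\sum_{k \in d_i \cap d_j} n_i^k n_j^k}{\lVert n_i \rVert_2 \lVert n_j \rVert_2};$$

* **affinity propagation** (Frey & Dueck's responsibility/availability
  message passing) selects exemplars on that similarity matrix, with the
  diagonal preference set to φ × mean off-diagonal similarity;
* a small set of labeled **seed documents** turns the method
  semi-supervised: after message passing, clusters sharing a seed label are
  merged, which repairs the over-segmentation a large preference (φ = 3)
  deliberately produces.

Companion tools: global F-measure and entropy on class-by-cluster
contingency tables, a vector-space k-means baseline, a synthetic
topic-corpus generator, and construction of a directed journal relationship
network (edge A→B when journal B contributes ≥ 2 articles to the cluster
dominated by A) with its small-world statistics.

## Worked example

```r
library(ssapcluster)

# 10 planted topics, 15 documents each, 20% shared background vocabulary
spec <- synthetic_corpus_spec(docs_per_topic = 15, rng_seed = 42)
x <- generate_corpus(spec)
truth <- attr(x, "truth")

# unsupervised affinity propagation at the semi-supervised preference
S <- set_preferences(build_similarity_matrix(x), phi = 3)
ap <- run_ap(S)
length(ap$clusters)                      # 12 clusters — slightly fragmented
f_measure(build_contingency(truth, ap))  # 0.965

# four labeled seeds per topic guide the cluster merge
seeds <- construct_seed_set(x, per_class = 4, rng_seed = 42)
res <- run_ssap(x, seeds, phi = 3)
res
#> <clustering_result> 150 documents in 11 clusters (converged, 111 iterations)

tab <- build_contingency(truth, res, exclude_seeds = TRUE)
f_measure(tab)       # 0.978  (seeds excluded; 110 unlabeled documents)
cluster_entropy(tab) # 0.000  (every cluster is pure)
```

The fragments produced at φ = 3 are pure, so merging them by seed label
raises the F-measure from 0.965 to 0.978 while entropy stays at 0.

The network side runs from any class-by-cluster contingency CSV; the
packaged matrix of 400 articles from 10 BioMed Central journals is the
bundled example:

```r
net <- build_relationship_network(biomed_journal_matrix())
net
#> <relationship_network> 10 nodes, 27 directed edges (threshold 2, degree_consistent)
s <- network_stats(net)
s$clustering_coefficient        # 0.36 (2 dp)
s$characteristic_path_length    # 1.89 (2 dp)
s$diameter                      # 5
homologous_counts(biomed_journal_matrix())$total  # 169 homologous texts
```

A thin command-line wrapper (`inst/scripts/ssap_tool.R`) exposes
`simulate`, `cluster`, `evaluate`, `network` and `fixture-network`
subcommands over the same functions; every clustering run writes a manifest
(settings, seeds, input checksums) sufficient to reproduce it bit for bit.

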