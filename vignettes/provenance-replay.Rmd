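---
title: "Replaying analyses from recorded provenance"
author: "provreplay authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replaying analyses from recorded provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provreplay)
```

## The problem

Bioinformatics platforms that capture *retrospective provenance* — the
record of what actually ran, with which parameters, on which inputs, in
which software environment — make every result self-documenting. Each
result archive carries, alongside its data payload, the complete action
record of the step that produced it and of every ancestor step, back to the
original data imports. `provreplay` consumes such archives and turns that
decentralized record back into usable research documentation: executable
replay scripts, a collated bibliography, and a one-command
"reproducibility supplement".

The workflow is: **validate** (MD5 checksum manifests alert when a result
was altered after creation), **parse** (each archive's nested YAML
provenance tree becomes typed records), **graph** (records across one or
more archives union into a directed acyclic graph of results), and
**generate** (the DAG is ordered and rendered into shell and API dialect
scripts, plus citations).

## The archive format

A result archive is a zip with exactly one top-level directory named by the
result's version-4 UUID:

```
<uuid>/
  VERSION              three-line dialect: format tag, archive version,
                       framework version
  metadata.yaml        uuid, semantic type, data format
  checksums.md5        md5sum-compatible manifest (archive version >= 2)
  data/...             opaque payload (never interpreted by this package)
  provenance/
    VERSION, metadata.yaml, citations.bib
    action/action.yaml             the terminal action record
    artifacts/<ancestor-uuid>/     one subtree per ancestor, same layout
```

Design choices worth knowing:

* **Identity is the UUID, not a content hash.** Whole-file digests are too
  slow to serve as identifiers for large data; MD5 manifests are used only
  as an *integrity alert* over the (small) archive members, never as a
  security boundary or identity key.
* **The manifest never lists itself**, entries are sorted by path with the
  digest/two-space/path line form, so standard command-line utilities can
  verify an unpacked archive.
* **Archive version 1 predates manifests.** Validation reports
  `predates-checksums` for such archives — a warning, not a failure — so
  older results still parse and replay.
* **Action records** (`action/action.yaml`) store the execution UUID,
  runtime start/end as ISO-8601 instants with offset, the action type
  (import / method / visualizer / pipeline), inputs and parameters as
  lists of single-key maps (order survives YAML round-trips), the output
  name, the environment (platform, language, framework and plugin
  versions), and citation keys. Parameters are restricted to scalars and
  flat lists of scalars; nested structures are rejected so code generation
  stays faithful. Unknown top-level keys pass through untouched for
  forward compatibility.
* **Import records** carry no inputs and instead fingerprint the imported
  files (filename + MD5), so replayed analyses can state unambiguously
  which external data the user must supply.

## Graph semantics

Results are nodes, keyed by UUID; each recorded input induces a
producer-to-consumer edge. Actions *annotate* their output nodes rather
than being nodes themselves — an execution with several outputs is
recovered by grouping nodes on the shared execution UUID, which is also how
the replay emits one statement per action. Acyclicity is checked at
construction.

Unioning archives merges nodes by UUID. Results are immutable, so two
full-provenance records for one UUID must agree field-for-field; a
disagreement is a hard conflict error. An input UUID with no provenance
subtree (data predating capture, or a partial archive) becomes a retained
*no-provenance* node rather than an error, and surfaces in replay output as
an explicit user-action-needed comment.

Topological order alone is not unique, so replay output would not be
stable across runs. Ties are therefore broken by ascending (start time,
result UUID), nodes without provenance first. Combined with a
pinned-timestamp mode for the header, the full pipeline is byte-identical
across repeated runs and across permutations of input order.

## Code generation

`planReplay()` emits one statement per execution group in that
deterministic order; variables are named from recorded output names
(sanitized, collision-suffixed, one namespace shared by all dialects), so
definitions always precede uses. The renderers then make dialect-specific
choices:

* **Shell dialect**: `--i-`/`--p-`/`--o-` flags with kebab-case names,
  `.qza` filenames (`.qzv` for visualizer outputs); booleans render as
  `--p-name` / `--p-no-name`; null parameters have no shell literal, so
  they are omitted with a comment naming the framework default.
* **API dialect**: one call per action with keyword arguments; nulls
  render as explicit `None`; the same variable names as the shell script.
* **Metadata parameters are never replayed verbatim.** Replayed analyses
  typically target new sample metadata, so a parameter named `metadata`
  (or ending `-metadata`/`_metadata` — the archive schema carries no
  per-parameter type tags, so the name is the convention) renders as a
  placeholder filename plus a TODO instruction. Recorded values for all
  other parameters — defaults and nulls included — appear exactly once in
  the rendered statement.
* Headers carry the tool version, generation timestamp (or a fixed token
  in pinned mode), every source result UUID exactly once, and numbered
  usage instructions.

Citations are resolved per node against that node's own bibliography,
collected in topological order of first appearance, and deduplicated with
DOI taking precedence over key: DOIs are the only identity that survives
across independently written archives, while keys are namespaced per
result and collide meaninglessly. Key collisions among survivors get
letter suffixes. Deduplication is idempotent and never drops a DOI.

## The synthetic-analysis generator

Real archives from a production platform are not required anywhere:
`simulateAnalysis()` writes fully valid archives with known ground truth.
It emulates a small amplicon-style workflow — imports with fingerprinted
FASTQ manifests feeding actions drawn from a vocabulary of realistic
plugin/action templates (demultiplexing, denoising with multi-output
statistics, taxonomy classification, filtering, core diversity metrics,
barplot visualizations) — with monotone timestamps, per-execution
environment records, and namespaced citations carrying synthetic DOIs
under the reserved `10.5555/` test prefix.

Defaults describe a typical small study: one import feeding five actions,
a quarter of actions multi-output, a quarter of eligible actions taking a
sample-metadata parameter, archive-format version 2. Each action's first
input is the previous execution's first (non-visualization) output, so the
final result's ancestry spans the whole analysis; additional inputs branch
randomly to earlier results. Identical specs generate byte-identical
archives (the zip writer pins member timestamps), which is what makes the
determinism tests exact rather than approximate.

What the generator does *not* emulate: scientifically meaningful payload
data (payloads are opaque stand-in text), pipeline alias indirection
(pipeline records parse like methods; alias resolution is out of scope),
and the full zoo of historical real-world archive layouts (exactly two
format versions are modeled: with and without checksum manifests). Passing
tests therefore demonstrate correctness of parsing, graph reconstruction,
validation, and generation over this format family — not compatibility
with any specific external platform's archives.

## Numerical and procedural choices

* Problem sizes: the test suite exercises 25 seeded analyses of 3–40
  executions for round-trip fidelity, exhaustive single-byte tampering
  over every member of 5 archives, 100 random analyses for replay
  well-formedness, and one 450-execution analysis as the large-scale
  scenario (archiving its principal terminal; visualization dead ends
  outside one terminal's ancestry are legitimately absent from that
  result's provenance, exactly as with real single-result archives).
* Tampering the checksum manifest itself cannot be reported *as* the
  manifest path — the manifest is excluded from its own entries — so a
  corrupted manifest surfaces as a digest mismatch on the listed path or
  as an `unparseable` status. Either way the archive never validates
  `valid`.
* Degenerate inputs: empty byte streams hash to the standard MD5 of the
  empty message; an empty manifest is a valid (empty) manifest; a DAG of
  one import is a valid single-node graph; rendering zero citations
  produces a comment-only document that round-trips to zero entries.
* The CLI validates in `warn` mode by default — provenance validation is
  an alert mechanism, not a gate — and `--validate strict` turns failures
  into exit status 2 with no outputs written.

## Limitations

MD5 is an integrity alert, not tamper-proofing; a determined adversary can
forge it. Replay scripts are generated, not executed: the package
guarantees well-formedness (grammar-checked in the test suite) and
faithfulness to the record, not that the target platform version is
installed or that the analysis re-runs successfully on new data. Recorded
sample metadata is deliberately not reconstructed.
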