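---
title: "Enumerating lines of therapy: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating lines of therapy: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotengine)
```

## The model

A **line of therapy (LoT)** is a serial chronological number assigned to
each systemic anti-cancer therapy (SACT) a patient receives; it denotes a
discrete attempt to treat the cancer. `lotengine` operates on the
*therapy segment* — one row of a standardized minimum dataset, a
contiguous period of one therapeutic approach — and reconstructs lines as
runs of consecutive segments. Three ideas carry the whole model:

1. **Qualification.** Only SACT earns a line: the segment must carry a
   systemic modality (coded `5A`, or `5B` for experimental SACT) and at
   least one agent that is a real anti-cancer exposure — not
   supportive/symptomatic care, not a blinded placebo, and given at a
   dose/duration the clinician considers clinically relevant. Surgery
   (`5C`), radiotherapy (`5D`) and other local-energy modalities (`5E`)
   are recorded, audited, and never numbered: their impact on subsequent
   systemic options is unclear, and counting them would conflate local
   and systemic disease control. A pre-planned multimodal sequence
   (neoadjuvant chemotherapy → surgery → radiotherapy → endocrine
   therapy) is one segment and one SACT.

2. **Transitions.** Given the open line, the next qualifying segment is
   classified by a cascade applied strictly in order, first match wins:
   pre-planned continuation (one SACT by definition) — documented
   progression since the line opened (G1, new line) — same-class
   substitution after toxicity (G2, continue) — agents added without
   progression (G3, new line) — agents dropped, none added (G4,
   continue) — identical agent set (G5, continue). The cascade order is
   load-bearing: progression dominates substitution, so G2 can never fire
   once a new cPD is documented, and any addition that fails the G2
   conditions falls through to G3 rather than silently continuing.

3. **Dichotomization.** Each line belongs to the curative track (CLoT)
   or the palliative track (PLoT), decided once, at the line's opening
   segment, with recorded treatment intent taking precedence over the
   clinical setting — curative-intent therapy of a metastatic but
   chemocurable tumour (the classic example is seminoma with lung
   metastases) still increments CLoT. Labels are cumulative:
   `N (CLoT + PLoT)` with `N = CLoT + PLoT` enforced as an invariant, so
   "first-line metastatic" ambiguity disappears — the label says how many
   attempts preceded, and of what kind.

The key temporal construct is the **date of most recent clinical
progression (cPD)** carried on every segment. A progression is *new* for
the open line only when that date falls strictly after the line's opening
segment started; a cPD date preceding the opening is the progression that
motivated the current line and must not be counted twice. This one
comparison is what lets a toxicity substitution (which drags the old cPD
date along) share its line while the next post-progression therapy opens
a new one.

## What is configurable, and why

The framework deliberately leaves several scenarios to consensus;
`lotengine` makes each an explicit `lot_config()` field with a documented
default rather than a hard-coded guess:

* `same_class_source` (default `"agent_class"`): "same class" for G2 is
  equality of the caller-supplied free-text class, case-insensitive and
  trimmed, falling back to the coarse SACT subcategory (`i`–`v`) with a
  warning when a class is missing. The fine field must take priority:
  taxane→taxane has to pass, while subcategory-only matching would
  wrongly equate, say, capecitabine→eribulin (both cytotoxic `i`).
* `g2_stop_reasons` (default `{8C}`): G2 is worded for toxicity.
  Substitution after patient/clinician choice or for financial reasons is
  an open question, so by default it opens a new line and warns; sites
  that decide otherwise widen the set.
* `gap_resumption_continues` (default `TRUE`): an unplanned resumption of
  the identical regimen after a drug holiday, with no intervening
  progression, is still the same discrete attempt to treat; with an
  intervening cPD it is G1 regardless. Setting `FALSE` opens a new line
  instead.
* `unknown_intent_policy` (`"by_setting"`): when intent was never
  recorded, early setting defaults to the curative track and
  locally-advanced/metastatic to the palliative track, with a warning —
  the least surprising reading of intent-versus-setting coupling, applied
  only as a fallback.

Two further choices are fixed rather than configurable. A continuing
segment never changes its line's track, even if its own intent differs
(a warning is emitted): a line has exactly one curative/palliative
attribution, set at opening, or the cumulative arithmetic would break.
And counters accumulate over the whole journey — early, locally advanced
and metastatic — because restricting lines to the advanced setting is
exactly the inconsistency the cumulative format exists to remove. The
enumerator also imposes no ordering between tracks: a curative-track line
may follow palliative-track lines (oligometastatic disease rendered
resectable), since nothing in the framework prohibits it.

## Dataset, dates and degenerate inputs

The reader ingests CSV/TSV with the canonical ten columns plus a
structured `Agents` column (`name|class|category|flags`, semicolon
separated), an optional `Primary ID` and an optional
`Preplanned with previous` flag. Agent detail must be structured because
the prose Comments column is not deterministic input; Comments are
carried, round-tripped, and provably ignored (a test scrambles them and
asserts identical output). Dates are day-resolution, written
`YYYY MMM DD` with English month abbreviations resolved against R's
locale-independent `month.abb`; ISO-8601 is accepted as a second dialect.

Validation separates blocking defects (stop before start, a cPD date
after the segment it precedes, backwards-moving cPD dates, a systemic
segment without agents, duplicate serials) from warnings that real-world
records legitimately produce (missing intent, a segment stopped for
progression with no later cPD documented, an intent flip inside a line).
Enumeration refuses to run only on the former. Ties on equal start dates
are broken by serial number ascending; ongoing segments (no stop date)
are assigned like any other and leave their line open; an empty history
enumerates to an empty, warning-free result.

A cPD date that post-dates its segment's start is treated as an error,
not reinterpreted: the column is defined as the progression that preceded
the therapy, and silently accepting late-recorded progressions would make
G1 fire one segment too late.

## The synthetic generator as oracle

`generate_history()` exists to test every rule path without real
records. It composes a journey line by line — curative lines first
(early/curative), then palliative ones, each opened by a progression
documented after the previous line opened — and optionally appends,
per line, a toxicity substitution (must continue via G2), an agent drop
(G4), a dose change (G5) and an interleaved surgery/radiotherapy segment
(must be skipped). Because the generator decides which segments open
lines, it can emit the expected assignment for every segment *without
consulting the enumerator*; agreement between the two is therefore a
genuine two-route check, exercised over 1000 seeds in the test suite
(about a minute of runtime; histories run to a few dozen segments). Dates
sit on a synthetic monthly grid from 2000 Jan 01 — only event order
matters to the rules — and all draws come from a private stream seeded by
the scenario, restoring the caller's RNG state.

What the generator does *not* emulate bounds what green tests show: no
epidemiological realism (survival times, drug popularity, missingness
patterns), no contradictory or late-recorded dates, no free-text agent
lists needing curation, and intent/setting always coded except where the
scenario omits intent by design. Passing the property suite demonstrates
the rule algebra is implemented faithfully on well-formed histories; it
does not validate extraction from messy source records, which is
upstream of this package's contract.

## Numerical and formatting choices

There is no floating point anywhere: dates compare as integers, labels
are exact strings matching `^[0-9]+ \([0-9]+ \+ [0-9]+\)$`, and
`format_label()` refuses to print any triple violating `N = CLoT + PLoT`.
Round-tripping is a fixed point by construction — the writer serializes
codes as `"2C Metastatic"`, dates in the dialect's canonical form, absent
cPD as `"NA"` and absent stop dates as empty — and the reader is lenient
in exactly the ways the writer is canonical, so read∘write∘read is
byte-stable.

## Known limitations

* Agent identity is the normalized drug name; there is no drug
  dictionary, so synonyms (e.g. brand vs generic names) are distinct
  agents unless the caller harmonizes them.
* `preplanned_with_previous` is caller-asserted; the engine never infers
  pre-planning from timing, by design.
* Haematological malignancies are out of scope: the framework's
  vocabulary (operable/inoperable, early/metastatic) is specific to solid
  tumours.
* The engine assigns no lines to surgery/radiotherapy/local-energy
  modalities; if future consensus counts some of these, qualification —
  not the cascade — is the extension point.
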