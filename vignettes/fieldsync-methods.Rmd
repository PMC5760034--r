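---
title: "fieldsync: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fieldsync: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldsync)
```

## The problem

Long-term individual-based field studies — here modelled on a banded mongoose
(*Mungos mungo*) population of roughly 250 marked animals living in 10–12
social groups of 10–30 — generate several concurrent data streams: daily
group visits with presence/absence, weekly morning and evening weighings,
reproductive and care status records (pregnancy, mate-guarding, escorting,
babysitting), timed focal follows, group-level events and GPS tracks. Several
fieldworkers collect these simultaneously on separate devices, with no
network at the field site. The resulting engineering problem has three parts:

1. a storage model that tolerates continuous protocol change without database
   migrations and never destroys data;
2. a reconciliation protocol that lets many offline replicas converge on one
   hub copy with predictable conflict behaviour;
3. a domain layer that enforces at entry time the eligibility rules the field
   protocols define, because most transcription error is prevented, not
   cleaned up.

fieldsync implements all three, plus typed CSV export and a seeded synthetic
generator so the whole stack is testable with no field data.

## The entity-attribute-value store

Every datum is one *entry*: an (entity, attribute, value) triple with a
version number, a dirty flag and an origin. Entities are typed objects
(pack, individual, session, weight, …) identified by `<device-tag>-<counter>`
ids, which makes cross-device id collisions impossible by construction rather
than by coordination. Values are tagged scalars (`text`, `integer`, `real`,
`boolean`, `timestamp`, `null`); the tag travels with the payload through
persistence, sync and export, so types are never re-inferred. Structured
payloads (e.g. the set of individuals within 2 m in a scan) are stored as
JSON text under a single attribute.

Two rules shape everything else:

* **Data are never deleted.** Deletion sets a reserved boolean attribute
  (`_deleted`) as an ordinary dirty entry. Deleted entities stay fully
  readable, are excluded from default queries, and the deletion itself
  synchronises like any edit.
* **Versions are hub-assigned.** A local edit marks an entry dirty but never
  touches its version; the version changes only when the hub acknowledges a
  push or when a newer entry arrives in a pull. The first receipt of an entry
  at the hub is version 1, and each subsequent accepted update increments it
  by exactly one, so a hub version is literally the count of accepted writes.

The live store is an in-memory environment; `store_save()`/`open_store()`
persist it as a single SQLite file (journal mode DELETE, so the one file can
be copied, snapshotted or emailed as-is), and a plain-JSON dump supports
diffing in tests. Because the entry is the unit of everything, new attribute
names — even whole new observation categories — require no structural change
anywhere: replicas running newer protocol versions can push fields the hub
has never seen.

## The sync protocol

Synchronisation is two-way and always replica-initiated:

1. **Push.** The replica sends each dirty entry individually, in modification
   order, and waits for a per-entry acknowledgement carrying the hub-assigned
   version before clearing that entry's dirty flag. A transport failure
   mid-push therefore leaves acked entries clean and unacked entries dirty,
   and a retry resumes exactly where it stopped; the converged state is
   identical to an uninterrupted sync.
2. **Pull.** The replica sends its complete version list; the hub returns
   every entry strictly newer than reported, treating entries absent from the
   report as version 0 (that is how entities created on other devices
   propagate). Equal versions are never returned, which gives idempotence: an
   immediate repeat sync transfers zero entries in both phases.

Conflicts are resolved by **hub arrival order**: the hub overwrites its value
unconditionally on every accepted push, so when two replicas edit the same
entry the last one to sync wins. Device clocks are never consulted for any
ordering decision — field devices drift, and a wrong clock must never be able
to resurrect stale data. Timestamps are stored (ISO 8601 with explicit UTC
offset) but only as observational data. Because an entry is a single small
datum rather than a whole record, genuine conflicts are rare in practice.

The protocol layer is transport-agnostic: `serve_hub()` exposes the four
requests (push entry, diff, snapshot, ping) as an endpoint object that
serializes requests in arrival order, and `local_transport()` is the
in-process client used throughout the tests, with failure injection for
crash-safety checks. Binding the same endpoint to an HTTP server is an
implementation point deliberately left outside this package's scope: a
single-threaded R process cannot usefully serve and consume its own socket,
and every protocol property worth testing is a property of the endpoint
semantics, not of the socket. The CLI instead addresses the hub as a database
file on shared storage.

One behaviour the original system leaves unspecified: a replica pushing the
same entry twice in one session. Here each push is a fresh accepted update
(the version bumps twice). This is documented rather than hidden because it
affects version arithmetic in audits.

## The observation protocols

All protocol state lives in the store, so everything below survives a sync
round-trip and is editable after the fact (edits re-run the gating and mark
entries dirty again). Clocks are injectable: every lifecycle function takes
an explicit time, so tests and the generator drive simulated clocks.

Key parameters (all in `protocol_config()`):

| parameter | default | meaning |
|---|---|---|
| `month_days` | 30.4375 | days per month for age arithmetic (mean Gregorian month) |
| `adult_female_months` | 10 | strict threshold for pregnancy eligibility |
| `pup_age_days` | 90 | maximum age of a "dependent pup" |
| `gps_interval_s` | 180 | seconds between GPS fixes during a visit |
| `focal_seconds` | 1200 | active length of a focal follow |
| `score_levels` | 1–4 | ordinal scale for strength/accuracy scores |
| `weight_bounds` | off | optional entry-time feasibility bounds (grams) |

Design choices where the field protocol itself is silent:

* **Age threshold is strict.** "Older than 10 months" excludes exactly
  10.0 months; the month length is configurable because "month" is not a
  defined unit.
* **GPS fixes anchor at the visit start** and repeat every 180 s of session
  clock strictly before the end time, so a 20-minute visit has 7 fixes and a
  zero-duration visit still has its start fix.
* **Presence gates downstream records.** Weights, mate-guards and escorts
  must reference individuals marked present; a pregnancy additionally
  requires an eligible adult female. The single exception is babysitting
  inferred from temporary absence, whose subject is by definition absent.
  A screen that does not apply is skipped explicitly (`skip_screen()`), so
  "not applicable" is distinguishable from "not recorded".
* **The nearest neighbour is auto-included in the within-2 m set** rather
  than rejected when omitted: the containment is definitionally true and
  field entry should not pay for it.
* **A completed focal follow always has 20 scan slots.** Completion requires
  1200 s of active (unpaused) time; minutes without a recorded scan are
  filled with explicit empty scans flagged `missed = TRUE`. A gap is a
  datum — silently shifting later minutes would corrupt the time base. A
  follow paused for five minutes completes at 25 minutes of wall clock with
  its 20 scans.
* **Pup definition.** The den period covers roughly the first 30 days and
  escorting happens once pups travel with the group; lacking a stated upper
  bound, "dependent pup" defaults to under 90 days, configurable.
* **Entry-time weight screening is off by default** (`weight_bounds = NULL`);
  the feasibility screen also exists as the post-hoc `screen_weights()`,
  which is how residual typo rates are estimated on synced records.

## The synthetic generator

The generator exists to exercise the software at the study system's scale,
not to model mongoose biology. `population_spec()` defaults encode that
scale: 11 packs of 10–30 individuals (~220 expected, within the usual ~250),
even sex ratio, ages uniform over 0–8 years. Where the protocols fix a rate
(weekly weighing, 3-minute GPS cadence, 20-minute follows) the generator uses
it; where no distribution is stated, defaults are invented and labelled as
such: presence probability 0.95 per individual per visit, visit duration
20–40 min, adult weights normal with mean 1500 g and sd 250 g truncated at
300 g and scaled down for juveniles, interactions Poisson with mean 3 per
follow. Typo injection substitutes one digit (1234 → 1334); the canonical
fixture of 720 weight records with 18 corrupted mirrors the scale of the
original field test of error rates, and its corruptions substitute the
leading digit upward so that the feasibility screen's recall is 1 by
construction — the fixture validates the screening plumbing, not the
detectability of arbitrary typos (a typo that stays inside feasible bounds
is undetectable by a bounds check, exactly as in the field).

Every generator draws from a labelled substream of the master seed
(`substream_seed()`), so outputs are deterministic given the seed and adding
a generator never perturbs another's stream. The generator writes through
the public protocol API only — never raw store writes — so generated data
satisfy the same gating as field-entered data; the gating tests additionally
fuzz with deliberately ineligible records and then scan the whole store for
violations.

What the generator does *not* emulate, and tests therefore cannot show:
demographic dynamics (births, deaths, dispersal between packs), observer
effects, GPS noise, oestrus timing, or realistic edit-conflict rates.
Convergence and gating results transfer to real data because they are
properties of the algorithms, not of the data distribution; the invented
distributions only determine how hard the tests exercise them.

## Problem sizes and numerical choices

The shipped checks run three replicas with 200 seeded random edits each and
an interleaved sync schedule ending in two quiescence rounds; 50 crash-retry
trials at random push prefixes; several hundred fuzzed diff cases; a
thousand simulated visits for the gating scan; and the 720-record export
fixture. These sizes make every property check exact (set identity, zero
violations) rather than statistical, while keeping the default suite around
a minute. All value comparisons after round-trips are exact (`identical`),
including doubles: payload text uses 17 significant digits and the CSV
writer emits shortest round-trip representations.

## Known limitations

* No authentication or encryption: like the original field deployment, a
  trusted local network (or shared disk) is assumed.
* One hub; replicas never sync peer-to-peer. Any fully synced replica is,
  however, a complete backup.
* No retrospective life-history inference (e.g. declaring death after three
  days' absence) — deliberately out of scope, as are analyses of the
  exported data.
* The same entry pushed twice in one session bumps the hub version twice
  (see above).
* `query_entities()` predicates are conjunctive equality/function filters;
  anything richer belongs in dplyr on the exported tibbles.
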