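---
title: "Context-based positive and negative rule mining for microbial prospection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-based positive and negative rule mining for microbial prospection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpnarm)
library(dplyr)
```

## The problem

Soils above hydrocarbon reservoirs develop measurable microbial anomalies:
elevated counts of methane-, ethane-, propane- and butane-oxidizing
bacteria, sulphate reducers, paraffin dirt, shifts in pH/Eh, and
precipitation of iron minerals such as pyrite and maghemite. A microbial
prospection survey records these indicators per site and sampling
campaign, together with a Boolean outcome (was an energy reserve found),
and asks which indicator combinations predict the outcome.

Association rule mining is the natural tool: a rule $X \Rightarrow Y$
with support $\mathrm{supp}(X \cup Y)$ (how often $X$ and $Y$ co-occur)
and confidence $\mathrm{supp}(X \cup Y)/\mathrm{supp}(X)$ (conditional
accuracy). Two complications motivate this package's design:

1. **Negative rules matter.** The *absence* of an indicator can be as
   informative as its presence, so the miner also emits
   $X \Rightarrow \neg Y$, $\neg X \Rightarrow Y$ and
   $\neg X \Rightarrow \neg Y$.
2. **Context can lie.** An environmental *context variable* —
   temperature, water salinity, humidity, rainfall, fossil pollution —
   outside its normal range can falsely generate or suppress a rule.
   Maghemite precipitates under high salinity whether or not hydrocarbons
   are seeping; a drought can suppress indicator organisms at a site that
   is in fact a prospect.

## The mining model

### Frequent itemsets and the rule gates

Raw indicator values are discretized either to presence items (value
$> 0$ becomes `<id> == 1`; `binarize_presence()`) or to ordinal bins from
a user-supplied range table (`ordinalize_database()`; bins are half-open
$[b_i, b_{i+1})$, a value at a breakpoint goes to the upper bin). Missing
and zero values produce *no* item rather than a level-0 item, so absence
is never counted as positive evidence — this matters because negative
rules give absence its own, explicit representation.

Per time interval, classical Apriori (`frequent_itemsets()`) enumerates
itemsets with support at least `ms`, levelwise with join-prune candidate
generation. Sub-threshold singletons are retained (flagged) because
negative-rule generation needs marginal supports.

A positive rule $A \Rightarrow B$ (disjoint, nonempty $A$, $B$) is kept
when (`is_fipi()`):

$$\mathrm{supp}(A \cup B) \ge ms, \quad
  \mathrm{interest}(A,B) = |\mathrm{supp}(A \cup B) -
  \mathrm{supp}(A)\,\mathrm{supp}(B)| \ge mi, \quad
  \mathrm{conf}(A \Rightarrow B) \ge mc.$$

A negated form is kept when additionally both plain sides are frequent
(`is_iipi()`); its signed joint support follows from inclusion-exclusion
(`negative_supports()`), its confidence divides by the signed antecedent
support (e.g. $1 - \mathrm{supp}(A)$ for a $\neg A$ antecedent), and the
interest magnitude is shared by all four signed configurations of one
pair (it is bounded by $0.25$ and vanishes under independence). Negative
rules are generated from pairs of individually frequent itemsets; we do
not negate single terms inside a multi-item side.

`mine_rules()` enumerates all ordered pairs of disjoint frequent itemsets
within size caps (antecedent up to 4 items, matching the four-term
antecedents typical of field rules; consequent up to 7, the serialization
limit) with one cross-product over the transaction incidence matrix.

### Context adjustment

Each context variable carries an expert-chosen normal range
$[\mathrm{CIV}, \mathrm{CFV}]$ (inclusive at both bounds). For an
interval whose (median) context value $v$ violates a bound, the surplus
percentage is $d = (\mathrm{CIV} - v) \cdot 100 / v$ below range or
$d = (v - \mathrm{CFV}) \cdot 100 / v$ above, and every rule's support is
re-scaled (`adjusted_support()`):

| polarity | below CIV | above CFV |
|---|---|---|
| positive | $s \leftarrow s(1 + d/100)$ | $s \leftarrow s(1 - d/100)$ |
| negative | $s \leftarrow s(1 - d/100)$ | $s \leftarrow s(1 + d/100)$ |

The direction encodes the failure mode being corrected: above-range
context inflates apparent positive co-occurrence (so the support is
discounted), below-range context suppresses it (so it is restored).
Adjusted supports are clamped to $[0, 1]$; with a 100 % deficit the
shrinking cases reach exactly 0. When several variables are abnormal the
factors compose sequentially; because each case is multiplicative the
composition is a product and therefore exactly order-independent, except
that a single negative step pins the running support at 0. Confidence and
interest are recomputed from the adjusted support (confidence capped at
1); only `ms` is re-tested after adjustment — `mc` and `mi` act at mine
time on the observed values.

A support pushed *upward* can cross `ms` only if the rule was mined at
all. `mine_database()` therefore mines each abnormal-context interval
down to an exploration floor $ms / \max(1, F_\mathrm{pos},
F_\mathrm{neg})$, where $F$ is the composed factor per polarity; rules in
the band $[\mathrm{floor}, ms)$ are provisional and survive only if the
adjustment lifts them past `ms`. This admits exactly the rules the
adjustment can promote without re-mining the interval, which is also why
record-level context outliers (that leave the interval median within
range) do not trigger any adjustment.

### Temporal consolidation

Rules are identified by their canonical key — sorted antecedent tokens,
polarity, sorted consequent (`rule_key()`); support and interval are not
part of the identity. `intersect_rulesets()` keeps the keys extracted at
`k` or more *distinct* intervals (a duplicate within one interval counts
once) and reports the mean support/confidence over the contributing
intervals alongside the per-interval values, since no canonical
aggregate exists for this step. The bundled worked example shows the
procedure:

```{r demo}
demo <- consolidation_demo()
fin <- intersect_rulesets(demo$rulesets, k = 3)
tidy(fin) |> select(key, interval_count, support)
```

Ten rules over four intervals collapse to one: the recurring four-term
rule is kept, the five-term variant reaches only 2 intervals, and the
flipped-predicate variant extracted under 450 mm rainfall (normal range
100–300 mm) is a one-off. `near_miss_report()` surfaces such one-term
variants as a diagnostic but never merges them — predicate-level
reconciliation is not defined by the procedure and we do not invent one.

## The synthetic generator

`generate_database()` emulates the statistical structure the miner
assumes, not geochemical reality. Defaults are the study conditions: 28
sites by 178 intervals (4984 records), 29 indicators, 20 of 28 sites
with energy, 7 abnormal-context records per variable, rainfall normal
range 100–300 mm (the worked example's range); temperature 15–40 °C,
salinity 1–35 g/L, humidity 30–80 %, fossil pollution 1–10 ppm are
chosen once as field-plausible. Background presence is independent
Bernoulli at marginal 0.15 per indicator cell. Planted rules are placed
by exact counts per interval — `round(s n)` prospect-site records get the
antecedent, `round(s n (1-c)/c)` non-prospect records get it without the
outcome — so empirical support and confidence track their targets with
only rounding and background noise (at 28 records per interval the
granularity is $1/28 \approx 0.036$). Within-range context is uniform on
$[\mathrm{CIV}, \mathrm{CFV}]$; anomalies are uniform on the adjacent
band of one range width (or placed exactly, via
`inject_context_anomaly()`, e.g. 450 for a $+0.75$-width excursion above
300).

What passing tests on this generator do **not** show about real surveys:
indicators here are conditionally independent given the planted signal,
context variables are independent of the indicators except through
injected anomalies, and sites are exchangeable. Real microbial data have
correlated indicators (the oxidizer counts co-vary), context that
physically drives the indicators, and site-level heterogeneity. The
generator validates the *mining machinery*, not the geology.

`rescue_scenario()` wires the motivating failure end to end: one planted
rule, strong at intervals 1–2, suppressed into the adjustment band at
intervals 3–4 where rainfall is driven to 50 mm (a 100 % deficit, so the
adjustment exactly doubles the observed support), weak at interval 5.
Context-off consolidation at $k = 3$ loses the rule (2 intervals);
context-on restores intervals 3–4 and keeps it (4 intervals). Note the
direction: rescuing a suppressed *positive* rule requires a
*below*-range anomaly, because above-range context can only discount
positive supports.

## Numerical choices and conventions

- Supports are stored as fractions; `ms` accepts a fraction ($\le 1$) or
  an absolute count ($> 1$, divided by the interval's record count), so
  worked examples quoted in counts reproduce directly.
- Threshold comparisons use a $10^{-9}$ absolute tolerance: supports are
  ratios of small integers and the tolerance absorbs only float noise.
- Itemset and rule keys sort tokens with radix (byte) order, so output
  is locale-independent and identical across runs; rule files order
  antecedent groups by best support, then best confidence, then key.
- Interval indices are assigned per site by sorting distinct evaluation
  dates (ties on a date are integrity errors); the construction is
  deterministic and independent of row order in the CSV.
- Degenerate inputs: empty transaction lists, zero antecedent support
  and non-positive context values are classed errors
  (`cbpnarm_error_*`), not silent results; `apply_context()` skips (with
  a warning) a variable whose value makes the adjustment undefined.
- Test and example problem sizes: oracle-equivalence checks run
  exhaustive enumeration on databases of up to 8 items and 20
  transactions, where the powerset is fully checkable; recovery runs use
  the full 28 × 178 benchmark shape over 10 seeds.

## Open design points resolved here

- The context attributes of the survey schema are declared Boolean, but
  the adjustment needs numeric values; we store numeric context columns
  and treat "abnormal" as the derived flag.
- Whether adjustment may promote a previously infrequent rule: we
  re-test candidate rules mined within the adjustment band (above), and
  do not re-mine the interval under adjusted counts.
- Confidence of $\neg A$ antecedents divides by $1 - \mathrm{supp}(A)$.
- Aggregate support of a consolidated rule is the mean over contributing
  intervals, with per-interval values retained.
- CIV/CFV are expert inputs by design; the package deliberately does not
  learn them from data.

## Limitations

Mining is exhaustive over frequent-itemset pairs, which is appropriate
for desk-scale surveys (thousands of records, tens of items per
interval) but not for dense databases with hundreds of frequent items.
The interval-median context rule means a single anomalous record cannot
trigger adjustment; scenarios where context varies meaningfully within
an interval need finer interval construction. And the adjustment itself
is the standard heuristic re-scaling — it corrects support magnitudes,
not flipped predicate directions, and its factors are linear in the
percentage surplus with hard clamping at 0 and 1.
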