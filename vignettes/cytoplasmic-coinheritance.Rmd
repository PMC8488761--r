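---
title: "Modelling co-inherited symbionts and positively selected mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-inherited symbionts and positively selected mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytosweep)
```

## The question the package answers

Facultative heritable symbionts — *Wolbachia* and its relatives in
arthropods, and comparable microbes across invertebrates, plants and
microeukaryotes — pass from mother to offspring along the same cytoplasmic
route as mitochondria. The two elements are therefore co-inherited: a
selective sweep on one drags the other along. The classical view treats the
mitochondrial genome as a neutral passenger of symbiont sweeps. cytosweep
models the converse situation: a *positively selected* mitochondrial variant
(a "novel mitotype" with selective benefit $t$, by default up to 2%) arises
in a population that already carries a facultative symbiont, and we ask
whether the mitotype invades, what happens to symbiont prevalence and
diversity, and how the answer depends on which cytoplasmic background — a
symbiont-infected or an uninfected host — the mutation first appears in.

Because the symbiont is facultative, the population mixes four **cytotypes**,
tracked as frequencies summing to one:

| symbol | mitotype | symbiont |
|--------|----------|----------|
| $p$    | resident | infected |
| $q$    | resident | uninfected |
| $r$    | novel    | infected |
| $s$    | novel    | uninfected |

All dynamics are deterministic, discrete-generation, mean-field recursions on
$(p, q, r, s)$ — infinite population, no drift, no seed, no randomness.

## The three symbiont classes

**Fixed benefit** (`fixed_benefit_params(B, mu, t)`). Offspring of infected
mothers receive a net fitness factor $1 + B$ (benefit minus carriage costs,
folded into one number), balanced against segregational loss: a fraction
$\mu$ of an infected mother's offspring fail to inherit the symbiont and
join the uninfected class of the same mitotype. One generation is

$$p' = \frac{p(1-\mu)(1+B)}{W},\quad
  q' = \frac{p(1+B)\mu + q}{W},\quad
  r' = \frac{r(1+B)(1-\mu)(1+t)}{W},\quad
  s' = \frac{(r(1+B)\mu + s)(1+t)}{W},$$

with $W = p(1+B) + q + (r(1+B)+s)(1+t)$. In the resident subsystem
($r=s=0$) the symbiont settles at $p^* = 1 - (1+B)\mu/B$, which exists and
is stable iff $\mu < B/(1+B)$ — the persistence criterion.

**Negatively frequency-dependent benefit** (`freq_dep_params(b, c, mu, t)`).
The template for a defensive symbiont: protection is worth most when rare
(natural-enemy pressure declines as protection spreads), so the benefit is
$B_T = b(1 - (p_T + r_T))$, evaluated at the *current* generation's overall
symbiont frequency, against a fixed carriage cost $c$. The recursions are
those above with $1 + B$ replaced by $1 + B_T - c$. The resident equilibrium
is the radical form
$p^* = \big(b(2-\mu) - c - \sqrt{c^2 + b\mu(4 + b\mu - 2c)}\big)/2b$,
stable iff $\mu < (b-c)/(1+b-c)$. Uniquely in this class an
infected/uninfected polymorphism survives even at $\mu = 0$
(at $p^* = (b-c)/b$).

**Cytoplasmic incompatibility** (`ci_params(h, mu, t)`). Offspring of
uninfected mothers die at rate $h$ when the father is infected, so under
random mating (male cytotype frequencies equal to female ones, equal sex
ratio) uninfected mothers' offspring survive at the factor
$(p+r)(1-h) + q + s$. The advantage is positively frequency-dependent,
which makes the system bistable: besides extinction ($E_1$) there is an
unstable separatrix $E_2$ and an upper stable equilibrium $E_3$,

$$E_{2,3} = \frac{h \mp \sqrt{h^2 - 4h\mu(1-\mu)}}{2h(1-\mu)},$$

real iff $\mu < (1-\sqrt{1-h})/2$. Feasibility is not persistence here: the
symbiont must also *start* above $E_2$. One modelling fork deserves note:
as the recursions are written, offspring of infected mothers that *lose*
the symbiont (the $p\mu$ and $r\mu$ terms) do experience the
incompatibility survival factor — they are uninfected zygotes like any
others. Conventions differ across the CI literature; we implement the
equations as stated and make no claim about the biology of segregant
protection. We likewise implement the printed female-frequency recursions
directly rather than deriving them from a full mating table; the two agree
under the stated symmetry assumptions.

```{r equilibria}
cyto_equilibria(ci_params(h = 0.25, mu = 0.05))
```

## Invasion analysis

`resident_equilibrium()` places the system at the pre-invasion balance
($E_3$ for CI), `introduce_mutant()` moves a frequency $\varepsilon$
(default $10^{-5}$) into the novel-mitotype compartment of the chosen
origin, and `mutant_growth_factor()` linearizes the rare $(r, s)$ subsystem
there. The linearization is triangular — nothing flows from the uninfected
mutant class back into the infected one — so its eigenvalues are the two
compartments' own multiplication rates, and two facts follow immediately:

* **Infected origin.** The dominant rate is exactly $1 + t$ in all three
  models: an advantageous mitotype arising in an infected host always
  invades, fixes, and (whenever $\mu > 0$) re-enters the uninfected class
  via segregational loss, leaving equilibrium symbiont prevalence unchanged
  while erasing both mitochondrial and symbiont diversity.
* **Uninfected origin.** The growth factor is the uninfected compartment's
  rate, e.g. $(1+t)/\big((1+B)(1-\mu)\big)$ for the fixed-benefit model,
  giving the invasion boundary $t = B(1-\mu) - \mu$
  (`threshold_t_fixed_benefit()`). Note that a *neutral* marker in the
  uninfected class declines — that class is subsidized by segregational
  loss, not self-sustaining — so the factor is below one at $t = 0$.

For the frequency-dependent model the uninfected-origin boundary is
$t = (1-\mu)(1 + b(1-p^*) - c) - 1$ (`threshold_t_freq_dep_invasion()`,
verified in the tests against a root-find on the growth factor), and above
$t = (1+b-c)(1-\mu) - 1$ (`threshold_t_freq_dep_displacement()`) the mutant
beats the symbiont even when the symbiont is rare and its benefit maximal.
Between the two curves lies this model's signature outcome: the mutant
invades but cannot displace, and the population settles into **partitioned
coexistence** — ancestral mitotype held by infected hosts and their
segregants, novel mitotype polymorphic in the uninfected pool, at reduced
symbiont prevalence.

`classify_invasion()` runs the full recursion and labels the final state:

```{r classify}
glance(classify_invasion(freq_dep_params(b = 0.1, c = 0.05, mu = 0.02, t = 0.02),
                         origin = "uninfected"))
```

## Numerical choices

* **Conservation policy.** After every step, components within $-10^{-15}$
  of zero are clamped to zero; the state is renormalized only when its sum
  drifts from one by more than $10^{-12}$, and a deviation beyond $10^{-9}$
  is an error. Silent renormalization would mask formula bugs.
* **Fixed points.** `find_fixed_point()` iterates to a max-norm step below
  `tol` ($10^{-12}$ by default) with a budget of $10^6$ generations —
  generous, because convergence is geometric except near bifurcations
  (the CI tangency $\mu \to (1-\sqrt{1-h})/2$ is the slow case).
  Closed-form equilibria within $10^{-9}$ of 0 or 1 are snapped to the
  boundary. Hot loops run in compiled code; the pure-R step operators are
  the readable reference, and a test pins the two routes together at
  $10^{-15}$.
* **Classification cutoffs.** Extinction is $10^{-9}$ and fixation
  $1 - 10^{-9}$ while the recursion runs. At a *converged* state the cutoff
  widens to the introduction scale $\varepsilon$: a lineage decaying
  geometrically towards a boundary stalls the iteration marginally above
  $10^{-9}$, whereas genuine interior equilibria are macroscopic, so the
  widened cutoff cannot misclassify them.
* **Ties.** A growth factor within $10^{-6}$ of one is reported
  `indeterminate` rather than forced into a class; invasion boundaries are
  measure-zero sets and honesty beats a coin flip there.
* **Stability flags.** Where a closed-form criterion exists it is used
  verbatim; the CI pair $E_2$/$E_3$ carries its known separatrix/stable
  roles. Full four-dimensional stability is established numerically by the
  invasion machinery, not symbolically.

## Problem sizes

The shipped analyses are desk-scale by design: outcome grids of $50 \times
50$ cells for the fixed-benefit and frequency-dependent models and
$26 \times 26$ per CI strength (each CI cell needs a long bistable run);
the CI invasion ceiling scans $h$ in steps of 0.005 up to 0.2 with a
$26 \times 26$ $(\mu, t)$ grid per value, mutating cells decided by full
recursion. The persistence-criterion cross-check bisects $\mu$ to a
$10^{-4}$ bracket with $5 \times 10^5$-generation probes. All of it runs in
a few minutes on one core.

One operationalization deserves emphasis: the CI invasion ceiling
(`ci_invasion_ceiling()`) answers "largest $h$ with at least one invading
$(\mu, t \le 0.02)$ cell" *on its grid*. The uninfected-origin growth
factor rises towards one as $\mu$ approaches the feasibility bound where
$E_3$ collapses onto $E_2$, so clustering the $\mu$ grid against that
boundary, or refining it, admits invasion at somewhat larger $h$. The
default places 26 loss rates evenly strictly inside the open admissible
interval — biologically distinguishable values rather than a limit study —
and the reported ceiling is tied to that choice.

## What the models do and do not capture

These are deterministic mean-field recursions. They show which invasions
are *possible* and where they lead, not how often they happen: a real novel
mitotype starts as one copy and faces stochastic loss regardless of its
advantage, low-prevalence symbionts face fadeout the model cannot see, and
$\varepsilon$ here only sets transient length. Sex ratio is equal, male and
female cytotype frequencies coincide, and co-transmission is perfect — no
paternal leakage of mitochondria, no infectious or horizontal symbiont
transfer, and a single symbiont strain; where those assumptions break, the
coupling that drives every result here is weakened. Within-host dynamics,
multiple infections and eco-evolutionary feedback on the natural enemy
behind the frequency-dependent benefit are likewise out of scope. Passing
tests certify the recursions, their closed forms and their thresholds — not
any of the above.
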