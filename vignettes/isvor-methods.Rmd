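---
title: "Rumor diffusion with variation and silence: models and methods"
author: "isvor package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rumor diffusion with variation and silence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isvor)
```

# The scientific problem

Online rumors rarely stay fixed: as a claim circulates it is distorted,
exaggerated and re-fabricated into *variant* versions, and many people
who hear it neither spread nor refute it but fall *silent* for a while
before either forgetting it or rejoining the conversation.  The ISVOR
model extends the classic three-compartment rumor model with exactly
these two phenomena, splitting the population into ignorants (I),
spreaders of the original rumor (S), carriers of a mutated version (V),
silent "oysters" (O) and recovered/immune individuals (R).  The
package's purpose is to let a modeller ask intervention questions — is
it more effective to *immunize* variant carriers (raise $\mu_2$) or to
*silence* them (raise $\xi_2$)? — on realistic network substrates, with
a deterministic mean-field analysis alongside a stochastic agent-based
simulator.

# Parameters

All twelve transition probabilities live in an `isvor_params` object;
each is a dimensionless per-step (ABM) or per-unit-time (mean-field)
probability/rate in $[0,1]$.

| symbol | field | default | meaning |
|---|---|---|---|
| $\alpha$ | `alpha` | 0.5 | I $\to$ S on contact with a spreader |
| $\epsilon$ | `epsilon` | 0 | I $\to$ R on contact with a spreader (verbal rule; opt-in) |
| $\lambda$ | `lambda` | 0.2 | I $\to$ V on contact with a variation |
| $\mu_1$ | `mu1` | 0.5 | S $\to$ R per informed contact |
| $\mu_2$ | `mu2` | 0.5 | V $\to$ R per informed contact |
| $\gamma$ | `gamma` | 0.3 | S $\to$ V spontaneously |
| $\eta$ | `eta` | 0.5 | S $\to$ V on contact with a variation |
| $\xi_1$ | `xi1` | 0.5 | S $\to$ O (falls silent) |
| $\xi_2$ | `xi2` | 0.5 | V $\to$ O (falls silent) |
| $\theta$ | `theta` | 0.25 | O $\to$ R (forgets) |
| $\beta_1$ | `beta1` | 0.1 | O $\to$ S (resuscitates as spreader) |
| $\beta_2$ | `beta2` | 0.1 | O $\to$ V (resuscitates as variation) |
| $k$ | `k` | 10 | mean contact degree (mean-field only) |

The defaults are the reference study conditions used throughout the
experiments: networks of $N = 2000$ individuals with mean degree 10
(Watts–Strogatz with rewiring probability 0.4, or Barabási–Albert with
$m = 5$), one initial spreader, 50 replicates per ensemble.

Two glosses in the verbal role definitions are ambiguous and are
resolved in favour of the equation system: $\gamma$ is implemented as a
spontaneous S $\to$ V mutation (the $+\gamma S$ term in $dV/dt$), not as
S $\to$ O, and $\lambda$ by default converts ignorants on contact with
variations (the $k\lambda IV$ term); the alternative "fraction of new
infections mutates" reading is available as
`lambda_mode = "fraction_of_infections"`.  The rate $\epsilon$ appears
in the verbal rules but not in the equations, so it defaults to zero and
enters only when `include_epsilon = TRUE`.

# The mean-field system and its two variants

`isvor_rhs()` implements the five-equation mass-action system shown in
the README.  Its components do **not** sum to zero: the oyster's
forgetting outflow is written as contact-driven,
$-\theta O (S+V+O+R)$, while the matching recovery inflow is the
spontaneous $+\theta O$.  On the unit simplex the discrepancy is exactly
$\theta O I$ — density leaks out of the system while ignorants and
oysters coexist.  Because fidelity and well-posedness pull in different
directions, both variants ship:

* `variant = "as_printed"` — the system exactly as published, leak
  included (the leak identity $\sum_i \dot x_i = \theta O I$ is asserted
  to $10^{-12}$ in the test suite);
* `variant = "conserving"` — identical except forgetting is spontaneous
  ($-\theta O$), so $\sum_i \dot x_i = 0$ holds identically.  This is
  the default for experiments, and it also matches the verbal
  definition of forgetting as an internal decision of the oyster.

The two variants coincide whenever $\theta = 0$, and both leave the
whole rumor-free family $E_1 = (I_1, 0, 0, 0, 1-I_1)$ exactly invariant.

## Integration

The default integrator is adaptive Runge–Kutta (`deSolve::ode`, method
`ode45`) with relative/absolute tolerances $10^{-8}/10^{-10}$ and a step
ceiling of 0.5; the ceiling prevents the dense-output interpolant from
undershooting zero near the absorbing plateau (without it, components
dip to about $-10^{-8}$).  A fixed-step forward-Euler mode
(`method = "euler_dt"`, default $dt = 1$) mirrors the discrete-time
probability semantics of the simulator.  Conserving trajectories are
checked to stay within $10^{-6}$ of the simplex and a warning is raised
otherwise.

## Equilibria and stability

Setting the right-hand side to zero, candidates with active compartments
are self-contradictory: $I = 0$ with positive $S, V, O$ forces
$\mu_1 k S + \mu_2 k V + \theta O = 0$, and an all-positive state forces
$\alpha k I S + \lambda k I V = 0$.  `isvor_equilibria()` reports the
$E_1$ family as the only feasible one (with a degeneracy flag when every
rate is zero, in which case all states are equilibria).

Linearization around $E_1$ reduces to a $3 \times 3$ Jacobian in
$(S, V, O)$ with diagonal $U_1, U_2, B$ and off-diagonal coupling
$\gamma, \beta_1, \beta_2, \xi_1, \xi_2$.  Two conventions exist for the
(3,3) entry: the published matrix uses $B = \theta I_1 -
(\beta_1+\beta_2)$, while direct linearization of the contact-driven
forgetting term gives $\theta I_1 - \theta - (\beta_1+\beta_2)$.
`isvor_jacobian()` computes either (`entry33`), the report carries both
values and flags sign disagreements, and the published convention is
used for the verdict.

`stability_report()` evaluates the Hurwitz determinants of the factored
characteristic polynomial $(\chi-U_1)(\chi-U_2)(\chi-B)$ **and** the
numerical eigenvalues of the full matrix, and the eigenvalues are
authoritative.  The two can disagree: the factored polynomial's roots
are just the diagonal entries, so the Hurwitz conditions
$\Delta_1, \Delta_2, \Delta_3 > 0$ are equivalent to
$U_1, U_2, B < 0$ and ignore the Metzler (non-negative off-diagonal)
coupling, which can push the true spectral bound across zero.  Random
parameter draws show roughly one discordant draw in eight; the test
suite and the acceptance script measure and report this rate rather than
assuming concordance.  For the same reason only *local linear* stability
is certified — no global/Lyapunov claim is made.

`stability_interval()` therefore determines the stable range of $I_1$
by a 1001-point eigenvalue scan with bisection refinement of the
boundaries (tolerance $10^{-10}$), and reports the closed-form
sign-change candidates for comparison: $U_1 = 0$ at
$(\mu_1 k + \xi_1 + \gamma)/(\mu_1 k + \alpha k)$ (0.58 at the
defaults), $U_2 = 0$ at $(\mu_2 k + \xi_2)/(\mu_2 k + \lambda k)$, and
$B = 0$ at $(\beta_1+\beta_2)/\theta$ (0.8 at the defaults).  The
published closed-form bound prints $\xi_1 + \gamma$ in the $U_2$
numerator; solving $U_2 = 0$ gives $\xi_2$, so the package reports the
$U_2$-derived bound and lists the published expression as a comparison
value.  Note that at the default rates the eigenvalue-stable range lies
*below* the $U_1$ crossing — the off-diagonal coupling matters — which
is precisely why the numerical verdict, not the sign algebra, decides.

# The agent-based simulator

`abm_run()` advances a synchronous discrete-time chain on an undirected
graph: every node's next role is a function of the time-$t$
configuration only, candidate transitions are evaluated sequentially
with short-circuit (first success wins), contact-driven trials precede
spontaneous ones, and competing contact types are visited in randomized
order.  Role counts are conserved exactly; R has no outflow and I no
inflow; runs stop at the absorbing state ($S = V = O = 0$) or `t_max`.
All randomness flows through R's RNG, so `(graph, config, seed)`
determines a run bit-for-bit, and ensembles derive per-replicate
(graph, run) seed pairs from one root seed by a fixed splitting rule.

## Contact semantics

How a per-contact probability such as $\mu_2$ is applied each step is
the one genuinely open design choice in a discrete-time network version
of a mass-action model, and it changes the phenomenology, so the
package implements three conventions (`contact_mode`):

* **`maki_thompson`** (default).  Ignorants feel one independent
  infection trial per spreading neighbour (receiver-side pressure, so
  well-connected nodes are reached sooner and the outbreak matches the
  mass-action growth), while every *active* node keys its own
  contact-driven transitions on **one uniformly sampled discussion
  partner** per step: a spreader stifles ($\mu_1$) only if its sampled
  partner is informed, converts ($\eta$) only if that partner is a
  variation, and so on.  This is the classic Maki–Thompson convention
  from the rumor-modelling literature.  It keeps stifling proportional
  to the informed *fraction* of a node's neighbourhood rather than
  saturating with degree, which preserves the model's distinctive
  behaviour at the reference rates: the variation and oyster
  compartments reach substantial densities, and the two
  variation-targeted interventions ($\mu_2$ vs $\xi_2$) remain
  distinguishable — a contact-conditioned immunization is weakened
  while ignorants still dominate neighbourhoods, whereas silencing acts
  unconditionally.
* **`per_step`** — one Bernoulli trial per contact *class*, performed
  when at least one neighbour of that class is present; the stated
  probabilities act as per-step conditional probabilities.
* **`per_contact`** — one independent trial per neighbour of the class,
  the literal discrete counterpart of the degree-multiplied mass-action
  terms.  With mean degree 10 and rates of 0.1–0.5 these trials
  saturate (per-step probabilities approach 1), which collapses the
  variation compartment to a few per mille and makes $\mu_2/\xi_2$
  interventions nearly inert; the mode is retained because it is the
  exact discrete analogue of the printed equations and is the one used
  in the mean-field consistency test below.

Purely one-contact schemes (each node, including ignorants, samples a
single partner) were also examined and are *not* offered: at the
reference rates they are subcritical — the rumor dies before any
outbreak — so they cannot correspond to the reported dynamics.

## The exact oracle

Because the update is synchronous, nodes transition independently given
the configuration, so the one-step distribution over assignments is a
product of per-node distributions, each available in closed form (with
the randomized interleaving of competing contact classes enumerated
combinatorially).  `exact_one_step()` computes this product exactly for
graphs of up to 8 nodes, entirely in R and independently of the C++
simulation path; the test suite checks $10^5$-trial Monte-Carlo
frequencies against it within four binomial standard errors on four
fixtures (isolated spreader, isolated oyster, an I–S edge, an I–S–V
path).

## Consistency with the mean field

On a complete graph, with contact probabilities scaled by
$h\,k/(n-1)$ and spontaneous ones by $h$ (one ABM step $=$ ODE time
$h = 0.02$), the per-contact-mode ensemble mean tracks the conserving
mean-field solution within 0.05 in sup-norm ($n = 500$, 10 replicates)
— the engineering-level sanity link between the two halves of the
package.

# Baselines

Three comparators run on the same substrates with the same update
machinery: network SIR (infection $\alpha$ per spreader contact,
spontaneous recovery $\mu_1$ — the mapping used in the reference
comparison), SEIR (an exposed stage with spontaneous incubation 0.5),
and Twin-SIR (a competing "dispeller" type that converts both
susceptibles and rumor spreaders on contact, seeded after a 5-step
delay).  The SEIR and Twin-SIR rate values are standard reconstructions
— only the SIR mapping is prescribed — and only qualitative orderings
are asserted about them.

# Experiments

`run_sweep()` varies one rate over a grid with **common random
numbers**: replicate $r$ uses the identical graph and initial spreader
for every grid value, so paired per-replicate differences isolate the
parameter effect; a fresh network is generated per replicate (pin one
with `pin_graph`).  The headline statistic is the diffuser peak
$\max_t\{S(t)+V(t)\}$, summarised as the *mean of per-replicate peaks*
(the peak of the ensemble-mean curve is also available but is biased
low by peak-time jitter across replicates; ties in a peak search break
to the earliest time).  `intervention_comparison()` reports the
low-to-high drop in that statistic for $\mu_2$ and $\xi_2$ with
bootstrap confidence intervals; `reproduce_figure()` packages the five
scripted experiments (role densities, baseline comparison, $\mu_2$,
$\xi_2$ and $\alpha$ sweeps) at full scale ($N = 2000$, 50 replicates)
or a reduced scale ($N = 300$, 10 replicates) with CSV outputs and a
JSON manifest.  "Threshold" values quoted for late-time densities are
operationalized as the value at the absorbing time (or `t_max`).

The test suite runs the analytic checks at full precision and the
stochastic checks at the reference scale ($N = 2000$, 50 replicates, a
few hundred runs in total — a couple of minutes on one CPU thanks to
the compiled stepping kernels); unit tests use smaller graphs
($N = 100$–500).

# What the synthetic conditions do and do not show

The generators emulate the *structural* ingredients the model cares
about — small-world clustering with shortcuts (WS) and heavy-tailed
degree heterogeneity (BA) — under homogeneous rates, a single seeded
spreader, and synchronous time steps.  They do not emulate degree-rate
correlations, directed or weighted ties, community structure, external
broadcast events, or time-varying behaviour, so passing tests certify
the implementation and the model's internal logic, not fidelity to any
empirical cascade.  No fitting to real social-media data is provided or
implied.

# Known limitations

* The published equation system leaks density at rate $\theta O I$; the
  conserving variant is a minimal repair, not a canonical one.
* Stability certificates are local and linear; the Hurwitz conditions
  derived from the factored polynomial disagree with the true spectrum
  on a measurable fraction of parameter space, and the two closed-form
  interval bounds printed for the stable range are mutually
  inconsistent with the sign cases they come from — all quantities are
  reported side by side instead of reconciled.
* Discrete-time synchronous updating with probabilities as large as 0.5
  is far from the continuous-time limit; agreement with the ODE is only
  demonstrated under the rescaled mixing-limit conditions above.
* Under the default Maki–Thompson semantics a *less* infectious rumor
  yields a higher variation peak (slow outbreaks leave variants in
  mostly-ignorant neighbourhoods where contact-conditioned
  immunization rarely fires); orderings of the variation peak across
  infection rates are therefore semantics-dependent, and
  `contact_mode` exists precisely to make that dependence explicit.
* The Twin-SIR and SEIR parameterizations are reconstructions; their
  curves are compared only qualitatively.
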