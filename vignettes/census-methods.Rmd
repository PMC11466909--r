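---
title: "An exact bifurcation census of planar quadratic mass-action networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exact bifurcation census of planar quadratic mass-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnbif)
```

## The model

A chemical reaction network on two species X, Y with mass-action kinetics is
a finite set of reactions, each an ordered pair of complexes (nonnegative
integer combinations of the species). With stoichiometric matrix $\Gamma$
(columns = product minus reactant coefficients) and reactant-exponent matrix
$A = \Gamma_\ell^{\mathsf T}$, the concentration dynamics are

$$\dot x \;=\; \Gamma\,(\kappa \circ x^{A}), \qquad \kappa \in \mathbb R^m_+ .$$

The census universe is: two species, four reactions, all reactant complexes
bimolecular (molecularity $\le 2$, so the right-hand side is quadratic), all
product complexes trimolecular (molecularity $\le 3$), and stoichiometric
rank two. This is the smallest planar setting in which folds, Hopf
bifurcations and their codimension-two degeneracies can occur at positive
equilibria: by the one-equilibrium bound for networks with fewer than $n+2$
distinct reactant complexes, rank-two multistationarity needs at least four
reactions, and bimolecular products already rule Hopf bifurcations out.

## Dynamical equivalence: what gets counted

Two networks are counted once if they generate the same *family* of ODE
systems, possibly after swapping X and Y. Since a reaction with reactant $c$
and vector $\gamma$ contributes $\kappa\,\gamma\,x^{c}$ with free
$\kappa>0$, the family is determined, per reactant complex, by the set of
strictly positive combinations of its reaction vectors — the relative
interior of their conic hull. The package's canonical key records, per
reactant, the primitive ray (single reaction), the pair of extreme rays of a
pointed sector, or a line descriptor (opposite rays), and minimises the
serialisation over the species transposition. The chosen class
representative uses the product complex of minimal molecularity on each ray,
ties broken lexicographically, which makes the catalogs byte-reproducible.

## The reduced Jacobian core

For a dynamically nontrivial rank-two network the positive kernel
$\ker\Gamma\cap\mathbb R^4_+$ is a two-dimensional cone with exactly two
extreme rays $r_1, r_2$ (computed exactly by active-set enumeration). On the
cross-section $h(\alpha)=\alpha r_1+(1-\alpha)r_2$, $\alpha\in(0,1)$, every
positive equilibrium has Jacobian $J=\lambda\,M(\alpha)\,\mathrm{diag}(1/x)$
with $M(\alpha)=\Gamma\,\mathrm{diag}(h(\alpha))\,A$. All feasibility
decisions are sign conditions on the affine entries of $M$ and the quadratic
$\det M$:

* a positive **nondegenerate** equilibrium exists iff
  $\operatorname{rank}[A\,|\,\mathbf 1]=3$ and $\det M\not\equiv 0$;
* a **zero eigenvalue** occurs iff $\det M(\alpha)=0$ for some admissible
  $\alpha$ (roots isolated by Sturm sequences; the root is held as an exact
  algebraic number);
* the **companion eigenvalue** at a det-root is the trace
  $M_{11}/x_1+M_{22}/x_2$ with $x$ free, so each sign of a diagonal entry at
  the root is an achievable sign of the second eigenvalue;
* **purely imaginary** pairs need $\det M>0$ together with either
  $M_{11}M_{22}<0$ (then $x_2/x_1 = -M_{22}/M_{11}$ zeroes the trace) or
  $M_{11}=M_{22}=0$ (the trace vanishes for *every* positive $x$ — this
  second, easily missed branch contributes 39 of the 198 Hopf classes and is
  handled by a dedicated pipeline in which $x_2$ itself is the free
  variable);
* a **double zero** needs $\det M=0$ and $M_{11}M_{22}<0$ at the same point.

Everything is decided in exact rational arithmetic (arbitrary-precision
rationals in the compiled kernel); floating point appears only in test
oracles and diagnostic output. This matters because many decisions sit on
razor edges — e.g. the three networks whose zero eigenvalue always has
algebraic multiplicity two, or Hopf regions a fraction of a percent wide.

## Focal values

On a Hopf piece the equilibrium, rates and Jacobian are rational functions
of the free parameter; the frequency is $\omega=\sqrt{\det J}$. After the
linear change to rotation form and a time rescale, the field's quadratic
coefficients live in the quadratic extension
$\mathbb Q(\alpha)[\omega]/(\omega^2-\det J(\alpha))$. The focal values are
computed by the Poincaré–Lyapunov recursion: a formal Lyapunov function
$V=(x^2+y^2)/2+V_3+\dots+V_8$ is built degree by degree, the homological
(rotation) operator is inverted over the rationals, and the obstructions
$\eta_2,\eta_3,\eta_4$ at degrees 4, 6, 8 are the focal values $L_1,L_2,L_3$
up to positive factors. Signs over the whole feasible domain are decided by
isolating the real roots of the norm $u^2-v^2\,\det J$ of
$L_1=u+v\,\omega$ and sampling the gaps at rational points; zeros of $L_1$
are algebraic numbers at which $L_2$ (and if necessary $L_3$) are evaluated
exactly. A network is *supercritical* / *subcritical* if $L_1$ is negative /
positive throughout, *vertical* if $L_1\equiv L_2\equiv L_3\equiv 0$ (for a
quadratic field this certifies a center, so the Hopf point sits inside a
continuum of periodic orbits), *mixed* if $L_1$ changes sign with
$L_2=L_3=0$ on its zero set, and *Bautin* if $L_2\neq 0$ there. The
recursion is only extended past degree 4 when a zero of $L_1$ is actually
found, which keeps the census stage fast.

The sign conventions were cross-checked against an independent
implementation of the classical curvature-coefficient formula (numeric, in
the test helpers) and against the explicitly integrable vertical network,
which is Hamiltonian on its critical surface.

## Bogdanov–Takens normal form

At a double-zero root $\alpha^*$ (rational or quadratic-irrational; the
package works in $\mathbb Q(\sqrt D)$ with $D$ the discriminant of
$\det M$), the Jacobian is nilpotent of index two. In the basis $q_0, q_1$
with $Jq_0=0$, $Jq_1=q_0$ and the dual pair $p_1, p_0$, the quadratic part
yields $a_{20}=\langle p_0,B(q_0,q_0)\rangle$,
$b_{20}=\langle p_1,B(q_0,q_0)\rangle$,
$b_{11}=\langle p_1,B(q_0,q_1)\rangle$; only the sign
$\sigma=\operatorname{sign}((a_{20}+b_{11})\,b_{20})$ and zero/nonzero
distinctions are reported, which are invariant under the admissible basis
scalings. $\sigma=-1$ is the supercritical case (stable cycle, attracting
homoclinic loop), $\sigma=+1$ subcritical; $a_{20}+b_{11}=0$ is the
*vertical* Bogdanov–Takens case, where the package instead verifies the
constant Dulac divergence and the Hamiltonian structure on the critical
parameter surface symbolically. Transversality certificates (for folds,
Hopf crossings and BT unfoldings) are computed as exact ranks of the
derivative of $(f,\operatorname{tr}J,\det J)$ with respect to state and
rate constants at the algebraic witness.

## Design choices that were genuinely open

* **Cross-section normalisation.** Extreme rays are primitive integer
  vectors and $h$ is their affine combination. Any positive rescaling of
  the rays reparameterises the section monotonically; a property test
  confirms classifications are unchanged.
* **Representative selection.** Minimal-molecularity products with
  lexicographic tie-breaks. Counts are representative-independent; only the
  catalog listings depend on it.
* **Degenerate-trace Hopf pieces.** The condition "$\det M>0$ and
  $M_{11}M_{22}<0$" is the generic description; the census treats the
  double-vanishing diagonal as a first-class second branch rather than an
  error, since a third of a percent of the space lands on it. Networks with
  *identically* vanishing diagonals (a two-parameter Hopf set) do not occur
  in this universe; the code stops with a diagnostic if one is ever fed in.
* **Zero-eigenvalue stability at the origin.** Decided only when the
  linearisation is uniform in the rates or an invariant axis carries the
  center manifold with a sign-definite leading term; anything else is
  reported as undecided rather than guessed. All thirty bimolecular fold
  networks fall into the decidable cases.
* **"Continuum of equilibria" detection.** A class without nondegenerate
  equilibria has $\det M\equiv 0$; the solvability function
  $h(\alpha)^W$ is then checked for constancy, and the equilibrium curve
  at critical rates is classified from its monomial parameterisation
  $x(\alpha)=(h(\alpha)/\kappa)^G$ — for every such class in this universe
  it is a straight line (through the origin, vertical or horizontal).

## What the generator does and does not emulate

The enumeration module *is* the data generator: the study population is the
complete combinatorial universe described above, so there are no sampling
choices, no noise model and no seeds — reruns are bit-identical. The
synthetic-random-network helper used in the property tests draws uniformly
from the raw (unreduced) space purely to exercise the decision procedures
against numeric scans; it is not part of the census. Conclusions are
statements about this finite universe of idealised mass-action models, not
about any particular biochemical system: real networks have more species,
conservation laws (rank below species count is out of scope here) and
kinetics beyond mass action.

## Problem sizes and runtime

The raw distinct-reactant space has $15\cdot 9^4 = 98{,}415$ networks
(trimolecular products) and reduces to 5897 classes; the structurally
filtered Hopf base enumerates about $45{,}000$ reaction 4-subsets and
reduces to 946 classes. The full census with focal-value and normal-form
classification runs in a few minutes on one CPU; the acceptance script,
which stops at the determinant-level decisions, in about a minute. All
per-class decisions are cached within a session.

## Known limitations

* Only $n=2$ species and full rank: networks with conservation laws need
  the reduced Jacobian machinery on stoichiometric classes, which is not
  implemented.
* Limit-cycle counting beyond the Bautin double cycle (uniqueness of the
  Hopf cycle, homoclinic bifurcations of the seven fold-and-Hopf networks
  without a double zero) is out of scope.
* The inheritance/enlargement calculus is implemented only as the rank-one
  induced-subnetwork pattern test, not as a general engine.
* Boundary equilibria other than the origin are not analysed.
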