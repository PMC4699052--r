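---
title: "Secure genome analysis with somewhat-homomorphic encryption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure genome analysis with somewhat-homomorphic encryption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoSHE)
```

# The problem

A data owner holds genomic data — case/control genotype tables over SNV
sites, or VCF variant records of individual genomes — and wants an untrusted
server to compute on them without ever seeing plaintext. genoSHE implements
the full toolchain for two such analyses under somewhat-homomorphic
encryption (SHE):

* **Task 1 (GWAS):** per-SNV minor allele frequencies (MAF) and the allelic
  chi-square statistic between a case and a control group;
* **Task 2 (sequence comparison):** the Hamming distance and an approximate
  edit distance between two participants' variant sets.

Two RLWE-based schemes are provided, because they sit at opposite ends of a
practical trade-off: a *leveled modulus-switching scheme* (BGV style) that is
fast on deep circuits, and a *scale-invariant scheme* (YASHE style, an
NTRU-like single-element scheme) that is leaner on shallow, addition-heavy
workloads.

# The rings

Both schemes work in $R_q = \mathbb{Z}_q[x]/(\Phi_m(x))$ with plaintext space
$R_t$, $1 < t < q$. The leveled scheme uses an odd index $m$; the
scale-invariant scheme uses a power of two, $\Phi_m(x) = x^n + 1$ with
$n = m/2$, and a prime $q \equiv 1 \pmod m$. All coefficient arithmetic is
exact: moduli are arbitrary-precision integers (the modulus chain of the
leveled scheme exceeds 64 bits even at demonstration scale), carried by a
sign-magnitude bignum engine in compiled code. Products are reduced modulo
$\Phi_m$ exactly — negacyclic wrap for power-of-two $m$; for odd $m$, a fold
modulo $x^m - 1$ followed by precomputed rows of $x^k \bmod \Phi_m$.
Coefficients are stored in the centered representation $(-q/2,\, q/2]$.

## Batching

When $\Phi_m$ factors modulo $t$ into $\ell$ irreducible polynomials $f_i$ of
common degree $d$ ($\ell d = \varphi(m)$, with $d$ the multiplicative order
of the prime base of $t$ modulo $m$), $R_t \cong \prod_i
\mathbb{Z}_t[x]/(f_i)$ and one ciphertext carries $\ell$ independent
*plaintext slots* on which additions and multiplications act componentwise.
`slotLayout()` builds this structure: equal-degree splitting finds the
factors for prime $t$; for $t = 2^r$ the mod-2 factors are Hensel-lifted.
Only integers are ever stored in slots (constant terms of the factor
residues), which is all the pipelines need. Factor order is not canonical in
theory, so it is fixed here by sorting factors lexicographically on their
coefficient vectors; packing/unpacking is deterministic.

For addition-only workloads the scale-invariant pipeline instead uses
*coefficient packing*: $\lfloor n/s \rfloor$ persons' length-$s$ genotype
vectors laid head-to-tail in one polynomial. Addition acts coefficientwise;
no multiplicative structure is needed or available.

# The schemes

**Leveled scheme.** Keys: sparse ternary secret $s$ of Hamming weight $h$
(default 64), public RLWE pair $(a,\, b = [as + te]_q)$, and an evaluation
key over $R_{P q_{L-2}}$ encrypting $P s^2$. Decryption is
$[c_0 - s c_1]_{q_l} \bmod t$. Multiplication tensors two ciphertexts to a
three-component ciphertext decryptable under $(1, s, s^2)$, then *key
switching* returns to two components: the ciphertext is scaled up by $P$,
$d_2 \cdot \mathrm{evk}$ is added, and the same rescaling primitive used for
modulus switching divides $P$ back out. This modulus-raising gadget is one of
the two standard realizations; the construction here follows the evaluation
key's stated domain $R^2_{P q_{L-2}}$. *Modulus switching* after each product
drops one chain prime and shrinks the noise by that factor (plus a small
additive term in $t(1+h)$). Every multiplication therefore consumes exactly
one level; additions are free. Fresh ciphertexts live at level $L-1$ and are
switched once before their first product, so a depth-$M$ circuit needs
$L = M + 2$ moduli.

Chain primes are chosen $\equiv 1 \pmod t$. This is what makes rescaling
plaintext-neutral: dividing the noise polynomial by $p$ multiplies the
message by $p^{-1} \bmod t$, which is 1 exactly when $p \equiv 1$. ($P$ is
likewise $\equiv 1 \bmod t$, of the form $2^K t + 1$; it needs no primality,
only headroom $P \gtrsim q_{L-2}\, n B t$ so the switching noise is
negligible.) The prime size is derived from worst-case noise bounds: fresh
noise $t(B(2h+1)+1)$, a multiplicative expansion factor $n \cdot 2(1 +
\max_j \sum_k |R_{kj}|)$ computed exactly from the reduction rows of the
chosen ring, and the additive rescaling term; each prime must dominate the
expansion times the stable noise level, plus a small safety margin.

**Scale-invariant scheme.** Keys: $f = [tf' + 1]_q$ with dense ternary $f'$
(resampled, up to 32 attempts, until invertible in $R_q$), public key
$h_{\mathrm{pub}} = [tgf^{-1}]_q$; the symbol $h$ is reserved for the secret
Hamming weight, hence the name $h_{\mathrm{pub}}$. A ciphertext is a single
element $[\lfloor q/t \rfloor [m]_t + e + h_{\mathrm{pub}} s]_q$ and
decryption is $\lfloor (t/q) [f \cdot c]_q \rceil \bmod t$, rounding half
away from zero (the tie is unreachable for odd prime $q$, but the convention
is fixed). Multiplication is scale-invariant: the *integer* product of the
two ciphertexts is scaled by $t/q$ with rounding and then re-linearized by
the word-decomposition evaluation key $\gamma_i = [f\omega^i + e_i +
h_{\mathrm{pub}} s_i]_q$: the inner product of the balanced base-$\omega$
digits of the scaled product with $\gamma$ is the output ciphertext. The
inherent noise $v$ (defined by $f \cdot c = \lfloor q/t\rfloor [m]_t + v$)
is measured exactly in tests; decryption is correct while
$\|v\|_\infty < q/(2t)$ roughly, and the implementation warns at $q/(4t)$.

The modulus size follows the published bound: $\log_2 q \approx 2M \log_2(nt)
+ \log_2(12\sigma \ell_\omega \omega)$ for $M$ levels, iterated twice because
$\ell_\omega = \lfloor \log_\omega q \rfloor + 1$ depends on $q$. The
production word is $\omega = 2^{128}$; demonstration moduli are much smaller
than $2^{256}$, so the examples pass a smaller $\omega$ (e.g. $2^{24}$) to
keep $\ell_\omega \ge 2$ and the key-switch noise below $q$ — with
$\omega \ge q$ the decomposition is vacuous and correctness collapses.

The degree $n$ of the scale-invariant ring is an explicit argument of
`yasheParamsGen()`: its security ceiling on $q$ comes from tables that are
out of scope here, so the package does not pretend to derive $n$ from
$\lambda$ alone.

# Genomic encodings

* Genotypes: AA → 2, AB → 1, BB → 0, i.e. the A-allele count; group
  aggregation is then a plain sum.
* Variant records are merged by exact (chromosome, position) equality into
  the list $L$; a one-sided position gets an absent marker.
* Per site and participant: presence flag $e$, type flag $f$ ($0$ iff
  INS/DEL), a 15-bit string $s$ (two bits per base, A→00 G→01 C→10 T→11,
  then a 1, then zero padding — the trailing 1 keeps e.g. "A" distinct from
  "AA" and every encoding distinct from the absent all-zero string), and a
  length $D$ (reference length for deletions, alternate length otherwise,
  0 if absent) carried as $\mu$ LSB-first bits.

Two conventions are under-determined by the record-level algorithms and were
fixed as follows. An *absent* side keeps $f = 1$: the Hamming circuit
multiplies by $f f'$, and an absent-side $f = 0$ would wrongly cancel the
"one side missing counts 1" case. A *deletion* contributes its reference
length to $D$ but its alternate string to $s$: both files share the
reference genome, so only alternate strings are compared. Records at one
position with different REF strings are accepted but reported loudly: the
circuits compare alternate strings only and take the record-level
algorithms' literal fall-through there.

# Circuits

On $\{0,1\}$ values, XOR is $(x-y)^2$ and AND is $xy$; every circuit
therefore has a *binary* form over $t = 2$ (run under the leveled scheme)
and an *arithmetic* form over a prime $t$ (run under the scale-invariant
scheme, where $x^n + 1 \bmod 2$ collapses to $(x+1)^n$ and batching needs
$t \ne 2$). Both forms are written once against a small evaluator interface,
so identical circuit code runs on plaintext slot vectors, ciphertexts of
either scheme, and a depth-counting evaluator used for static accounting.

* equality $E(s, s') = \bigwedge_{j=1}^{15}(s_j \oplus s'_j \oplus 1)$,
* Hamming term $(E \wedge (e \oplus e' \oplus 1) \oplus 1) \wedge f \wedge f'$,
* comparison $c_j = ((x_j \oplus 1) \wedge y_j) \oplus ((x_j \oplus 1 \oplus
  y_j) \wedge c_{j-1})$ with $c_1 = (x_1 \oplus 1) \wedge y_1$ (the
  arithmetic rendering of $c_1$ is $(1-x_1)y_1$; a printed form without the
  $(1-x_1)$ factor contradicts the binary definition at $x=y=0$ and is
  treated as a typo),
* bitwise max $x_j \oplus (C(x,y) \wedge (x_j \oplus y_j))$ (ties return the
  first argument),
* edit term, per length bit $j$:
  $(E(s,s') \wedge (f \oplus f' \oplus 1) \oplus 1) \wedge \max(D, D')[j]$.

Products are arranged in balanced trees, and the Hamming/edit terms are
folded so the big product is a single tree: binary Hamming multiplies 16
factors (15 equality bits plus the presence term) in depth 4, then one
product with $f f'$ — depth 5, hence $L = 7$; binary edit reaches depth 6,
hence $L = 8$. The arithmetic forms distribute $(1 + X)\cdot m = m + X m$ to
stay at depth 6. Depth is asserted as $\le$ the published budgets because
the published chain lengths do not say whether auxiliary additions'
switches are counted.

Sites are batched across slots (block-partitioned when there are more sites
than slots); each bit position of the encoding is one ciphertext. After
decryption, the per-site Hamming terms are summed, and the bit-sliced edit
terms are recombined as $\sum_j \ell_{i,j} 2^{j-1}$ — the max recombination
happens in the clear, matching the bit-sliced design.

# GWAS statistics

With allele counts $n_A = \sum_i g_i$ per SNV (slot- or coefficient-packed,
then summed homomorphically), the decrypted quantities give
$\mathrm{MAF} = \min(m_j,\, 2N - m_j)/2N$ and, from the pair
$(ct_{\mathrm{case}} + ct_{\mathrm{cont}},\; ct_{\mathrm{case}} -
ct_{\mathrm{cont}})$, the allelic chi-square
$$\chi^2 = \frac{4N\,(n_A - n'_A)^2}{(n_A + n'_A)\,(4N - (n_A + n'_A))},$$
which is the 2×2 contingency-table statistic with margins $R = S = 2N$ —
the package proves this equivalence exhaustively for all tables with
$N \le 10$. Divisions and minima happen after decryption only. Differences
are decoded signed: residues above $t/2$ represent negatives (the boundary
$t/2$ decodes to $+t/2$; it is unreachable once the pipeline's wraparound
validation $4N < t$ holds — the same rule that makes $t = 2^9$ sufficient
for MAF counts and $t = 2^{10}$ for the chi-square sums at $N = 200$).
Monomorphic sites (aggregate sum 0 or $4N$) have an undefined statistic and
yield NaN with a warning rather than a silent 0.

# Parameter calculators

`bgvDepth()`, `bgvLogq()`, `yasheLogqBound()`, `bgvSecurityMinPhi()`,
ciphertext sizes and `planTable()` reproduce the closed-form parameter
arithmetic: per-multiplication switch count $d_{n,t} \approx \log_2(h n
t^4)/36$ (applied with a ceiling when building integer chains), leveled
modulus size $24 + \tfrac32 \log_2 n + (L-2)(11 + \tfrac12 \log_2 n)$, sizes
$2n\log_2 q$ and $n \log_2 q$ bits, and the RLWE degree bound
$\varphi(m) \ge (L(\log_2 m + 23) - 8.5)(\lambda + 110)/7.2$ (the printed
inequality is typographically ambiguous; this grouping is consistent with
the accepted $\lambda = 80$ deployments and is guarded by consistency
checks, not equalities). One display convention deserves a note: at
$n = 8190$ the exact base term is 43.4995 and the per-level increment
17.4998. The package displays the base rounded to nearest (43) and the
increment rounded *up* (18) — a per-level bit budget is the quantity one
must not undershoot when sizing chain primes. No single nearest-integer rule
reproduces both published integers.

# Synthetic data

Deployment-scale cohort data are private, so `genCaseControl()` and
`genVcfPair()` emulate their shape with attached ground truth computed by
the independent record-level oracles:

* genotypes $g \sim \mathrm{Binomial}(2, p_j)$ per person and SNV
  (Hardy–Weinberg), $p_j \sim U(0.05, 0.5)$ by default, defaults 200 + 200
  persons × 311 SNVs; an optional associated SNV shifts the case-group
  frequency by $\delta$;
* variant pairs: positions shared with probability `pShared` (identical
  records with probability `pIdentical`, otherwise independent records over
  a common reference string), SUB/INS/DEL mixed 60/20/20, alternate strings
  of at most 7 bases.

The generator models neither linkage disequilibrium, population structure
nor realistic mutation spectra; passing tests demonstrate *cryptographic and
algorithmic* correctness (encrypted results equal plaintext ground truth
exactly), not statistical realism of the genetics.

# Problem sizes and numerical choices

Demonstration and test runs use deliberately small rings so that exact
bignum arithmetic stays fast: $m = 255$ ($t = 2^9$/$2^{10}$, 16 slots,
$L = 3$) and $n = 64$ for the GWAS pipelines at 20 persons/group × 16 SNVs;
$m = 1023$ ($t = 2$, 60 slots, $L = 7$ or 8) and $n = 128$ ($t = 127$, 64
degree-2 slots, $M = 6$) for the 50-site distance pipelines. These rings
reproduce the deployment structure (slot batching, chain lengths, degree-2
factors for odd prime $t$) at reduced degree; they are *not* 80-bit-secure —
security-sized rings come from `bgvParamsGen(lambda = 80, ...)` and the
published power-of-two degrees. All plaintext-side polynomial arithmetic
stays below $2^{52}$ and is therefore exact in doubles; everything modulo
$q$ is exact bignum. Seeds: every randomized step (sampling, key
generation, synthetic data) draws from R's RNG, so a single `set.seed()`
fixes a whole pipeline; the factor-splitting inside `slotLayout()` uses a
local derived seed and restores the RNG state, and its output is made
deterministic by sorting regardless.

# Limitations

Security estimation is nominal (the printed degree bound for the leveled
scheme; none for the scale-invariant scheme beyond the caller's choice of
$n$): no modern lattice estimator is consulted, and the demonstration rings
are toy-sized. No bootstrapping, rotations, NTT acceleration, constant-time
arithmetic or side-channel hardening. The approximate edit distance is the
set-difference surrogate, not Wagner–Fischer. Serialization is a JSON text
container with exact decimal coefficients and an md5 checksum — chosen over
a binary format so staged pipelines are reproducible and diffable;
bit-exact roundtrips are tested.
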