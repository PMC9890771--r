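# cipherDDP

Privacy-preserving outsourced solving of the **double digest problem**
(DDP) — reconstructing a restriction-site physical map from the three
fragment-length multisets of a double digest experiment, without ever
disclosing those lengths to the machine doing the search.

A double digest experiment cuts one DNA molecule with restriction
enzyme α, with enzyme β, and with both, and gel electrophoresis yields
three multisets of fragment lengths `A` (p values), `B` (q values) and
`C` (t values) with `sum(A) = sum(B) = sum(C)`. The DDP asks for two
*mapping sequences* — permutations μ of `1..p` and ν of `1..q` — whose
merged cut sites reproduce `C`. Writing `C'_{μ,ν}` for the ascending
implied simultaneous-digest spectrum of an arrangement, the solver
maximises

    f(μ, ν) = 1 / (1 + Σ_i |C'_{μ,ν}[i] − C[i]|),

and `f = 1` certifies an exact map. The problem is strongly
NP-complete, and the lengths themselves are the commercially sensitive
part of the data.

The package keeps them private with an **order-preserving homomorphic
index** (OPHI): each length `m` becomes an n-vector
`c_i = k_i·m + r_i` (i ≤ n−1), `c_n = k_n·Σr`, under secret normal keys
`0 < k_i ≤ 2^10` and budgeted positive noise. Componentwise addition is
additively homomorphic and comparing the first n−1 components preserves
plaintext order, so the whole DDP computation — cut-site prefix sums,
merging, step differences, spectrum comparison — runs on ciphertexts.
There is no decryption algorithm, by design. A **quantum-inspired
genetic algorithm** (QIGA; qubit-amplitude chromosomes, measurement
collapse, rotation gates, crossover, mutation) searches the permutation
pairs over the encrypted payload and returns only μ and ν, which carry
no length information. The owner verifies the result against the
plaintext instance in one pass; a lazy server returning random mappings
is caught with probability `1 − 1/(p!·q!)` per designated solution and
retried.

The five-stage protocol (encrypt → transfer → solve on ciphertexts →
transfer → extract and verify) is implemented as owner-side and
server-side functions with strict role separation, plus JSON file
formats for every channel artifact and a thin command line
(`exec/cipherddp`).

## Worked example

```r
library(cipherDDP)
set.seed(42)
g <- generateInstance(10)     # synthetic double digest, |C| = 10
g$instance
#> DDPInstance: p=5 q=6 t=10; sums A/B/C = 1000/1000/1000 (valid)

r <- runPipeline(g$instance, cryptoSeed = 7, gaSeed = 11)
r$success;  r$generations;  r$residual
#> [1] TRUE
#> [1] 1535
#> [1] 2.066328
r$mapping
#> MappingPair
#>   mu: 1 2 3 4 5
#>   nu: 2 4 3 6 5 1
r$map$sites
#>  [1]   49   74  146  153  228  321  561  634  997 1000
```

The pipeline encrypted the instance, ran the QIGA for 1535 generations
purely on ciphertexts until a measurement's residual (2.07) dropped
below the public noise threshold, and the owner's plaintext
verification accepted the returned mapping; `r$map$sites` is the
reconstructed physical map — the merged cut-site coordinates on the
1000-unit molecule. The server-side artifacts (`r$files`) contain only
ciphertext vectors and the two permutations.

Security arithmetic in one line: recovering a minimal 7-fragment
instance from its ciphertexts by exhaustive search succeeds with
probability `2^-119`:

```r
exhaustiveSearchBounds()$log2Full
#> [1] -119
```

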