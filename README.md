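# fahfalib

In silico MS/MS spectral libraries and automatic annotation for FAHFA
lipids (fatty acid esters of hydroxy fatty acids).

FAHFAs are a lipid class with anti-diabetic and anti-inflammatory
activity, but only a handful of reference standards exist, so untargeted
LC–MS/MS profiling cannot rely on experimental spectral libraries.
`fahfalib` takes the rule-based route: it enumerates the FAHFA structure
space combinatorially, generates negative-mode CID spectra for every
structure from a fragmentation template anchored on reference-standard
behaviour, writes the result as a NIST MSP library, and annotates query
spectra (MGF) by precursor-window retrieval plus forward/reverse
dot-product matching.

## The model in brief

A FAHFA `na:da-(p-O-nb:db)` is a fatty acyl chain (na carbons, da double
bonds) esterified to the hydroxyl of a hydroxy fatty acid backbone
(nb, db, hydroxyl carbon p). Its neutral formula is
C<sub>na+nb</sub>H<sub>2(na+nb)−2(da+db)−2</sub>O<sub>4</sub> and it is
observed as the deprotonated anion [M−H]⁻. Under collision-induced
dissociation the major product ions are:

| ion | composition (anion) |
|---|---|
| precursor | [M−H]⁻ |
| fatty acid fragment | C<sub>na</sub>H<sub>2na−2da−1</sub>O₂⁻ |
| hydroxy fatty acid fragment | C<sub>nb</sub>H<sub>2nb−2db−1</sub>O₃⁻ |
| its dehydration product | intact − H₂O |
| positional tail ion | C<sub>nb−p+1</sub>H<sub>2(nb−p)+1</sub>O⁻ |
| positional head ion | C<sub>p−1</sub>H<sub>2p−3</sub>O⁻ |

The two positional ions are sub-percent secondary fragments that encode
the hydroxyl position: they shift by one CH₂ (±14.01565 Da) per carbon.
They are visible only at slow (1 spectrum/s, "fragment-rich")
acquisition; fast profiling acquisition (4 spectra/s) sees only the four
major ions, so it identifies the species but not the hydroxyl position.

With the default 33-fatty-acid panel (14:0–24:6) the library holds
33² = 1089 general structures × 3 collision energies (10/20/40 V)
= 3267 profiling spectra, plus 4290 positional structures (saturated
backbones of length {14,15,16,17,18,20,22,24}, hydroxyl on every carbon
except C1 and the terminal carbon, × 33 acyl partners) rendered as 40 V
fragment-rich spectra — 7557 records in total.

Matching uses the conventional open reading of the NIST similarity: peak
weights w = I^0.5, score = 999·(Σ w_q w_r)²/(Σ w_q² · Σ w_r²) over
greedily aligned peaks; the *reverse* variant drops unmatched query
peaks from the query norm so noise and co-eluting ions do not penalise
the hit.

## Worked example

```r
library(fahfalib)

lib <- build_library()          # ~3 s
glance(lib)
#>   n_spectra n_profiling n_fragment_rich n_species precursor_mz_min
#> 1      7557        3267            4290      5379             449.

# the 20 V profiling spectrum of LAHOA, 18:2-(O-18:1)
prof <- dplyr::filter(lib, acquisition_mode == "profiling")
rec  <- dplyr::filter(prof, name == "18:2-(O-18:1)", collision_energy == 20)
rec$peaks[[1]]
#>         mz intensity                    role
#> 1 279.2330 100.00000 fa_anion+hfa_dehydrated
#> 2 297.2435  26.08696               hfa_anion
#> 3 559.4732  34.78261               precursor

# simulate a noisy acquired spectrum of it and annotate
q    <- simulate_query(rec, noise_model(), seed = 42)
hits <- annotate(q, prof)
hits[1, c("rank", "hit_name", "hit_abbreviation", "delta_mz_mda",
          "dot", "reverse_dot")]
#>   rank      hit_name hit_abbreviation delta_mz_mda dot reverse_dot
#> 1    1 18:2-(O-18:1)            LAHOA     4.573291 973         998
```

The fatty-acid anion of 18:2 and the dehydrated hydroxy-18:2 ion of the
backbone coincide exactly at m/z 279.233, so the rendered spectrum has
three peaks; the simulated query adds m/z jitter, intensity noise and
background peaks, and the annotator still returns the true species at
rank 1 with a reverse dot product of 998 and a 4.6 mDa precursor error —
the same regime as real profiling data (hits are reported at reverse
dot ≥ 900 within a 5 mDa precursor window).

Library I/O and the command line:

```r
write_msp(lib, "fahfa_library.msp")   # NIST text library, byte-stable
queries <- read_mgf("acquired.mgf")
write_annotation_report(annotate_batch(queries, lib), "hits.tsv")
```

```sh
Rscript inst/cli/fahfa.R build    --out lib.msp
Rscript inst/cli/fahfa.R simulate --species "18:2-(O-18:1)" --ce 20 \
                                  --seed 42 --out q.mgf
Rscript inst/cli/fahfa.R annotate --library lib.msp --queries q.mgf \
                                  --out hits.tsv
```

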