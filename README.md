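# dux4pipe

Quantitative pipeline for preclinical evaluation of DUX4-targeting siRNA
therapeutics in facioscapulohumeral muscular dystrophy (FSHD).

FSHD is caused by ectopic expression of the transcription factor DUX4 in
skeletal muscle. Because DUX4 itself is expressed at very low levels in
sporadic bursts, DUX4 *activity* is measured through the genes it induces, and
an siRNA drug candidate is characterised by (i) how strongly it suppresses
that downstream signature, (ii) whether its seed region silences unintended
"bystander" transcripts, and (iii) how long the siRNA persists in muscle
tissue. `dux4pipe` implements the full quantitative tool-chain for these three
questions, plus synthetic-data generators so every stage can be exercised and
validated without access to laboratory data.

## What it computes

**FSHD composite score** (DUX4 activity from qPCR Ct values):

    dCt  = mean Ct(4 DUX4-regulated genes) - mean Ct(2 housekeeping genes)
    ddCt = dCt(treated) - mean dCt(mock)
    composite = 2^(-ddCt) x 100 (%)

together with single-gene Livak 2^(-ddCt) relative expression,
geometric-mean panel composites (% of vehicle group), and NanoString-style
positive-control / housekeeping / calibrator normalisation.

**Seed-based off-target profile.** Seeds are the 6mer, two 7mers, and 8mer
windows of guide-strand bases 1-8 (5' end); a seed match is the DNA reverse
complement of the seed in a transcript's 3'UTR. For each seed class the log2
fold-change distribution of seed-matched expressed genes is compared with a
background set (genes with 6mer matches for 10 simulated random siRNAs) using
the Mann-Whitney AUC effect size, `P(FC_matched < FC_background)` with ties
half-weighted, and a two-sample Kolmogorov-Smirnov test (asymptotic p at
effective size `nm/(n+m)`). Repression of matched genes pushes AUC above 0.5.

**DE signature filters.** log2CPM normalisation with a low-expression filter
(average log2CPM < -3 eliminated), BH FDR, disease/treatment signature
concordance counts at printed thresholds (|log2FC| >= 1, FDR < 0.05), and
DUX4-responsive panel selection (TPM > 35 and log2FC > 1.5, strict).

**PK/PD curves.** Tissue half-life by ln-linear regression
(`t_1/2 = ln 2 / lambda`, `lambda = -slope`), three-parameter log(inhibitor)
vs response EC50/Emax fitting (Hill slope fixed at -1), RISC-loading ratios
relative to miR-16, 8-point standard-curve quantification, and
specific-binding-with-Hill-slope ELISA fits.

## Worked example

```r
library(dux4pipe)

guide <- "UCCAAACGAGUCUCCGUCG"   # guide complementary to the human target site
extract_seeds(guide)
#>    class start end     seed
#> 1   6mer     2   7   CCAAAC
#> 2 7mer_a     1   7  UCCAAAC
#> 3 7mer_b     2   8  CCAAACG
#> 4   8mer     1   8 UCCAAACG

db <- sim_utr_database(n_genes = 1000, implant_fraction = 0.05,
                       guide = guide, seed = 7)
matches <- scan_utr_matches(extract_seeds(guide), db$utrs)
table(class = matches$class, hit = matches$hit)
#>         hit
#> class    FALSE TRUE
#>   6mer     818  182
#>   7mer_a   957   43
#>   7mer_b   952   48
#>   8mer     988   12

ct <- sim_ct_table(n_mock = 8, n_treated = 8, knockdown_dct = 2, seed = 7)
fshd_composite(ct, c("MBD3L2", "ZSCAN4", "LEUTX", "KHDC1L"),
               c("AHSA1", "RPL27"))$summary
#>          condition group n   mean      sd geomean
#> mock.         mock  <NA> 8 162.74 192.528  100.00
#> treated.   treated  <NA> 8  15.11   1.663   15.03
```

The 6mer class hits ~18% of genes: the 50 implanted sites plus the expected
~13% random-background rate for a 6-nt motif in ~600-nt random UTRs
(`1 - (1 - 4^-6)^(L-5)`); the rarer 7/8mer hits are nested inside the 6mer
hits. In the Ct table a 2-cycle knockdown corresponds to a 25% composite;
with only 8 wells per condition the sporadic bursting of DUX4-regulated genes
(prob. 0.2, 3-cycle bursts in the generator) makes the mock reference noisy —
here the treated group reads 15% of mock, and the mock group's own mean of
163% with SD 193 shows exactly the burst-driven variability that motivates a
composite score over many wells in the first place.

```r
s <- sim_conc_time(t_half = 17, cv = 0.2, seed = 7)
fit_halflife_lnlinear(s$time, s$conc)
#> half-life: 17.2 days (lambda 0.0404 /day)

dr <- sim_dose_response(noise_sd = 2, seed = 7)
fit_log_inhibitor_response_3p(dr$conc, dr$response)
#> EC50 0.35 nM, Emax 95.4%
```

`run_workflow(out_dir, seed)` chains simulate → scan → off-target statistics
→ composite scoring → PK fits and writes tab-separated stage outputs plus a
JSON summary; reruns with the same seed are byte-identical.

## Vignette

`vignettes/dux4pipe-methods.Rmd` documents the models, the statistical
conventions and their assumptions, the synthetic-data generator design, and
known limitations.
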